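---
title: "Models and numerical methods in hydrotraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in hydrotraits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrotraits)
```

# Scope

`hydrotraits` implements the quantitative core of a tree-hydraulics
analysis: sigmoidal response-curve fitting with threshold derivation,
pressure–volume (PV) analysis of leaf water relations, conduit and pit
anatomical indices, conductance normalizations, stomatal operating traits,
and an assumption-gated two-sample testing procedure, together with seeded
generators that emulate each raw measurement type. This vignette explains
the models, the defaults, and the numerical decisions that were genuinely
open.

# The exponential-sigmoid response model

Percentage loss of conductivity (PLC) under xylem pressure $P$ (MPa,
negative) is modeled as

$$\mathrm{PLC}(P) = \frac{100}{1 + \exp[a\,(P - P_{50})]},$$

with $a > 0$ in MPa$^{-1}$ and $P_{50} < 0$ the pressure at 50% loss.
Thresholds invert in closed form:
$P_y = P_{50} + \ln(100/y - 1)/a$, so
$P_{12} - P_{50} = P_{50} - P_{88} = \ln(22/3)/a$ — the logistic is
symmetric, and `thresholds_of()` exploits this exactly.

**Fitting.** `fit_sigmoid()` minimizes the unweighted sum of squared
percent residuals with `nlminb` on a log-$a$ scale (positivity by
construction; relative tolerance $10^{-14}$, which comfortably delivers
the $10^{-6}$ relative recovery of noiseless data demonstrated in the test
suite). Initialization is parameter-free: $a_0 = 1$ MPa$^{-1}$ and
$P_{50,0}$ at the observed point whose percent is closest to 50. On
non-convergence, three deterministic perturbed restarts are tried and the
lowest-SSE solution kept; a still-failing fit errors rather than returning
garbage.

**Identifiability guards.** A fit is refused when fewer than 3 points are
supplied, the percent range is under 30 percent-units, all percents lie
strictly on one side of 50%, or all pressures coincide. Noisy percents
outside $[0, 100]$ are deliberately *not* clipped: clipping truncates the
residual distribution asymmetrically and biases $a$.

**Orientation.** PLC rises toward 100% as pressure falls, but percent
stomatal conductance falls during dehydration. Fitting the literal rising
model to a falling series would require $a < 0$. Instead the fit carries a
`direction` field (auto-detected from the pressure–percent correlation):
falling series are fitted as the mirrored logistic
$100 - 100/\{1+\exp[a(P-P_{50})]\}$ with $a > 0$, and `percent_at()` /
`pressure_at_percent()` respect the stored orientation. Consequently
`pressure_at_percent(closure_fit, 12)` is the water potential at 12% of
maximum conductance — the operational definition of full stomatal closure
($\Psi_{sc}$) — and lies on the more-negative side of the midpoint, as it
must. By symmetry this is the same fitted curve either way; the
orientation only fixes the meaning of the threshold levels.

# Pressure–volume analysis

For each leaf, $1/\Psi$ is regressed on the water saturation deficit
$\mathrm{WSD} = (TW - FW)/(TW - DW)$ (1 − relative water content). Beyond
the turgor loss point the symplast behaves osmotically: solute
conservation gives $\Psi = \Psi_{osat}/(1 - W)$, i.e. a straight line
$1/\Psi = (1 - W)/\Psi_{osat}$ in these coordinates. While turgid, turgor
pressure adds a curved component. The analysis fits a quadratic to the
turgescent section and an ordinary least-squares line to the osmotic
section, then reads off:

* $\Psi_{osat}$ = 1/(line intercept at WSD = 0) — the reciprocal step is
  implicit when the y-axis carries $1/\Psi$;
* $\Psi_{TLP}$ = line value at the parabola–line intersection;
* $a_{ela}$ = |quadratic coefficient| of the turgescent parabola (the
  "opening width"; larger = narrower parabola = stiffer walls). Its
  absolute magnitude depends on the parameterization of the fitted
  parabola, so it should be compared only *between* leaves analysed the
  same way, not against values from other software.

**Split selection.** Every admissible split (at least `min_segment = 3`
points per segment) is scored by the summed SSE of the two fits, and the
minimizing split is chosen — but only among splits whose parabola–line
system has a real intersection inside the observed WSD range. The
physical TLP must exist; without this admissibility constraint the SSE
criterion occasionally prefers splits that misassign a turgescent point
to the line and lose the intersection (negative discriminant),
turning a healthy curve into a spurious "no TLP" failure. Ties break
toward the smaller turgescent segment.

**Local elbow parabola for the TLP.** A single quadratic cannot track the
steep near-saturation branch of $1/\Psi$ without distorting its shape
near the boundary, and the curve meets the osmotic line at a shallow
angle, so small shape errors displace the intersection strongly. The
package therefore refits a local parabola to the last `tlp_window = 4`
turgescent points *plus the first osmotic point*: including the first
point beyond the boundary brackets the crossing inside data instead of
extrapolating into unmodeled curvature, where the intersection can even
disappear when the true boundary falls mid-gap between samples. On the
mechanistic generator this reduces the worst-case noiseless $\Psi_{TLP}$
error across a broad truth grid from ~6% to ~1%. The full-segment
parabola is still what $a_{ela}$ is read from.

**Hard invariants.** A fit errors (never silently returns) when
$\Psi_{TLP} > \Psi_{osat}$, when the osmotic line slope is not positive in
(WSD, $1/\Psi$) space, or when the line intercept is non-negative.

# Flow, anatomy and operating traits

* Centrifuge PLC series: $\mathrm{PLC}_i = 100(1 - k_i/k_1)$, the first
  reading (at −0.25 MPa) being the 100%-conductivity reference even if
  native embolism exists; native embolism is the separate diagnostic
  `native_plc()` from pre/post-flush conductances, floored at 0. Note a
  small inherent bias: the reference reading itself sits at ~1% PLC on
  steep curves, so raw-conductance pipelines recover $P_{50}$ closely but
  not to machine precision even noiselessly.
* Specific conductivity $k_s = k \cdot l / A_{xylem}$; the default input
  unit kg s⁻¹ MPa⁻¹ is converted via water density 1 g cm⁻³
  (kg ↔ 10³ cm³) so $k_s$ is in cm² s⁻¹ MPa⁻¹. No viscosity or
  temperature normalization is applied.
* $d_h = \Sigma d^5 / \Sigma d^4 \ge \bar d$, with equality iff all
  diameters are equal. Wall reinforcement $(t/b)^2$ is computed over all
  measured pairs by default; an optional `near_dh` window restricts pairs
  to conduits near $d_h$.
* Group summaries use the hierarchical (per-sample-first) mean so samples
  with many conduits/leaves do not dominate; this equals the pooled mean
  only for balanced samples. $d_{max}$ is the mean of each sample's single
  largest conduit, consistent with the other per-sample-first statistics.
* $g_{smax}$ pools the top $n = 8$ conductances of each measurement
  campaign and averages the concatenated pool (`pool_gsmax`,
  `mode = "per_campaign"`); taking the top 8 of the combined set is
  available as `mode = "pooled"` since the field convention is ambiguous.
  $\Psi_{lmin}$ averages the 8 lowest water potentials irrespective of
  time of day. Safety margins are signed differences of thresholds
  (negative = risky ordering), and `sequence_thresholds()` orders named
  thresholds as they are crossed during dehydration.

# Gated two-sample testing

`gated_two_sample_test()` mirrors the procedure common in ecophysiology
papers: per-group one-sample Kolmogorov–Smirnov checks against a normal
with the sample's own moments (estimated moments make this a
Lilliefors-style approximation, slightly conservative; recorded in the
report), and Levene's test — ANOVA on absolute deviations from group
means, the SPSS default centering — for variance homogeneity. Levene
$p < \alpha$ selects Welch's unequal-variance test, otherwise the pooled
Student t-test. The gate is data-driven, never user-chosen post hoc.
Normality failure warns but does not switch test families (no
non-parametric fallback is provided, matching the procedure emulated).
Degenerate zero-variance groups follow stated conventions ($p = 1$ with
equal means, $p = 0$ otherwise). Under the null the gated procedure's
type-I error stays within [0.03, 0.07] at $\alpha = 0.05$ (verified by
simulation in the test suite).

# Synthetic generators: what they emulate, and what a green test means

All generators are pure functions of their arguments and seed, and leave
the caller's RNG state untouched.

* `gen_vulnerability()`: exact sigmoid plus **additive Gaussian noise in
  percent space** (default sd 5 percent-units — flowmeter noise is roughly
  absolute); raw-conductance mode emits $k_i = k_0(1 - \mathrm{PLC}_i/100)$
  with multiplicative log-normal noise. Default pressure schedule −0.25 to
  −7.75 MPa in 0.5 MPa steps, mirroring a centrifuge run that starts at
  −0.25 MPa and spins until flow vanishes.
* `gen_pv_leaf()`: mechanistic PV model — osmotic component
  $\Psi_{osat}/(1-W)$ plus turgor $-\Psi_{osat}(1 - W/W_{TLP})$ declining
  linearly to zero at the TLP, hence
  $\Psi_{TLP} = \Psi_{osat}/(1 - W_{TLP})$ analytically — with **Gaussian
  noise in $1/\Psi$ space** (pressure-chamber read-off, default sd
  0.01 MPa⁻¹). The default WSD schedule, 0.04–0.40 in 0.02 steps
  (~19 readings), represents bench dehydration sampled at ~2% of saturated
  water content, starting once the leaf is measurably off saturation:
  over-saturated initial points are conventionally discarded in PV work,
  and exactly at $W = 0$ the model's $1/\Psi$ diverges.
* `gen_conduits()`: log-normal diameters (median 20 µm, log-sd 0.3,
  200 conduits per section), the canonical right-skewed model for conduit
  populations.
* `gen_diurnal()`: flat-topped quartic-exponential bump for $g_s$
  (morning rise, broad midday maximum, evening decline) with an antiphase
  $\Psi_l$ course from a near-zero pre-dawn value; curves are rescaled
  after evaluation so the sampled maximum/minimum equal the configured
  truths exactly in the noiseless case.

These generators reproduce the *statistical structure* each analysis
stage assumes — not real leaves or stems. A green recovery test
establishes that the estimators are correct and well-conditioned under
the stated noise models; it cannot establish that field data satisfy
those models (e.g. real PV curves can show oversaturation plateaus,
operator-terminated schedules, or non-Gaussian errors, and real
vulnerability curves can deviate from the logistic in the tails).

# Conventions and degenerate inputs

Pressures are stored as negative MPa throughout; readers and fitters
reject positive pressures with an explicit message and offer
`auto_negate = TRUE` for data recorded as tensions. CSVs are
comma-separated, UTF-8, dot-decimal, with a mandatory header; validation
errors name the file, column and row. Pipeline runs are deterministic
given config and seed (sub-seeds are derived arithmetically per group and
sample). Significance is flagged with an asterisk in formatted trait
tables, only ever sourced from the gate procedure.

# Known limitations

* $a_{ela}$ is comparable only within a consistent parameterization; no
  absolute calibration is attempted.
* Alternative vulnerability models (Weibull, cumulative normal) and
  per-fit confidence intervals are out of scope; uncertainty is carried
  as SE across samples.
* The KS normality gate uses estimated moments without the Lilliefors
  small-sample correction; with gate decisions at $\alpha = 0.05$ this
  only affects the (logged) normality warning, not the variance-driven
  test choice.
* No multiple-testing correction is applied; comparisons are pairwise at
  $\alpha = 0.05$ by design.
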