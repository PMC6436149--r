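# Seeded synthetic-data generators emulating each raw measurement type:
# centrifuge vulnerability series, pressure-volume leaves, conduit diameter
# populations, and diurnal gas-exchange courses. All generators are pure
# functions of their arguments and seed; the caller's RNG state is left
# untouched.

#' Default centrifuge pressure schedule
#'
#' First reading at -0.25 MPa, then 0.5 MPa steps down to -7.75 MPa
#' (spins continue until flow is no longer measurable).
#'
#' @return Numeric vector of pressures, MPa.
#' @export
default_pressure_schedule <- function() seq(-0.25, -8, by = -0.5)

#' Simulate a vulnerability (PLC vs pressure) series
#'
#' Draws percent responses on the exponential sigmoid with additive
#' Gaussian noise in percent space (instrument flow noise is roughly
#' absolute). In raw-conductance mode (`k0` given) the noiseless PLC is
#' converted to a conductance series `k_i = k0 * (1 - PLC_i/100)` with
#' multiplicative log-normal noise of coefficient of variation
#' `k_noise_cv`, for testing the flow pipeline.
#'
#' @param a Slope parameter, MPa^-1 (> 0).
#' @param p50 Pressure at 50% response, MPa (< 0).
#' @param pressures Pressure schedule, MPa (<= 0); default
#'   [default_pressure_schedule()].
#' @param noise_sd Additive percent-space noise SD (default 5
#'   percent-units; 0 for noiseless).
#' @param seed Optional integer seed.
#' @param k0 Optional reference conductance; switches to raw-k mode.
#' @param k_noise_cv Multiplicative log-normal noise CV for raw-k mode
#'   (default 0).
#' @return data.frame `pressure_mpa`, `percent` (and `k` in raw-k mode,
#'   where `percent` holds the noiseless truth).
#' @examples
#' gen_vulnerability(0.95, -5, noise_sd = 0)
#' @export
gen_vulnerability <- function(a, p50, pressures = default_pressure_schedule(),
                              noise_sd = 5, seed = NULL,
                              k0 = NULL, k_noise_cv = 0) {
  pars <- validate_sigmoid_pars(list(a = a, p50 = p50))
  check_numeric(pressures, "pressures", nonpos = TRUE)
  check_numeric(noise_sd, "noise_sd", nonneg = TRUE)
  truth <- percent_at(pars, pressures)
  with_seed(seed, {
    if (is.null(k0)) {
      data.frame(pressure_mpa = pressures,
                 percent = truth + stats::rnorm(length(truth), 0, noise_sd))
    } else {
      check_numeric(k0, "k0", positive = TRUE)
      check_numeric(k_noise_cv, "k_noise_cv", nonneg = TRUE)
      k <- k0 * (1 - truth / 100)
      if (k_noise_cv > 0) {
        sdlog <- sqrt(log(1 + k_noise_cv^2))
        k <- k * stats::rlnorm(length(k), -sdlog^2 / 2, sdlog)
      }
      data.frame(pressure_mpa = pressures, percent = truth, k = k)
    }
  })
}

#' Mechanistic leaf water potential during dehydration
#'
#' Total water potential of the synthetic pressure-volume leaf at
#' saturation deficit `w`: osmotic component `psi_osat / (1 - w)` (solute
#' conservation) plus, while turgid (`w < w_tlp`), turgor
#' `-psi_osat * (1 - w / w_tlp)` declining linearly to zero at the turgor
#' loss point. Continuous at `w_tlp` with
#' `Psi_TLP = psi_osat / (1 - w_tlp)`; tends to 0- as `w -> 0+`.
#'
#' @param w Water saturation deficit(s) in \[0, 1).
#' @param psi_osat Osmotic potential at full saturation, MPa (< 0).
#' @param w_tlp WSD at turgor loss, in (0, 1).
#' @return Water potential(s), MPa.
#' @examples
#' pv_model_psi(0.10, -2.0, 0.10)  # -2.222 = -2.0 / 0.9
#' @export
pv_model_psi <- function(w, psi_osat, w_tlp) {
  check_numeric(w, "w", nonneg = TRUE)
  if (any(w >= 1)) stop("`w` must lie in [0, 1)", call. = FALSE)
  check_numeric(psi_osat, "psi_osat", negative = TRUE)
  if (!is.numeric(w_tlp) || w_tlp <= 0 || w_tlp >= 1) {
    stop("`w_tlp` must lie in (0, 1)", call. = FALSE)
  }
  psi_osat / (1 - w) + ifelse(w < w_tlp, -psi_osat * (1 - w / w_tlp), 0)
}

#' Simulate a pressure-volume dehydration series for one leaf
#'
#' Evaluates [pv_model_psi()] on a WSD schedule and adds Gaussian noise in
#' 1/Psi space (pressure-chamber read-off error). The default schedule
#' samples WSD 0.04-0.40 in 0.02 steps: bench dehydration with readings
#' roughly every 2% of saturated water content, starting once the leaf is
#' measurably off full saturation (over-saturated initial points are
#' conventionally discarded in pressure-volume work).
#'
#' @param psi_osat Osmotic potential at full saturation, MPa (< 0).
#' @param w_tlp WSD at turgor loss, in (0, 1).
#' @param wsd_schedule WSD sampling points, each in (0, 0.9].
#' @param noise_sd_invpsi Noise SD in 1/Psi space, MPa^-1 (default 0.01).
#' @param seed Optional integer seed.
#' @return data.frame `wsd`, `psi_mpa`, `inv_psi` (noisy 1/Psi; `psi_mpa`
#'   is its reciprocal so the two stay consistent).
#' @examples
#' gen_pv_leaf(-2.56, 0.1381, noise_sd_invpsi = 0)
#' @export
gen_pv_leaf <- function(psi_osat, w_tlp, wsd_schedule = seq(0.04, 0.40, 0.02),
                        noise_sd_invpsi = 0.01, seed = NULL) {
  check_numeric(wsd_schedule, "wsd_schedule", positive = TRUE)
  if (any(wsd_schedule > 0.9)) {
    stop("`wsd_schedule` must lie within (0, 0.9]", call. = FALSE)
  }
  check_numeric(noise_sd_invpsi, "noise_sd_invpsi", nonneg = TRUE)
  psi <- pv_model_psi(wsd_schedule, psi_osat, w_tlp)
  with_seed(seed, {
    inv <- 1 / psi + stats::rnorm(length(psi), 0, noise_sd_invpsi)
    if (any(inv >= 0)) {
      # noise pushed a point across zero; resample those draws once
      bad <- inv >= 0
      inv[bad] <- 1 / psi[bad] - abs(stats::rnorm(sum(bad), 0, noise_sd_invpsi))
    }
    data.frame(wsd = wsd_schedule, psi_mpa = 1 / inv, inv_psi = inv)
  })
}

#' Simulate a right-skewed conduit diameter population
#'
#' Log-normal diameters, the canonical right-skewed model for conduit
#' diameter distributions. `sigma_log = 0` gives a degenerate population
#' with all diameters at the median (so d_h equals the mean).
#'
#' @param median_um Median diameter, um (> 0); default 20 (typical
#'   apple-branch conduits run ~20-25 um).
#' @param sigma_log Log-scale SD (>= 0); default 0.3.
#' @param n Number of conduits (> 0); default 200 per section.
#' @param seed Optional integer seed.
#' @return Numeric vector of diameters, um.
#' @export
gen_conduits <- function(median_um = 20, sigma_log = 0.3, n = 200L,
                         seed = NULL) {
  check_numeric(median_um, "median_um", positive = TRUE)
  check_numeric(sigma_log, "sigma_log", nonneg = TRUE)
  if (!is.numeric(n) || n <= 0) stop("`n` must be positive", call. = FALSE)
  with_seed(seed, {
    if (sigma_log == 0) rep(median_um, n)
    else stats::rlnorm(n, log(median_um), sigma_log)
  })
}

#' Simulate a diurnal gas-exchange course
#'
#' Smooth unimodal stomatal-conductance course (morning rise, broad
#' midday maximum, evening decline; a flat-topped quartic-exponential
#' bump) with an antiphase leaf-water-potential course declining from a
#' near-zero pre-dawn value to its midday minimum. Curves are rescaled
#' after evaluation so that, noiselessly, `max(gs) == gs_max_true` and
#' `min(psi_l) == psi_min_true` exactly at the sampled times.
#'
#' @param gs_max_true True maximum conductance, mmol m^-2 s^-1 (> 0).
#' @param psi_min_true True minimum leaf water potential, MPa (< 0).
#' @param n_times Number of samples between 05:00 and 18:00 (default 27,
#'   i.e. half-hourly-ish); at least 4.
#' @param noise_gs Additive gs noise SD (default 0).
#' @param noise_psi Additive Psi_l noise SD, MPa (default 0).
#' @param psi_predawn Pre-dawn water potential, MPa (< 0, default -0.2).
#' @param seed Optional integer seed.
#' @return data.frame `time` (hours), `gs_mmol`, `psi_mpa`.
#' @export
gen_diurnal <- function(gs_max_true = 500, psi_min_true = -2.7,
                        n_times = 27L, noise_gs = 0, noise_psi = 0,
                        psi_predawn = -0.2, seed = NULL) {
  check_numeric(gs_max_true, "gs_max_true", positive = TRUE)
  check_numeric(psi_min_true, "psi_min_true", negative = TRUE)
  check_numeric(psi_predawn, "psi_predawn", negative = TRUE)
  if (psi_min_true >= psi_predawn) {
    stop("`psi_min_true` must be more negative than `psi_predawn`",
         call. = FALSE)
  }
  if (!is.numeric(n_times) || n_times < 4L) {
    stop("`n_times` must be at least 4", call. = FALSE)
  }
  check_numeric(noise_gs, "noise_gs", nonneg = TRUE)
  check_numeric(noise_psi, "noise_psi", nonneg = TRUE)
  tt <- seq(5, 18, length.out = n_times)
  bump <- function(t, centre, width) exp(-((t - centre) / width)^4)
  gs_shape <- bump(tt, 12.5, 4.5)
  psi_shape <- bump(tt, 13, 5)
  gs <- gs_max_true * gs_shape / max(gs_shape)
  psi <- psi_predawn + (psi_min_true - psi_predawn) * psi_shape / max(psi_shape)
  with_seed(seed, {
    gs <- pmax(gs + stats::rnorm(n_times, 0, noise_gs), 0)
    psi <- pmin(psi + stats::rnorm(n_times, 0, noise_psi), -1e-6)
    data.frame(time = tt, gs_mmol = gs, psi_mpa = psi)
  })
}
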