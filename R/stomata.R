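# Stomatal operating-point and closure traits: percent conductance
# normalization, extreme-value g_smax / Psi_lmin, safety margins, threshold
# sequencing, stomatal density and pore-length aggregation.

#' Percent stomatal conductance series
#'
#' Normalizes a (Psi_l, g_s) dehydration series by its own maximum g_s,
#' producing (pressure, percent) points that feed [fit_sigmoid()]. The
#' water potential at full stomatal closure (Psi_sc) is then
#' `pressure_at_percent(fit, 12)` and the onset of closure
#' `pressure_at_percent(fit, 88)`.
#'
#' @param psi_l Leaf water potentials, MPa (< 0).
#' @param gs Stomatal conductances, mmol m^-2 s^-1 (>= 0, max > 0).
#' @return data.frame `pressure_mpa`, `percent` with exactly one 100%
#'   point (the series maximum).
#' @examples
#' percent_gs(c(-0.5, -2, -4), c(600, 300, 60))
#' @export
percent_gs <- function(psi_l, gs) {
  check_numeric(psi_l, "psi_l", negative = TRUE)
  check_numeric(gs, "gs", nonneg = TRUE)
  if (length(psi_l) != length(gs)) {
    stop("`psi_l` and `gs` must have equal length", call. = FALSE)
  }
  if (max(gs) == 0) stop("all stomatal conductances are zero", call. = FALSE)
  data.frame(pressure_mpa = psi_l, percent = 100 * gs / max(gs))
}

#' Mean of the n most extreme values
#'
#' Operating extremes such as maximum stomatal conductance (g_smax, mean
#' of the highest g_s readings) and minimum leaf water potential
#' (Psi_lmin, mean of the lowest Psi_l readings) are defined as means of
#' the n most extreme values of a campaign.
#'
#' @param values Numeric vector (non-empty).
#' @param n How many extreme values to average (conventionally 8). When
#'   fewer values exist, all are used with a warning.
#' @param side `"highest"` or `"lowest"`.
#' @return Mean of the selected values.
#' @examples
#' extreme_mean(1:10, 8, "highest")  # 6.5
#' @export
extreme_mean <- function(values, n = 8L, side = c("highest", "lowest")) {
  side <- match.arg(side)
  check_numeric(values, "values")
  check_numeric(n, "n", positive = TRUE)
  if (length(values) < n) {
    warning("fewer than ", n, " values; using all ", length(values),
            call. = FALSE)
    n <- length(values)
  }
  sorted <- sort(values, decreasing = (side == "highest"))
  mean(sorted[seq_len(n)])
}

#' Pooled maximum operating stomatal conductance
#'
#' g_smax pools the highest conductances of several measurement campaigns
#' (e.g. a diurnal course and an in-situ dehydration series). Two pooling
#' modes: `"per_campaign"` (default) takes the top `n` of each campaign
#' and averages the concatenated pool; `"pooled"` takes the top `n` of all
#' values combined.
#'
#' @param campaigns List of numeric g_s vectors, one per campaign.
#' @param n Extremes taken per campaign (or overall for `"pooled"`).
#' @param mode `"per_campaign"` or `"pooled"`.
#' @return Mean g_smax.
#' @export
pool_gsmax <- function(campaigns, n = 8L, mode = c("per_campaign", "pooled")) {
  mode <- match.arg(mode)
  if (!is.list(campaigns) || !length(campaigns)) {
    stop("`campaigns` must be a non-empty list of numeric vectors", call. = FALSE)
  }
  if (mode == "pooled") {
    return(extreme_mean(unlist(campaigns), n, "highest"))
  }
  tops <- unlist(lapply(campaigns, function(v) {
    m <- min(n, length(v))
    sort(v, decreasing = TRUE)[seq_len(m)]
  }))
  mean(tops)
}

#' Hydraulic safety margin between two dehydration thresholds
#'
#' Signed difference `a - b` (both negative MPa). Positive means threshold
#' `a` is reached at less negative water potential, i.e. before `b` during
#' dehydration; a negative margin between stomatal closure and embolism
#' onset flags the "risky" ordering (stomata close only after embolism
#' begins).
#'
#' @param threshold_a,threshold_b Water-potential thresholds, MPa (< 0).
#' @return Margin in MPa; antisymmetric in its arguments.
#' @examples
#' safety_margin(-3.75, -2.90)  # -0.85: closure after embolism onset
#' @export
safety_margin <- function(threshold_a, threshold_b) {
  check_numeric(threshold_a, "threshold_a", negative = TRUE)
  check_numeric(threshold_b, "threshold_b", negative = TRUE)
  threshold_a - threshold_b
}

#' Order named dehydration thresholds
#'
#' Sorts named water-potential thresholds from least to most negative,
#' the order in which they are crossed during dehydration. Ties keep
#' input order (stable sort). The ordering is an output of the data, not
#' an assumption.
#'
#' @param thresholds Named numeric vector of thresholds, MPa (< 0), at
#'   least one.
#' @return data.frame `name`, `value` ordered least to most negative.
#' @examples
#' sequence_thresholds(c(P12 = -2.90, Psi_TLP = -2.97, Psi_sc = -3.75,
#'                       P50 = -5.00))
#' @export
sequence_thresholds <- function(thresholds) {
  check_numeric(thresholds, "thresholds", negative = TRUE)
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds)))) {
    stop("`thresholds` must be a fully named vector", call. = FALSE)
  }
  ord <- order(-thresholds)  # least negative first; stable for ties
  data.frame(name = names(thresholds)[ord], value = unname(thresholds[ord]))
}

#' Stomatal density from counts on a defined area
#'
#' @param count Stomata counted (>= 0).
#' @param area_mm2 Counting area, mm^2 (> 0).
#' @return Density, stomata mm^-2.
#' @examples
#' stomatal_density(53, 0.2)  # 265
#' @export
stomatal_density <- function(count, area_mm2) {
  check_numeric(count, "count", nonneg = TRUE)
  check_numeric(area_mm2, "area_mm2", positive = TRUE)
  count / area_mm2
}

#' Group summary of stomatal density and pore length
#'
#' Per-region densities are averaged per leaf first, then across leaves
#' ([hierarchical_mean()]); pore lengths likewise.
#'
#' @param density_leaf Leaf identifier per density region.
#' @param count Stomata counts per region.
#' @param area_mm2 Region areas, mm^2 (> 0).
#' @param pore_leaf Optional leaf identifier per pore-length measurement.
#' @param pore_length_um Optional pore lengths, um (> 0).
#' @return List with `sd` and (when given) `pore_length`, each a
#'   [hierarchical_mean()] summary.
#' @export
stomatal_anatomy_summary <- function(density_leaf, count, area_mm2,
                                     pore_leaf = NULL, pore_length_um = NULL) {
  dens <- stomatal_density(count, area_mm2)
  out <- list(sd = hierarchical_mean(dens, density_leaf))
  if (!is.null(pore_length_um)) {
    check_numeric(pore_length_um, "pore_length_um", positive = TRUE)
    if (is.null(pore_leaf)) {
      stop("`pore_leaf` required with `pore_length_um`", call. = FALSE)
    }
    out$pore_length <- hierarchical_mean(pore_length_um, pore_leaf)
  }
  out
}
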