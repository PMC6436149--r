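# Conduit- and pit-level anatomical indices from measured lumen areas,
# diameters and wall-thickness pairs.

#' Circular-equivalent conduit diameter from lumen area
#'
#' `d = 2 * sqrt(A / pi)`, assuming a circular conduit cross-section.
#'
#' @param area Lumen area(s), um^2 (> 0).
#' @return Diameter(s), um.
#' @examples
#' diameter_from_area(pi)  # 2
#' @export
diameter_from_area <- function(area) {
  check_numeric(area, "area", positive = TRUE)
  2 * sqrt(area / pi)
}

#' Hydraulically weighted conduit diameter
#'
#' `d_h = sum(d^5) / sum(d^4)`, which up-weights the wide conduits that
#' dominate flow (conductivity scales with the fourth power of diameter).
#' Always >= the arithmetic mean, with equality iff all diameters are
#' equal.
#'
#' @param diameters Conduit diameters, um (non-empty, > 0).
#' @return Hydraulic diameter, um.
#' @examples
#' hydraulic_diameter(c(10, 20))  # 19.412
#' @export
hydraulic_diameter <- function(diameters) {
  check_numeric(diameters, "diameters", positive = TRUE)
  sum(diameters^5) / sum(diameters^4)
}

#' Conduit wall reinforcement (t/b)^2
#'
#' Squared ratio of double wall thickness `t` between adjacent conduits to
#' conduit diameter `b`, a proxy for implosion resistance. Optionally
#' restricted to pairs whose `b` lies within a relative window around the
#' hydraulic diameter (the "near d_h" convention).
#'
#' @param t Double wall thicknesses, um (> 0).
#' @param b Conduit diameters, um (> 0), same length as `t`.
#' @param d_h Optional hydraulic diameter used by the `near_dh` filter.
#' @param near_dh Optional relative half-width; keeps pairs with
#'   `abs(b - d_h) <= near_dh * d_h` (e.g. `0.1` for +/- 10\%). Requires
#'   `d_h`.
#' @return List with `per_pair` ((t/b)^2 per pair), `mean`, `mean_e3`
#'   (mean x 10^3, the unit used in trait tables), `n`.
#' @examples
#' wall_reinforcement(1.5, 22)$mean_e3  # 4.65
#' @export
wall_reinforcement <- function(t, b, d_h = NULL, near_dh = NULL) {
  check_numeric(t, "t", positive = TRUE)
  check_numeric(b, "b", positive = TRUE)
  if (length(t) != length(b)) {
    stop("`t` and `b` must have equal length", call. = FALSE)
  }
  if (!is.null(near_dh)) {
    if (is.null(d_h)) stop("`near_dh` filtering requires `d_h`", call. = FALSE)
    keep <- abs(b - d_h) <= near_dh * d_h
    if (!any(keep)) {
      stop("no wall pairs within ", near_dh * 100, "% of d_h", call. = FALSE)
    }
    t <- t[keep]; b <- b[keep]
  }
  tb2 <- (t / b)^2
  list(per_pair = tb2, mean = mean(tb2), mean_e3 = mean(tb2) * 1e3,
       n = length(tb2))
}

#' Conduit diameter frequency distribution
#'
#' Left-closed, right-open bins `[k*w, (k+1)*w)` of width `w`.
#'
#' @param diameters Conduit diameters, um (may be empty).
#' @param bin_width Bin width, um (> 0); default 5.
#' @param relative If `TRUE`, frequencies are normalized to sum to 1.
#' @return data.frame `bin_left`, `bin_right`, `count` (or `frequency`).
#' @export
diameter_histogram <- function(diameters, bin_width = 5, relative = FALSE) {
  check_numeric(bin_width, "bin_width", positive = TRUE)
  if (!length(diameters)) {
    out <- data.frame(bin_left = numeric(0), bin_right = numeric(0))
    out[[if (relative) "frequency" else "count"]] <- numeric(0)
    return(out)
  }
  check_numeric(diameters, "diameters", nonneg = TRUE)
  idx <- floor(diameters / bin_width)
  bins <- seq(min(idx), max(idx))
  counts <- vapply(bins, function(b) sum(idx == b), numeric(1L))
  out <- data.frame(bin_left = bins * bin_width,
                    bin_right = (bins + 1) * bin_width)
  out[[if (relative) "frequency" else "count"]] <-
    if (relative) counts / sum(counts) else counts
  out
}

#' Hierarchical (per-sample-first) group mean
#'
#' Averages values within each sample first and then across samples, so
#' that samples with many measurements do not dominate the group mean (the
#' "unbalanced weighting" guard used for conduit statistics). This is NOT
#' the pooled mean unless all samples are equal-sized.
#'
#' @param values Numeric measurements.
#' @param sample Sample identifier per value (any atomic vector), same
#'   length as `values`.
#' @return List with `mean`, `se` (`NA` for a single sample), `n_samples`,
#'   and `sample_means`.
#' @examples
#' hierarchical_mean(c(10, 20, 20, 20, 20), c("a", "b", "b", "b", "b"))$mean  # 15
#' @export
hierarchical_mean <- function(values, sample) {
  check_numeric(values, "values")
  if (length(values) != length(sample)) {
    stop("`values` and `sample` must have equal length", call. = FALSE)
  }
  sm <- tapply(values, sample, mean)
  if (length(sm) == 1L) {
    warning("single sample: SE undefined", call. = FALSE)
  }
  list(mean = mean(sm), se = se_of(as.numeric(sm)),
       n_samples = length(sm), sample_means = sm)
}

#' Mean xylem ring width per section
#'
#' Ring width is measured at several (conventionally five) positions
#' across a section and averaged per sample; group summaries then use
#' [hierarchical_mean()] across samples.
#'
#' @param positions Ring-width measurements, um (> 0).
#' @return Mean ring width, um. A single position triggers a warning.
#' @examples
#' ring_width(c(400, 500, 600, 500, 510))  # 502
#' @export
ring_width <- function(positions) {
  check_numeric(positions, "positions", positive = TRUE)
  if (length(positions) == 1L) {
    warning("single ring-width position measured", call. = FALSE)
  }
  mean(positions)
}

#' Per-pit means of repeated pit measurements
#'
#' TEM pit parameters (membrane thickness, chamber depth) are measured
#' several times per pit; the per-pit value is the mean of its repeats.
#' Group summaries then aggregate per-shoot via [hierarchical_mean()].
#'
#' @param values Measurements, nm (> 0).
#' @param pit Pit identifier per measurement.
#' @return Named numeric vector of per-pit means.
#' @export
pit_means <- function(values, pit) {
  check_numeric(values, "values", positive = TRUE)
  if (length(values) != length(pit)) {
    stop("`values` and `pit` must have equal length", call. = FALSE)
  }
  out <- tapply(values, pit, mean)
  stats::setNames(as.numeric(out), names(out))
}
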