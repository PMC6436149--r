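#' Pressure-volume analysis of leaf water relations
#'
#' During slow bench dehydration of a leaf, plotting the reciprocal water
#' potential 1/Psi against the water saturation deficit (WSD) yields a
#' curve with two regimes: a curved turgescent section (turgor pressure
#' still positive) and, beyond the turgor loss point (TLP), a straight
#' osmotic section (solute conservation makes 1/Psi linear in WSD). The
#' turgescent section is fitted with a parabola and the osmotic section
#' with a line; the osmotic potential at full saturation (Psi_osat) is the
#' reciprocal of the line's intercept at WSD = 0, the TLP water potential
#' (Psi_TLP) comes from the parabola-line intersection, and the cell-wall
#' elasticity index a_ela is the opening-width (quadratic) coefficient of
#' the parabola (lower = more elastic walls).
#'
#' @name pressure-volume
#' @keywords internal
NULL

#' Water saturation deficit from leaf masses
#'
#' WSD = (TW - FW) / (TW - DW), i.e. 1 minus relative water content:
#' 0 for a fully saturated leaf, 1 at oven-dry mass.
#'
#' @param tw Turgid (saturated) mass, g.
#' @param fw Fresh mass at measurement, g.
#' @param dw Oven-dry mass, g. Requires `tw >= fw >= dw > 0` elementwise.
#' @return WSD in \[0, 1\], vectorized over the inputs.
#' @examples
#' compute_wsd(2.0, 1.8, 1.0)  # 0.2
#' @export
compute_wsd <- function(tw, fw, dw) {
  check_numeric(tw, "tw", positive = TRUE)
  check_numeric(fw, "fw", positive = TRUE)
  check_numeric(dw, "dw", positive = TRUE)
  if (any(fw > tw)) stop("mass ordering violated: fresh mass exceeds turgid mass",
                         call. = FALSE)
  if (any(dw > fw)) stop("mass ordering violated: dry mass exceeds fresh mass",
                         call. = FALSE)
  if (any(tw == dw)) stop("degenerate leaf: turgid mass equals dry mass",
                          call. = FALSE)
  (tw - fw) / (tw - dw)
}

# parabola/line intersection WSD nearest the split; NA when no real root
# falls inside [wmin, wmax]
pv_intersection <- function(parab, line, wmin, wmax, w_split) {
  A <- parab[3L]; B <- parab[2L] - line[2L]; C <- parab[1L] - line[1L]
  if (abs(A) < 1e-12) {
    w <- if (abs(B) > 1e-12) -C / B else NA_real_
    roots <- w
  } else {
    disc <- B^2 - 4 * A * C
    if (!is.finite(disc) || disc < 0) return(NA_real_)
    roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  inside <- roots[!is.na(roots) & roots >= wmin & roots <= wmax]
  if (!length(inside)) return(NA_real_)
  inside[which.min(abs(inside - w_split))]
}

quad_coefs <- function(w, y) {
  unname(stats::coef(stats::lm(y ~ w + I(w^2))))
}

line_coefs <- function(w, y) {
  unname(stats::coef(stats::lm(y ~ w)))
}

#' Fit a pressure-volume curve
#'
#' Splits the (WSD, 1/Psi) series into a turgescent (low-WSD) and an
#' osmotic (high-WSD) segment, fits a quadratic to the former and an
#' ordinary least-squares line to the latter, and derives Psi_osat,
#' Psi_TLP and the elasticity index a_ela.
#'
#' The split is chosen by scanning every admissible split index (at least
#' `min_segment` points per segment) and minimizing the summed SSE of the
#' two fits, restricted to splits whose parabola-line system has a real
#' intersection inside the observed WSD range (the physical TLP must
#' exist); ties break toward the smaller turgescent segment. Because a
#' single quadratic cannot track the steep near-saturation branch without
#' distorting the intersection, Psi_TLP is computed from a local "elbow"
#' parabola refitted to the `tlp_window` turgescent points nearest the
#' boundary plus the first osmotic point, so the parabola-line crossing is
#' bracketed by data instead of extrapolated; a_ela is still the
#' |quadratic coefficient| of the full turgescent-segment parabola.
#'
#' @param wsd Water saturation deficits in \[0, 1); sorted internally.
#' @param psi Leaf water potentials, MPa (< 0). Exactly one of `psi` or
#'   `inv_psi` must be given.
#' @param inv_psi Optional reciprocal water potentials 1/Psi, MPa^-1 (< 0).
#' @param min_segment Minimum points per segment (default 3).
#' @param tlp_window Number of boundary-adjacent turgescent points used
#'   for the local TLP parabola (default 4; the first osmotic point is
#'   always added to bracket the crossing).
#' @return Object of class `pv_fit`: `psi_osat`, `psi_tlp`, `a_ela`,
#'   `split_wsd`, `line_slope`, `line_intercept`, `parab_coeffs`,
#'   `n_points`, `sse`, plus the input `data`.
#' @examples
#' leaf <- gen_pv_leaf(psi_osat = -2.56, w_tlp = 0.1381, noise_sd_invpsi = 0)
#' fit_pv(leaf$wsd, leaf$psi_mpa)
#' @export
fit_pv <- function(wsd, psi = NULL, inv_psi = NULL, min_segment = 3L,
                   tlp_window = 4L) {
  check_numeric(wsd, "wsd", nonneg = TRUE)
  if (any(wsd >= 1)) stop("`wsd` must lie in [0, 1)", call. = FALSE)
  if (is.null(inv_psi)) {
    if (is.null(psi)) stop("provide `psi` or `inv_psi`", call. = FALSE)
    check_numeric(psi, "psi", negative = TRUE)
    inv_psi <- 1 / psi
  } else {
    check_numeric(inv_psi, "inv_psi", negative = TRUE)
  }
  if (length(wsd) != length(inv_psi)) {
    stop("`wsd` and water-potential series must have equal length", call. = FALSE)
  }
  ord <- order(wsd)
  wsd <- wsd[ord]; inv_psi <- inv_psi[ord]
  n <- length(wsd)
  if (n < 6L) stop("insufficient data: need at least 6 points", call. = FALSE)
  if (n < 2L * min_segment) {
    stop("insufficient data for `min_segment` = ", min_segment, call. = FALSE)
  }

  best <- NULL
  for (s in seq(min_segment, n - min_segment)) {
    tw_ <- wsd[1:s];        ti <- inv_psi[1:s]
    ow <- wsd[(s + 1L):n];  oi <- inv_psi[(s + 1L):n]
    parab <- quad_coefs(tw_, ti)
    line <- line_coefs(ow, oi)
    sse <- sum((ti - parab[1L] - parab[2L] * tw_ - parab[3L] * tw_^2)^2) +
      sum((oi - line[1L] - line[2L] * ow)^2)
    w_int <- pv_intersection(parab, line, wsd[1L], wsd[n], wsd[s])
    if (is.na(w_int)) next
    # strict "<" keeps the earlier (smaller turgescent segment) split on ties
    if (is.null(best) || sse < best$sse) {
      best <- list(s = s, sse = sse, parab = parab, line = line, w_int = w_int)
    }
  }
  if (is.null(best)) {
    stop("no turgor loss point: parabola and osmotic line do not intersect ",
         "within the observed WSD range (data may be purely osmotic)",
         call. = FALSE)
  }

  s <- best$s
  line <- best$line
  if (line[2L] <= 0) {
    stop("fit failure: osmotic line slope is not positive in (WSD, 1/Psi) space",
         call. = FALSE)
  }
  if (line[1L] >= 0) {
    stop("fit failure: osmotic line intercept must be negative (Psi_osat < 0)",
         call. = FALSE)
  }

  # local elbow parabola (last turgescent points + first osmotic point)
  # brackets the crossing instead of extrapolating into unmodeled curvature
  i0 <- max(1L, s - as.integer(tlp_window) + 1L)
  i1 <- min(n, s + 1L)
  w_tlp_hat <- if (i1 - i0 + 1L >= 3L) {
    pv_intersection(quad_coefs(wsd[i0:i1], inv_psi[i0:i1]), line,
                    wsd[1L], wsd[n], wsd[s])
  } else NA_real_
  if (is.na(w_tlp_hat)) w_tlp_hat <- best$w_int

  psi_osat <- 1 / line[1L]
  psi_tlp <- 1 / (line[1L] + line[2L] * w_tlp_hat)
  if (!is.finite(psi_tlp) || psi_tlp > psi_osat + 1e-9) {
    stop("fit failure: Psi_TLP (", signif(psi_tlp, 4),
         ") less negative than Psi_osat (", signif(psi_osat, 4), ")",
         call. = FALSE)
  }

  structure(
    list(psi_osat = psi_osat,
         psi_tlp = psi_tlp,
         a_ela = abs(best$parab[3L]),
         split_wsd = w_tlp_hat,
         line_slope = line[2L],
         line_intercept = line[1L],
         parab_coeffs = best$parab,
         split_index = s,
         n_points = n,
         sse = best$sse,
         data = data.frame(wsd = wsd, inv_psi = inv_psi)),
    class = "pv_fit"
  )
}

#' @export
print.pv_fit <- function(x, ...) {
  cat("Pressure-volume fit\n")
  cat(sprintf("  Psi_osat = %.3f MPa\n", x$psi_osat))
  cat(sprintf("  Psi_TLP  = %.3f MPa  (at WSD %.3f)\n", x$psi_tlp, x$split_wsd))
  cat(sprintf("  a_ela    = %.3g\n", x$a_ela))
  cat(sprintf("  %d points, split after point %d, SSE %.4g\n",
              x$n_points, x$split_index, x$sse))
  invisible(x)
}

#' Summarize pressure-volume fits across leaves
#'
#' Arithmetic mean and standard error of `psi_osat`, `psi_tlp` and
#' `a_ela` over a list of per-leaf fits (the per-leaf-first averaging used
#' for group summaries).
#'
#' @param results List of [fit_pv()] objects (at least one).
#' @return A data.frame with one row per parameter: `parameter`, `mean`,
#'   `se` (`NA` for a single leaf), `n`.
#' @export
summarize_pv <- function(results) {
  if (!length(results)) stop("empty result list", call. = FALSE)
  if (inherits(results, "pv_fit")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1L), "pv_fit")))
  if (length(results) == 1L) {
    warning("single leaf: SE undefined", call. = FALSE)
  }
  pars <- c("psi_osat", "psi_tlp", "a_ela")
  do.call(rbind, lapply(pars, function(p) {
    v <- vapply(results, `[[`, numeric(1L), p)
    data.frame(parameter = p, mean = mean(v), se = se_of(v), n = length(v))
  }))
}
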