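#' Exponential-sigmoid response model for vulnerability and closure curves
#'
#' Xylem vulnerability curves (percentage loss of hydraulic conductivity,
#' PLC, versus xylem pressure) and stomatal-closure curves (percentage of
#' maximum stomatal conductance versus leaf water potential) are both
#' described by the same two-parameter exponential sigmoid
#' \deqn{y(P) = 100 / \{1 + \exp[a (P - P_{50})]\}}
#' where \eqn{P} is the (negative) water potential in MPa, \eqn{a > 0}
#' (MPa\eqn{^{-1}}) controls the steepness, and \eqn{P_{50}} is the pressure
#' at the 50\% response. Response thresholds such as P12 (onset of embolism
#' or of stomatal closure) and P88 (full embolism / full closure) follow by
#' closed-form inversion.
#'
#' @name sigmoid-model
#' @keywords internal
NULL

new_sigmoid_fit <- function(a, p50, residual_sse, n_points, fitted = NULL,
                            data = NULL, direction = "rising") {
  structure(
    list(a = a, p50 = p50, residual_sse = residual_sse,
         n_points = n_points, fitted = fitted, data = data,
         direction = direction),
    class = "sigmoid_fit"
  )
}

# Accept either a sigmoid_fit or a bare list/vector with a and p50.
# `direction` defaults to "rising" (PLC-like) when absent.
as_sigmoid_pars <- function(fit) {
  if (inherits(fit, "sigmoid_fit")) {
    return(list(a = fit$a, p50 = fit$p50, direction = fit$direction))
  }
  if (is.list(fit) && all(c("a", "p50") %in% names(fit))) {
    dir <- if (is.null(fit$direction)) "rising" else fit$direction
    return(list(a = fit$a, p50 = fit$p50, direction = dir))
  }
  if (is.numeric(fit) && all(c("a", "p50") %in% names(fit))) {
    return(list(a = unname(fit[["a"]]), p50 = unname(fit[["p50"]]),
                direction = "rising"))
  }
  stop("`fit` must be a sigmoid_fit or carry named elements `a` and `p50`",
       call. = FALSE)
}

validate_sigmoid_pars <- function(pars) {
  if (!is.finite(pars$a) || pars$a <= 0) {
    stop("slope parameter `a` must be finite and > 0 (MPa^-1)", call. = FALSE)
  }
  if (!is.finite(pars$p50) || pars$p50 >= 0) {
    stop("`p50` must be finite and < 0 (MPa)", call. = FALSE)
  }
  if (is.null(pars$direction)) pars$direction <- "rising"
  if (!pars$direction %in% c("rising", "falling")) {
    stop("`direction` must be \"rising\" or \"falling\"", call. = FALSE)
  }
  pars
}

#' Evaluate the sigmoid response at given pressures
#'
#' @param fit A [fit_sigmoid()] result, or any list/named vector with
#'   elements `a` (MPa^-1, > 0) and `p50` (MPa, < 0).
#' @param pressure Numeric vector of water potentials (MPa, finite).
#' @return Percent response in (0, 100), same length as `pressure`. For a
#'   `"rising"` fit (PLC-like, the default) the response is strictly
#'   decreasing in `pressure`, i.e. increases as pressure becomes more
#'   negative; a `"falling"` fit (percent stomatal conductance) is the
#'   mirror image.
#' @examples
#' percent_at(list(a = 0.95, p50 = -5), c(-5, -2.9, 0))
#' @seealso [pressure_at_percent()], [fit_sigmoid()], [thresholds_of()]
#' @export
percent_at <- function(fit, pressure) {
  pars <- validate_sigmoid_pars(as_sigmoid_pars(fit))
  check_numeric(pressure, "pressure")
  y <- 100 / (1 + exp(pars$a * (pressure - pars$p50)))
  if (pars$direction == "falling") 100 - y else y
}

#' Invert the sigmoid: pressure at a given percent response
#'
#' Closed-form inversion \eqn{P = P_{50} + \ln(100/y - 1)/a}. The standard
#' thresholds are `level = 12` (onset) and `level = 88` (full response).
#'
#' @inheritParams percent_at
#' @param level Percent response, strictly inside (0, 100).
#' @return Pressure (MPa) at which the model reaches `level`.
#' @examples
#' pressure_at_percent(list(a = 0.95, p50 = -5), 12)  # P12
#' @export
pressure_at_percent <- function(fit, level) {
  pars <- validate_sigmoid_pars(as_sigmoid_pars(fit))
  check_numeric(level, "level")
  if (any(level <= 0 | level >= 100)) {
    stop("`level` must lie strictly inside (0, 100) percent", call. = FALSE)
  }
  if (pars$direction == "falling") level <- 100 - level
  pars$p50 + log(100 / level - 1) / pars$a
}

sigmoid_sse <- function(a, p50, pressure, percent) {
  sum((percent - 100 / (1 + exp(a * (pressure - p50))))^2)
}

# One optimizer run from a given start; a kept positive via log transform.
# nlminb on the log-a scale is robust including on zero-residual data.
sigmoid_optimize <- function(pressure, percent, start) {
  obj <- function(par) sigmoid_sse(exp(par[1L]), par[2L], pressure, percent)
  res <- stats::nlminb(c(log(start[1L]), start[2L]), obj,
                       control = list(rel.tol = 1e-14, abs.tol = 0,
                                      iter.max = 500L, eval.max = 1000L))
  list(a = exp(res$par[1L]), p50 = res$par[2L], sse = res$objective,
       convergence = res$convergence)
}

#' Fit the exponential sigmoid to a (pressure, percent) series
#'
#' Unweighted nonlinear least squares for the two-parameter sigmoid.
#' Default initialization is `a = 1` MPa^-1 and `p50` at the pressure of
#' the point whose percent lies closest to 50. If the first optimization
#' does not converge, three perturbed restarts are tried and the
#' lowest-SSE solution kept; a still-failing fit raises an error.
#'
#' Noisy percents outside \[0, 100\] are retained unclipped (clipping
#' would bias the slope). Fits are refused as non-identifiable when the
#' percent range is below 30 percent-units, when all percents lie strictly
#' on one side of 50\%, or when all pressures coincide.
#'
#' @param pressure Water potentials, MPa (finite, \eqn{\le 0}); at least 3
#'   points. Positive pressures are rejected unless `auto_negate = TRUE`.
#' @param percent Response percentages (finite; may exceed \[0, 100\] due
#'   to noise).
#' @param init Optional length-2 numeric `c(a, p50)` start values.
#' @param auto_negate If `TRUE`, positive pressures are negated (for data
#'   recorded as tensions).
#' @param direction `"rising"` for responses that grow toward 100\% as
#'   pressure becomes more negative (PLC), `"falling"` for responses that
#'   decline (percent stomatal conductance), or `"auto"` (default) to
#'   choose by the sign of the pressure-percent correlation. A falling
#'   series is fitted as the mirrored logistic, keeping `a > 0`;
#'   [percent_at()] and [pressure_at_percent()] respect the stored
#'   orientation, so `pressure_at_percent(fit, 12)` is the water potential
#'   at 12\% conductance (full closure) for a falling fit.
#' @return An object of class `sigmoid_fit`: list with `a`, `p50`,
#'   `residual_sse`, `n_points`, `fitted`, `data`, `direction`.
#' @examples
#' p <- seq(-1, -8, by = -1)
#' y <- percent_at(list(a = 0.95, p50 = -5), p)
#' fit_sigmoid(p, y)
#' @export
fit_sigmoid <- function(pressure, percent, init = NULL, auto_negate = FALSE,
                        direction = c("auto", "rising", "falling")) {
  direction <- match.arg(direction)
  check_numeric(pressure, "pressure")
  check_numeric(percent, "percent")
  if (length(pressure) != length(percent)) {
    stop("`pressure` and `percent` must have equal length", call. = FALSE)
  }
  if (auto_negate) pressure <- -abs(pressure)
  check_numeric(pressure, "pressure", nonpos = TRUE)
  n <- length(pressure)
  if (n < 3L) {
    stop("insufficient data: need at least 3 (pressure, percent) points",
         call. = FALSE)
  }
  if (diff(range(pressure)) == 0) {
    stop("non-identifiable: zero pressure spread", call. = FALSE)
  }
  if (diff(range(percent)) < 30) {
    stop("non-identifiable: percent range below 30 percent-units",
         call. = FALSE)
  }
  if (all(percent < 50) || all(percent > 50)) {
    stop("non-identifiable: all percents on one side of the 50% level",
         call. = FALSE)
  }

  if (direction == "auto") {
    direction <- if (stats::cor(pressure, percent) <= 0) "rising" else "falling"
  }
  if (direction == "falling") percent <- 100 - percent

  if (is.null(init)) {
    init <- c(1, pressure[which.min(abs(percent - 50))])
  } else {
    if (length(init) != 2L || !all(is.finite(init)) || init[1L] <= 0) {
      stop("`init` must be c(a > 0, p50)", call. = FALSE)
    }
  }

  best <- sigmoid_optimize(pressure, percent, init)
  if (best$convergence != 0L) {
    # retry from perturbed starts, keep lowest SSE (deterministic offsets)
    for (f in list(c(2, 0.5), c(0.5, -0.5), c(1, 1))) {
      cand <- try(sigmoid_optimize(pressure, percent,
                                   c(init[1L] * f[1L], init[2L] + f[2L])),
                  silent = TRUE)
      if (!inherits(cand, "try-error") &&
          (cand$sse < best$sse || best$convergence != 0L)) {
        best <- cand
      }
    }
  }
  if (!is.finite(best$sse) || !is.finite(best$a) || !is.finite(best$p50)) {
    stop("sigmoid fit failed to converge to a finite solution", call. = FALSE)
  }
  if (best$p50 >= 0) {
    stop("sigmoid fit produced non-negative p50 (", signif(best$p50, 4),
         " MPa); data do not describe a response to negative pressure",
         call. = FALSE)
  }
  pars <- list(a = best$a, p50 = best$p50, direction = direction)
  if (direction == "falling") percent <- 100 - percent  # restore original
  new_sigmoid_fit(best$a, best$p50,
                  residual_sse = best$sse, n_points = n,
                  fitted = percent_at(pars, pressure),
                  data = data.frame(pressure_mpa = pressure, percent = percent),
                  direction = direction)
}

#' Response thresholds of a fitted sigmoid
#'
#' P12 (onset), P50 and P88 (full response) via closed-form inversion.
#' The logistic is symmetric, so `p12 - p50 == p50 - p88 == log(22/3)/a`.
#'
#' @inheritParams percent_at
#' @return List with `p12`, `p50`, `p88` (MPa, ordered least to most
#'   negative).
#' @examples
#' thresholds_of(list(a = 0.92, p50 = -4.29))
#' @export
thresholds_of <- function(fit) {
  pars <- validate_sigmoid_pars(as_sigmoid_pars(fit))
  list(p12 = pressure_at_percent(pars, 12),
       p50 = pars$p50,
       p88 = pressure_at_percent(pars, 88))
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  th <- thresholds_of(x)
  cat("Exponential-sigmoid response fit\n")
  cat(sprintf("  a    = %.4f MPa^-1\n", x$a))
  cat(sprintf("  P50  = %.3f MPa   (P12 = %.3f, P88 = %.3f)\n",
              th$p50, th$p12, th$p88))
  cat(sprintf("  SSE  = %.4g on %d points\n", x$residual_sse, x$n_points))
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) {
  c(a = object$a, p50 = object$p50)
}

#' @export
predict.sigmoid_fit <- function(object, pressure = NULL, ...) {
  if (is.null(pressure)) return(object$fitted)
  percent_at(object, pressure)
}
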