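# Internal helpers shared across modules.

#' Standard error of the mean
#'
#' @param x Numeric vector; `NA` values are dropped.
#' @return `sd(x)/sqrt(n)`, or `NA_real_` when fewer than two values remain.
#' @keywords internal
se_of <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("`seed` must be a single finite number", call. = FALSE)
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Validate a numeric vector: finite, optional sign constraints. `what` names
# the argument in error messages.
check_numeric <- function(x, what, finite = TRUE, positive = FALSE,
                          nonneg = FALSE, nonpos = FALSE, negative = FALSE,
                          allow_empty = FALSE) {
  if (!is.numeric(x)) stop("`", what, "` must be numeric", call. = FALSE)
  if (!allow_empty && length(x) == 0L) {
    stop("`", what, "` is empty", call. = FALSE)
  }
  if (finite && any(!is.finite(x))) {
    stop("`", what, "` contains non-finite values", call. = FALSE)
  }
  if (positive && any(x <= 0)) {
    stop("`", what, "` must be strictly positive", call. = FALSE)
  }
  if (nonneg && any(x < 0)) {
    stop("`", what, "` must be non-negative", call. = FALSE)
  }
  if (nonpos && any(x > 0)) {
    stop("`", what, "` must be non-positive (pressures are negative MPa); ",
         "pass `auto_negate = TRUE` where supported to flip sign-inverted input",
         call. = FALSE)
  }
  if (negative && any(x >= 0)) {
    stop("`", what, "` must be strictly negative (MPa)", call. = FALSE)
  }
  invisible(x)
}

# mean +/- SE summary used by several aggregation helpers
mean_se <- function(x, warn_single = NULL) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no values to summarize", call. = FALSE)
  if (length(x) == 1L && !is.null(warn_single)) warning(warn_single, call. = FALSE)
  list(mean = mean(x), se = se_of(x), n = length(x))
}
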