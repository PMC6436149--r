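# Assumption-gated two-sample testing: normality (one-sample KS against a
# normal with the sample's moments) and homogeneity of variance (Levene)
# checks decide between the pooled Student t-test and Welch's test.

# Levene's test with centering at the group means (the SPSS default):
# one-way ANOVA F-test on absolute deviations.
levene_test <- function(a, b) {
  z <- c(abs(a - mean(a)), abs(b - mean(b)))
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  if (stats::var(z) == 0) return(1)  # identical spread, nothing to test
  stats::anova(stats::lm(z ~ g))[["Pr(>F)"]][1L]
}

ks_normality <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)  # degenerate; flagged upstream
  suppressWarnings(stats::ks.test(x, "pnorm", mean(x), s)$p.value)
}

#' Gated two-sample comparison (Student vs Welch)
#'
#' Runs a one-sample Kolmogorov-Smirnov normality check per group
#' (against a normal with the sample's own moments; a Lilliefors-style
#' approximation) and Levene's test for equal variances (absolute
#' deviations from group means). If Levene rejects at `alpha`, the
#' unequal-variance Welch test is used; otherwise the pooled-variance
#' Student t-test. The gate decides the test; it is never chosen post
#' hoc. Normality failure does not switch to a non-parametric test; it is
#' recorded (and warned about) only.
#'
#' @param a,b Numeric samples, each with at least 3 values.
#' @param alpha Significance level for the gate and the final decision
#'   (default 0.05).
#' @return Object of class `gate_report`: `normality_p` (length-2),
#'   `variance_p`, `chosen_test` (`"pooled"` or `"welch"`), `statistic`,
#'   `df`, `test_p`, `significant`, `alpha`, `n` (length-2). When both
#'   groups have zero variance and equal means, `test_p = 1` by
#'   convention; zero variance with different means gives `test_p = 0`.
#' @examples
#' set.seed(1)
#' gated_two_sample_test(rnorm(20), rnorm(20, 5))
#' @export
gated_two_sample_test <- function(a, b, alpha = 0.05) {
  check_numeric(a, "a")
  check_numeric(b, "b")
  if (length(a) < 3L || length(b) < 3L) {
    stop("insufficient data: each group needs at least 3 values", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }

  norm_p <- c(ks_normality(a), ks_normality(b))
  if (any(!is.na(norm_p) & norm_p < alpha)) {
    warning("Kolmogorov-Smirnov normality check failed in at least one group; ",
            "t-based test applied regardless (no non-parametric fallback)",
            call. = FALSE)
  }

  if (stats::var(a) == 0 && stats::var(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    rep <- list(normality_p = norm_p, variance_p = 1,
                chosen_test = "pooled", statistic = NA_real_, df = NA_real_,
                test_p = if (equal) 1 else 0,
                significant = !equal, alpha = alpha,
                n = c(length(a), length(b)))
    return(structure(rep, class = "gate_report"))
  }

  var_p <- levene_test(a, b)
  chosen <- if (var_p < alpha) "welch" else "pooled"
  tt <- stats::t.test(a, b, var.equal = (chosen == "pooled"))
  structure(
    list(normality_p = norm_p, variance_p = var_p, chosen_test = chosen,
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         test_p = tt$p.value, significant = tt$p.value < alpha,
         alpha = alpha, n = c(length(a), length(b))),
    class = "gate_report"
  )
}

#' @export
print.gate_report <- function(x, ...) {
  cat("Gated two-sample comparison\n")
  cat(sprintf("  n = %d vs %d\n", x$n[1L], x$n[2L]))
  cat(sprintf("  KS normality p: %.3g / %.3g;  Levene p: %.3g\n",
              x$normality_p[1L], x$normality_p[2L], x$variance_p))
  cat(sprintf("  chosen test: %s t-test\n",
              if (x$chosen_test == "welch") "Welch (unequal-variance)"
              else "Student (pooled-variance)"))
  cat(sprintf("  p = %.4g %s (alpha = %.2f)\n", x$test_p,
              if (isTRUE(x$significant)) "*" else "", x$alpha))
  invisible(x)
}
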