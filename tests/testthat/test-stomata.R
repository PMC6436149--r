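# Stomatal operating traits: normalization, extremes, margins, sequencing.

test_that("percent_gs normalizes by the series maximum", {
  out <- percent_gs(c(-0.5, -2, -4), c(600, 300, 60))
  expect_equal(out$percent, c(100, 50, 10))
  expect_equal(out$pressure_mpa, c(-0.5, -2, -4))
  expect_equal(percent_gs(-1, 250)$percent, 100)
  expect_error(percent_gs(c(-1, -2), c(0, 0)), "zero")
  # exactly one 100% point, everything in [0, 100]
  set.seed(21)
  for (i in 1:10) {
    gs <- runif(15, 0, 600)
    out <- percent_gs(-runif(15, 0.1, 5), gs)
    expect_equal(sum(out$percent == 100), 1L)
    expect_true(all(out$percent >= 0 & out$percent <= 100))
  }
})

test_that("closure thresholds come from the shared sigmoid", {
  psi <- seq(-0.5, -6, by = -0.5)
  # conductance declines sigmoidally: mirrored logistic, midpoint -3.5
  gs_true <- 600 * (1 - 1 / (1 + exp(1.2 * (psi - (-3.5)))))
  out <- percent_gs(psi, gs_true)
  fit <- fit_sigmoid(out$pressure_mpa, out$percent)
  expect_equal(fit$direction, "falling")
  psi_sc <- pressure_at_percent(fit, 12)   # 12% gs = full closure
  onset <- pressure_at_percent(fit, 88)    # 88% gs = onset of closure
  expect_lt(psi_sc, fit$p50)   # closure beyond the midpoint
  expect_gt(onset, fit$p50)
  # normalization rescales by gs at the least negative psi, not the
  # asymptote, so recovery is close but not exact
  expect_equal(fit$p50, -3.5, tolerance = 0.05)
  # the fitted curve reproduces the normalized data
  expect_equal(percent_at(fit, out$pressure_mpa), fit$fitted, tolerance = 1e-9)
})

test_that("extreme_mean averages the n most extreme values", {
  expect_equal(extreme_mean(1:10, 8, "highest"), 6.5)
  expect_warning(m <- extreme_mean(c(-2.0, -2.5, -3.0), 8, "lowest"),
                 "fewer")
  expect_equal(m, -2.5)
  expect_equal(extreme_mean(rep(7, 12), 8, "highest"), 7)
  expect_equal(extreme_mean(c(5, 1, 9, 3), 2, "lowest"), 2)
  expect_error(extreme_mean(numeric(0), 8), "empty")
})

test_that("pool_gsmax pools campaign extremes in both modes", {
  c1 <- c(600, 590, 10, 20)
  c2 <- c(400, 390, 380, 370)
  expect_equal(pool_gsmax(list(c1, c2), n = 2),
               mean(c(600, 590, 400, 390)))
  expect_equal(pool_gsmax(list(c1, c2), n = 2, mode = "pooled"),
               mean(c(600, 590)))
  expect_error(pool_gsmax(list()), "non-empty")
})

test_that("safety_margin is the signed threshold difference", {
  expect_equal(safety_margin(-3.75, -2.90), -0.85)  # closure after onset
  expect_equal(safety_margin(-2.5, -2.5), 0)
  expect_equal(safety_margin(-4.41, -3.65), -0.76)
  # antisymmetry
  expect_equal(safety_margin(-1.2, -3.4), -safety_margin(-3.4, -1.2))
  expect_error(safety_margin(1, -2), "negative")
})

test_that("sequence_thresholds orders least to most negative, stably", {
  seqd <- sequence_thresholds(c(P12 = -2.90, Psi_TLP = -2.97,
                                Psi_sc = -3.75, P50 = -5.00))
  expect_equal(seqd$name, c("P12", "Psi_TLP", "Psi_sc", "P50"))
  tied <- sequence_thresholds(c(first = -2, second = -2))
  expect_equal(tied$name, c("first", "second"))
  single <- sequence_thresholds(c(only = -3))
  expect_equal(single$value, -3)
  expect_error(sequence_thresholds(c(-1, -2)), "named")
})

test_that("stomatal anatomy summarizes density and pore length per leaf", {
  expect_equal(stomatal_density(53, 0.2), 265)
  s <- stomatal_anatomy_summary(
    density_leaf = c("L1", "L2"), count = c(52, 54), area_mm2 = c(0.2, 0.2),
    pore_leaf = rep(c("L1", "L2"), each = 3),
    pore_length_um = c(15, 15.5, 14.5, 17, 18, 17.5))
  expect_equal(s$sd$mean, 265)
  expect_equal(s$sd$se, 5)
  expect_equal(s$pore_length$mean, mean(c(15, 17.5)))
  expect_error(stomatal_density(50, 0), "positive")
  expect_error(suppressWarnings(
    stomatal_anatomy_summary("L1", 50, 0.2, pore_length_um = 15)),
    "pore_leaf")
})

test_that("closure pipeline recovers Psi_sc from noisy gs courses", {
  # true closure curve: mirrored sigmoid, a = 1.2, midpoint -3.5;
  # Psi_sc (12% gs) = -3.5 - log(22/3)/1.2
  psi <- seq(-0.5, -6.5, by = -0.5)
  truth_sc <- -3.5 - log(22 / 3) / 1.2
  errs <- vapply(1:200, function(i) {
    d <- gen_vulnerability(1.2, -3.5, pressures = psi, noise_sd = 5,
                           seed = 3000 + i)
    gs_pct <- 100 - d$percent   # falling orientation
    fit <- tryCatch(fit_sigmoid(d$pressure_mpa, gs_pct, direction = "falling"),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    abs(pressure_at_percent(fit, 12) - truth_sc)
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.2)
})
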