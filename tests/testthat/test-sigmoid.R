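# Exponential-sigmoid model: evaluation, inversion, fitting, thresholds.

test_that("percent_at evaluates the sigmoid correctly", {
  fit <- list(a = 0.95, p50 = -5.00)
  expect_equal(percent_at(fit, -5.00), 50.0)
  # consistency with the published Golden-control P12 around -2.90 MPa
  expect_equal(percent_at(fit, -2.90), 12, tolerance = 0.2 / 12)
  # 100/(1 + e^{4.75})
  expect_equal(percent_at(fit, 0), 100 / (1 + exp(4.75)))
  expect_equal(percent_at(fit, 0), 0.857, tolerance = 1e-3)
})

test_that("percent_at is strictly decreasing and bounded in (0, 100)", {
  for (pars in list(list(a = 0.3, p50 = -7), list(a = 1.2, p50 = -3.5),
                    list(a = 3, p50 = -1.5))) {
    p <- seq(-10, 0, by = 0.25)
    y <- percent_at(pars, p)
    expect_true(all(diff(y) < 0))
    expect_true(all(y > 0 & y < 100))
  }
})

test_that("percent_at rejects invalid input", {
  expect_error(percent_at(list(a = -1, p50 = -5), -2), "a")
  expect_error(percent_at(list(a = 1, p50 = 5), -2), "p50")
  expect_error(percent_at(list(a = 1, p50 = -5), NA_real_), "non-finite")
})

test_that("pressure_at_percent inverts the model", {
  expect_equal(pressure_at_percent(list(a = 0.95, p50 = -5.00), 50), -5.00)
  # published threshold checks (printed inputs, +/- 0.01 printed rounding)
  expect_equal(pressure_at_percent(list(a = 0.80, p50 = -3.65), 12), -1.16,
               tolerance = 0.01 / 1.16)
  expect_equal(pressure_at_percent(list(a = 1.04, p50 = -4.77), 88), -6.69,
               tolerance = 0.01 / 6.69)
  expect_error(pressure_at_percent(list(a = 1, p50 = -5), 0), "level")
  expect_error(pressure_at_percent(list(a = 1, p50 = -5), 100), "level")
})

test_that("inversion round-trips through the model to 1e-9", {
  pars <- list(a = 1.3, p50 = -4.1)
  for (p in seq(-8, -0.5, by = 0.5)) {
    expect_equal(pressure_at_percent(pars, percent_at(pars, p)), p,
                 tolerance = 1e-9)
  }
})

test_that("fit_sigmoid recovers noiseless parameters to 1e-6 relative", {
  p <- seq(-1, -8, by = -1)
  fit <- fit_sigmoid(p, percent_at(list(a = 0.95, p50 = -5.00), p))
  expect_s3_class(fit, "sigmoid_fit")
  expect_equal(fit$a, 0.95, tolerance = 1e-6)
  expect_equal(fit$p50, -5.00, tolerance = 1e-6)
  # property over the parameter box
  for (a in c(0.3, 1.1, 3)) {
    for (p50 in c(-8, -4.5, -1)) {
      pr <- seq(p50 - 4, min(p50 + 4, -1e-3), length.out = 9L)
      f <- fit_sigmoid(pr, percent_at(list(a = a, p50 = p50), pr))
      expect_equal(f$a, a, tolerance = 1e-6)
      expect_equal(f$p50, p50, tolerance = 1e-6)
    }
  }
})

test_that("three symmetric points force the closed-form solution", {
  fit <- fit_sigmoid(c(-2, -3, -4), c(12, 50, 88))
  expect_equal(fit$a, log(100 / 12 - 1), tolerance = 1e-4)  # 1.9924
  expect_equal(fit$p50, -3.00, tolerance = 1e-6)
})

test_that("fit_sigmoid refuses degenerate or non-identifiable input", {
  expect_error(fit_sigmoid(c(-1, -2), c(10, 90)), "insufficient")
  expect_error(fit_sigmoid(c(-1, -2, -3, -4), rep(50, 4)),
               "non-identifiable")
  expect_error(fit_sigmoid(rep(-3, 5), c(10, 30, 50, 70, 90)),
               "zero pressure spread")
  expect_error(fit_sigmoid(c(-1, -2, -3, -4), c(55, 60, 70, 90)),
               "one side")
  expect_error(fit_sigmoid(c(1, 2, 3, 4), c(10, 40, 60, 90)), "negative MPa")
  # auto_negate accepts sign-inverted pressures
  f <- fit_sigmoid(c(1, 2, 3, 4, 5, 6, 7, 8),
                   percent_at(list(a = 1, p50 = -4), -(1:8)),
                   auto_negate = TRUE)
  expect_equal(f$p50, -4, tolerance = 1e-6)
})

test_that("fit_sigmoid agrees with exhaustive grid search on small instances", {
  set.seed(401)
  for (i in 1:3) {
    a <- runif(1, 0.5, 2); p50 <- runif(1, -6, -2)
    pr <- seq(-8, -0.5, length.out = 10L)
    y <- percent_at(list(a = a, p50 = p50), pr) + rnorm(10, 0, 4)
    if (diff(range(y)) < 30 || all(y < 50) || all(y > 50)) next
    fit <- fit_sigmoid(pr, y)
    oracle <- grid_search_sigmoid(pr, y)
    grid_res_a <- (3 - 0.2) / 120
    grid_res_p <- (8 - 1) / 120
    expect_lte(fit$residual_sse, oracle$sse + 1e-9)
    expect_lt(abs(fit$a - oracle$a), grid_res_a)
    expect_lt(abs(fit$p50 - oracle$p50), grid_res_p)
  }
})

test_that("thresholds_of matches published and closed-form values", {
  th <- thresholds_of(list(a = 0.92, p50 = -4.29))  # Red fertilized
  expect_equal(th$p12, -2.12, tolerance = 0.01 / 2.12)
  expect_equal(th$p88, -6.46, tolerance = 0.01 / 6.46)
  th2 <- thresholds_of(list(a = 2, p50 = -3))
  expect_equal(th2$p12, -3 + log(22 / 3) / 2)
  expect_equal(round(th2$p12, 3), -2.004)
  expect_equal(round(th2$p88, 3), -3.996)
})

test_that("thresholds are symmetric about p50", {
  set.seed(7)
  for (i in 1:20) {
    pars <- list(a = runif(1, 0.3, 3), p50 = runif(1, -8, -1))
    th <- thresholds_of(pars)
    expect_equal(th$p12 - th$p50, th$p50 - th$p88, tolerance = 1e-12)
    expect_equal(th$p12 - th$p50, log(22 / 3) / pars$a, tolerance = 1e-12)
    expect_true(th$p12 > th$p50 && th$p50 > th$p88)
  }
})

test_that("sigmoid_fit methods work", {
  p <- seq(-1, -8, by = -1)
  fit <- fit_sigmoid(p, percent_at(list(a = 1, p50 = -4), p))
  expect_named(coef(fit), c("a", "p50"))
  expect_equal(predict(fit), fit$fitted)
  expect_equal(predict(fit, -4), 50, tolerance = 1e-6)
  expect_output(print(fit), "P50")
})
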