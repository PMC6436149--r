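# Synthetic-data generators: determinism, model conformity, reader
# round-trips.

test_that("generators are pure functions of their seed", {
  expect_identical(gen_vulnerability(0.95, -5, seed = 11),
                   gen_vulnerability(0.95, -5, seed = 11))
  expect_identical(gen_pv_leaf(-2.5, 0.15, seed = 11),
                   gen_pv_leaf(-2.5, 0.15, seed = 11))
  expect_identical(gen_conduits(seed = 11), gen_conduits(seed = 11))
  expect_identical(gen_diurnal(seed = 11, noise_gs = 20, noise_psi = 0.1),
                   gen_diurnal(seed = 11, noise_gs = 20, noise_psi = 0.1))
  # different seeds differ
  expect_false(identical(gen_conduits(seed = 1), gen_conduits(seed = 2)))
  # the caller's RNG stream is not consumed
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(gen_conduits(seed = 5)); after <- runif(1)
  expect_identical(before, after)
})

test_that("noiseless vulnerability series lies exactly on the model", {
  d <- gen_vulnerability(0.95, -5.00, noise_sd = 0)
  expect_equal(d$percent, percent_at(list(a = 0.95, p50 = -5), d$pressure_mpa))
  # consistency with the published Golden-control P12
  d2 <- gen_vulnerability(0.95, -5.00, pressures = -2.90, noise_sd = 0)
  expect_equal(d2$percent, 12, tolerance = 0.2 / 12)
  expect_error(gen_vulnerability(-1, -5), "a")
})

test_that("raw-k mode emits conductances consistent with PLC", {
  d <- gen_vulnerability(1, -4, k0 = 5, noise_sd = 0)
  expect_equal(d$k, 5 * (1 - d$percent / 100))
  dn <- gen_vulnerability(1, -4, k0 = 5, k_noise_cv = 0.05, seed = 2)
  expect_true(all(dn$k >= 0))
  expect_false(identical(dn$k, 5 * (1 - dn$percent / 100)))
})

test_that("PV generator matches its analytic model", {
  expect_equal(pv_model_psi(0.10, -2.0, 0.10), -2.0 / 0.9)
  expect_equal(pv_model_psi(0.1381, -2.56, 0.1381), -2.56 / (1 - 0.1381))
  # just past the TLP the noiseless curve sits exactly on the osmotic line
  w <- 0.20
  leaf <- gen_pv_leaf(-2.0, 0.10, wsd_schedule = w, noise_sd_invpsi = 0)
  expect_equal(leaf$inv_psi, (1 - w) / -2.0)
  # continuity at the TLP
  eps <- 1e-9
  expect_equal(pv_model_psi(0.15 - eps, -2.5, 0.15),
               pv_model_psi(0.15 + eps, -2.5, 0.15), tolerance = 1e-6)
  expect_error(gen_pv_leaf(-2.5, 0.15, wsd_schedule = c(0.5, 0.95)), "0.9")
})

test_that("conduit generator produces the stated populations", {
  expect_equal(gen_conduits(median_um = 18, sigma_log = 0, n = 10),
               rep(18, 10))
  d0 <- gen_conduits(median_um = 18, sigma_log = 0, n = 10)
  expect_equal(hydraulic_diameter(d0), mean(d0))
  # widening the distribution raises E[d_h - d_mean]
  gap <- function(sig) {
    d <- gen_conduits(20, sig, n = 5000, seed = 42)
    hydraulic_diameter(d) - mean(d)
  }
  expect_gt(gap(0.4), gap(0.2))
  expect_gt(gap(0.2), gap(0.05))
  expect_error(gen_conduits(n = 0), "positive")
})

test_that("diurnal generator hits its extremes noiselessly", {
  d <- gen_diurnal(gs_max_true = 500, psi_min_true = -2.7)
  expect_equal(max(d$gs_mmol), 500)
  expect_equal(min(d$psi_mpa), -2.7)
  expect_equal(extreme_mean(d$gs_mmol, 8, "highest"), 500,
               tolerance = 0.02)
  expect_lt(extreme_mean(d$psi_mpa, 8, "lowest"), -2.5)
  expect_error(gen_diurnal(psi_min_true = -0.1), "psi_predawn")
})

test_that("generator output passes the readers' validation unchanged", {
  tmp <- withr::local_tempdir()
  f1 <- file.path(tmp, "vc.csv")
  write_traits_csv(gen_vulnerability(1, -4, seed = 1), f1)
  expect_silent(read_response_csv(f1))
  f2 <- file.path(tmp, "pv.csv")
  write_traits_csv(gen_pv_leaf(-2.5, 0.15, seed = 1), f2)
  expect_silent(read_pv_csv(f2))
  f3 <- file.path(tmp, "flow.csv")
  kd <- gen_vulnerability(1, -4, k0 = 3, seed = 1)
  write_traits_csv(kd[, c("pressure_mpa", "k")], f3)
  expect_silent(read_flow_csv(f3))
  f4 <- file.path(tmp, "gas.csv")
  dd <- gen_diurnal(seed = 1)
  write_traits_csv(data.frame(tree_id = 1, time = dd$time,
                              gs_mmol = dd$gs_mmol, psi_mpa = dd$psi_mpa), f4)
  expect_silent(read_gas_exchange_csv(f4))
})
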