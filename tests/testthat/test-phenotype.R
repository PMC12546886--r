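# Virtual seed lab: kinetics, vigor, SVI, dose-response, batch simulation.

test_that("germination_curve follows the logistic kinetics", {
  kin <- germination_kinetics(G_max = 95, k = 0.5, t50 = 5)
  expect_equal(germination_curve(kin, 5), 95 / 2)
  expect_equal(germination_curve(kin, 5 + 30 / 0.5), 95, tolerance = 1e-6)
  expect_equal(germination_curve(kin, 7), 95 / (1 + exp(-1)))
  t <- seq(0, 14, by = 0.1)
  expect_true(all(diff(germination_curve(kin, t)) >= 0))
  expect_error(germination_curve(kin, -1), "t must")
})

test_that("vigor_index and composite_svi arithmetic", {
  expect_equal(vigor_index(100, 10), 10)
  expect_equal(vigor_index(0, 55), 0)
  expect_equal(vigor_index(82.4, 9.25), 82.4 * 9.25 / 100)
  w <- svi_weights(weights = c(a = 0.5, b = 0.5), X_min = c(a = 0, b = 0),
                   X_max = c(a = 1, b = 1))
  expect_equal(composite_svi(c(a = 1, b = 0.5), w), 0.75)
  expect_equal(composite_svi(c(a = 1, b = 1), w), 1)
  expect_equal(composite_svi(c(a = 0, b = 0), w), 0)
  expect_error(composite_svi(c(a = 2, b = 0), w, clip = FALSE), "bounds")
  expect_equal(composite_svi(c(a = 2, b = 0), w, clip = TRUE), 0.5)
})

test_that("feature normalization is an exact affine round-trip", {
  norm <- feature_normalizer(mu = 3, sigma = 2, w = 0.7, b = -1)
  expect_equal(normalize_feature(3, norm), -1)
  z <- feature_normalizer(mu = 5, sigma = 4)
  expect_equal(normalize_feature(9, z), 1)
  x <- rnorm(100, 3, 5)
  expect_equal(denormalize_feature(normalize_feature(x, norm), norm), x)
})

test_that("effective_dose couples energy and resonance", {
  v <- default_varieties()
  p1 <- v[[1]]
  mech <- profile_mechanics(p1)
  prot <- calibration_protocol(p1)
  expect_equal(effective_dose(prot, p1), total_energy(prot, mech))
  zero <- treatment_protocol(0, 300, 120, check = FALSE)
  expect_equal(effective_dose(zero, p1), 0)
  # strictly increasing in duration
  doses <- vapply(seq(30, 300, by = 30), function(d) {
    effective_dose(treatment_protocol(2.5, 200, d), p1)
  }, 0)
  expect_true(all(diff(doses) > 0))
  # off-resonance frequencies deliver strictly less dose
  d_res <- effective_dose(treatment_protocol(2.5, p1$f_n, 120), p1)
  d_off <- effective_dose(treatment_protocol(2.5, 1000, 120), p1)
  expect_lt(d_off, d_res)
})

test_that("dose_response is a unimodal hormesis curve peaking at d_opt", {
  v <- default_varieties()
  for (p in v) {
    dr <- dose_response(p$d_opt, p)
    expect_equal(dr$delta_g, p$delta_g_max)
    expect_equal(dr$delta_vi, p$delta_vi_max)
    expect_equal(dose_response(0, p)$delta_g, 0)
    # derivative changes sign exactly once on (0, 10 d_opt)
    d <- seq(1e-6, 10 * p$d_opt, length.out = 4000)
    slope_sign <- sign(diff(dose_response(d, p)$delta_g))
    changes <- sum(diff(slope_sign[slope_sign != 0]) != 0)
    expect_equal(changes, 1)
  }
  p1 <- v[[1]]
  p1$gamma <- 1
  expect_equal(dose_response(2 * p1$d_opt, p1)$delta_g,
               p1$delta_g_max * 2 * exp(-1))
})

test_that("simulate_batch recovers control means and is reproducible", {
  v <- default_varieties()
  p <- v[[1]]
  p$dispersion[] <- 0
  sim <- simulate_batch(p, NULL, n_seeds = 4000, n_replicates = 3,
                        rng_seed = 9)
  se <- sqrt(82.4 * (100 - 82.4) / (3 * 4000))
  expect_lt(abs(sim$summary[["germination_pct"]] - 82.4), 3 * se)
  # determinism
  sim2 <- simulate_batch(p, NULL, n_seeds = 200, n_replicates = 3,
                         rng_seed = 5)
  sim3 <- simulate_batch(p, NULL, n_seeds = 200, n_replicates = 3,
                         rng_seed = 5)
  expect_identical(sim2$records, sim3$records)
  expect_error(simulate_batch(p, NULL, n_seeds = 0), "empty batch")
})

test_that("a null treatment is statistically indistinguishable from control", {
  v <- default_varieties()
  p <- v[[2]]
  p$delta_g_max <- 0; p$delta_vi_max <- 0
  prot <- calibration_protocol(p)
  trt <- simulate_batch(p, prot, n_seeds = 100, n_replicates = 3,
                        rng_seed = 21)
  ctl <- simulate_batch(p, NULL, n_seeds = 100, n_replicates = 3,
                        rng_seed = 22)
  tst <- t.test(trt$records$germinated, ctl$records$germinated)
  expect_gt(tst$p.value, 0.01)
})

test_that("germination-day ECDF converges to the logistic kinetics", {
  v <- default_varieties()
  p <- v[[1]]
  p$dispersion[] <- 0
  sim <- simulate_batch(p, NULL, n_seeds = 5000, n_replicates = 1,
                        rng_seed = 33)
  days <- sim$records$germination_day[sim$records$germinated == 1]
  # reference truncated-logistic CDF on [0, 14]
  Fref <- function(t) {
    (plogis(t, p$t50, 1 / p$k_germ) - plogis(0, p$t50, 1 / p$k_germ)) /
      (plogis(14, p$t50, 1 / p$k_germ) - plogis(0, p$t50, 1 / p$k_germ))
  }
  grid <- seq(0, 14, by = 0.01)
  ks <- max(abs(ecdf(days)(grid) - Fref(grid)))
  expect_lt(ks, 0.05)
})

test_that("optimal-dose simulation reproduces the published optimized cells", {
  v <- default_varieties()
  ci_g <- list(c(92.3, 95.9), c(89.4, 93.2), c(95.1, 98.3))
  ci_vi <- list(c(87.4, 92.0), c(84.3, 89.3), c(90.2, 94.6))
  for (i in seq_along(v)) {
    sim <- simulate_batch(v[[i]], calibration_protocol(v[[i]]),
                          n_seeds = 1000, n_replicates = 3,
                          rng_seed = 40 + i)
    g <- sim$summary[["germination_pct"]]
    vi <- sim$summary[["vigor_index"]]
    expect_gt(g, ci_g[[i]][1]); expect_lt(g, ci_g[[i]][2])
    expect_gt(vi, ci_vi[[i]][1]); expect_lt(vi, ci_vi[[i]][2])
  }
})

test_that("benefit_cost_ratio discounts correctly", {
  expect_equal(benefit_cost_ratio(econ_model(c(100, 100), c(100, 100),
                                             0.07)), 1)
  expect_equal(benefit_cost_ratio(econ_model(300, 100, 0)), 3)
  # spreadsheet-style oracle at r = 0.05
  r <- 0.05
  oracle <- (110 / 1.05 + 121 / 1.05^2) / (100 / 1.05 + 100 / 1.05^2)
  expect_equal(benefit_cost_ratio(econ_model(c(110, 121), c(100, 100), r)),
               oracle)
  expect_error(benefit_cost_ratio(econ_model(c(1), c(0), 0)), "costs")
})
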