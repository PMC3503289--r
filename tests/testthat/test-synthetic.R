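test_that("default scenario carries the bench-scale design", {
  sp <- scenario_starch_default()
  expect_equal(sp$S0_grid, c(1, 5, 10, 50, 100))
  expect_equal(sp$t_grid, c(5, 10, 20, 40, 60, 90, 120))
  expect_equal(sp$true_kinetics$Km, 3.38)
  expect_equal(sp$true_kinetics$Vmax, 0.134 * 60)
  expect_equal(sp$noise_cv, 0)
})

test_that("generation is deterministic under a fixed seed", {
  sp <- scenario_starch_default(noise_cv = 0.05, replicates = 3)
  a <- generate_series(sp)
  b <- generate_series(sp)
  expect_identical(a, b)
  # and does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_series(sp)); after <- runif(1)
  expect_identical(before, after)
  c2 <- generate_series(scenario_starch_default(noise_cv = 0.05,
                                                replicates = 3, seed = 2))
  expect_false(identical(a, c2))
})

test_that("noiseless generation returns exact integrated-rate data", {
  sp <- scenario_starch_default()
  sers <- generate_series(sp)
  expect_length(sers, 5)
  k <- sp$true_kinetics
  for (s in sers)
    expect_equal(s$observations$St,
                 predict_outlet(s$S0, s$observations$t, k))
  # end-to-end recovery through the estimator
  fit <- suppressWarnings(estimate_km_vmax(sers[[3]], drop_complete = TRUE))
  expect_equal(fit$Km_hat, 3.38, tolerance = 1e-6)
  expect_equal(fit$Vmax_hat, 8.04, tolerance = 1e-6)
})

test_that("noiseless conversion rises with residence time", {
  sers <- generate_series(scenario_starch_default())
  for (s in sers) {
    X <- conversion(s$S0, s$observations$St)
    expect_true(all(diff(X) >= 0))
  }
})

test_that("multiplicative noise is mean-one with the requested spread", {
  truth <- mm_kinetics(Km = 3.38, Vmax = 0.134, rate_unit = "per_sec")
  sp <- scenario_spec(truth, S0_grid = 10, t_grid = c(5, 10),
                      noise_cv = 0.05, replicates = 200, seed = 20121031)
  sers <- generate_series(sp)
  St_true <- predict_outlet(10, c(5, 10), truth)
  obs5 <- sapply(sers, function(s) s$observations$St[1])
  expect_equal(mean(obs5) / St_true[1], 1, tolerance = 0.02)
  cv <- sd(obs5) / mean(obs5)
  expect_lt(abs(cv - 0.05) / 0.05, 0.2)    # empirical CV within 20%
})

test_that("Km error under 5% noise reproduces its calibrated value", {
  truth <- mm_kinetics(Km = 3.38, Vmax = 0.134, rate_unit = "per_sec")
  sp <- scenario_spec(truth, S0_grid = 10, noise_cv = 0.05,
                      replicates = 200, seed = 20121031)
  errs <- sapply(generate_series(sp), function(s)
    abs(suppressWarnings(estimate_km_vmax(s, drop_complete = TRUE))$Km_hat /
          3.38 - 1))
  # frozen Monte-Carlo calibration at this seed and design
  expect_equal(median(errs), 0.02638645, tolerance = 1e-6)
  expect_lt(median(errs), 0.15)
})

test_that("scenario validation rejects malformed designs", {
  k <- mm_kinetics(Km = 1, Vmax = 1)
  expect_error(scenario_spec(k, S0_grid = numeric(0)), "nonempty")
  expect_error(scenario_spec(k, t_grid = c(10, 5)), "increasing")
  expect_error(scenario_spec(k, noise_cv = -0.1), "nonnegative")
  expect_error(scenario_spec(k, replicates = 0), "at least 1")
})
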