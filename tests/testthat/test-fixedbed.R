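test_that("residence time reproduces the bench operating points", {
  expect_equal(residence_time(reactor_spec(VR = 60, epsilon = 0.42, Q = 5.04)), 5)
  expect_equal(residence_time(reactor_spec(VR = 60, epsilon = 0.42, Q = 0.21)), 120)
  expect_equal(residence_time(reactor_spec(VR = 50, epsilon = 0.3, Q = 15)), 1)
  # linear in VR and epsilon, antitone in Q
  base <- residence_time(reactor_spec(30, 0.4, 2))
  expect_equal(residence_time(reactor_spec(60, 0.4, 2)), 2 * base)
  expect_equal(residence_time(reactor_spec(30, 0.8, 2)), 2 * base)
  expect_equal(residence_time(reactor_spec(30, 0.4, 4)), base / 2)
})

test_that("void fraction and entrapment efficiency are the stated ratios", {
  expect_equal(void_fraction(25.2, 60), 0.42)
  expect_equal(void_fraction(0, 60), 0)
  expect_equal(void_fraction(60, 60), 1)
  expect_error(void_fraction(61, 60), "exceed")
  expect_equal(entrapment_efficiency(0.081, 0.00405), 95)
  expect_equal(entrapment_efficiency(0.081, 0.0243), 70)
  expect_equal(entrapment_efficiency(0.081, 0), 100)
  expect_error(entrapment_efficiency(0.081, 0.1), "exceed")
})

test_that("linearization maps observations to the stated coordinates", {
  k <- mm_kinetics(Km = 1, Vmax = 0.05)
  s <- conversion_series(10, c(5, 10), c(10, 5))
  pts <- linearize_conversion(s)
  expect_equal(pts$x[1], 0)            # X = 0 maps to the origin
  expect_equal(pts$y[1], 0)
  expect_equal(pts$x[2], 0.05)         # X = 0.5 at t = 10
  expect_equal(pts$y[2], log(0.5) / 10)
})

test_that("exact integrated-rate data are collinear under linearization", {
  k <- mm_kinetics(Km = 3.38, Vmax = 0.05)
  s <- noiseless_series(10, k)
  pts <- linearize_conversion(s)
  fit <- lm(y ~ x, data = pts)
  expect_lt(max(abs(residuals(fit))), 1e-12)
  expect_equal(unname(coef(fit)[2]), 10 / 3.38, tolerance = 1e-10)   # S0/Km
  expect_equal(unname(coef(fit)[1]), -0.05 / 3.38, tolerance = 1e-10) # -Vmax/Km
})

test_that("complete conversion is rejected unless exclusion is requested", {
  s <- conversion_series(10, c(5, 10, 20), c(8, 5, 10 * 1e-13))
  expect_error(linearize_conversion(s), "complete conversion")
  expect_warning(pts <- linearize_conversion(s, drop_complete = TRUE),
                 "dropping 1")
  expect_equal(nrow(pts), 2)
})

test_that("estimator recovers the generating parameters from exact data", {
  # truth echoing the bench-scale fit at 10 g/L inlet
  k <- mm_kinetics(Km = 3.38, Vmax = 0.134, rate_unit = "per_sec")
  s <- noiseless_series(10, k)
  fit <- suppressWarnings(estimate_km_vmax(s, drop_complete = TRUE))
  expect_equal(fit$Km_hat, 3.38, tolerance = 1e-6)
  expect_equal(fit$Vmax_hat / 60, 0.134, tolerance = 1e-6)  # back to per-sec
  expect_gt(fit$r_squared, 1 - 1e-12)
})

test_that("two exact points give the interpolating line", {
  k <- mm_kinetics(Km = 2, Vmax = 0.08)
  s <- noiseless_series(5, k, t = c(10, 40))
  fit <- estimate_km_vmax(s)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points, 2L)
  expect_equal(fit$Km_hat, 2, tolerance = 1e-9)
})

test_that("estimator flags data implying nonpositive Km", {
  # conversion falling with residence time contradicts the rate law
  s <- conversion_series(10, c(5, 10), c(1, 9))
  expect_error(estimate_km_vmax(s), "nonpositive slope")
  expect_error(estimate_km_vmax(conversion_series(10, 5, 8)),
               "at least 2")
})

test_that("random truths are recovered from noiseless data", {
  set.seed(42)
  for (i in 1:50) {
    d <- draw_informative_kinetics()
    s <- noiseless_series(d$S0, d$k)
    fit <- suppressWarnings(estimate_km_vmax(s, drop_complete = TRUE))
    expect_equal(fit$Km_hat, d$Km, tolerance = 1e-6)
    expect_equal(fit$Vmax_hat, d$Vmax, tolerance = 1e-6)
  }
})

test_that("estimator error shrinks monotonically with the noise level", {
  truth <- mm_kinetics(Km = 3.38, Vmax = 0.134, rate_unit = "per_sec")
  med_err <- sapply(c(0.1, 0.05, 0.02), function(cv) {
    sp <- scenario_spec(truth, S0_grid = 10, noise_cv = cv,
                        replicates = 100, seed = 99)
    errs <- sapply(generate_series(sp), function(s)
      abs(suppressWarnings(estimate_km_vmax(s, drop_complete = TRUE))$Km_hat /
            3.38 - 1))
    median(errs)
  })
  expect_true(all(diff(med_err) < 0))
})

test_that("fit table serializes with the documented header", {
  k <- mm_kinetics(Km = 2, Vmax = 0.08)
  fit <- estimate_km_vmax(noiseless_series(5, k, t = c(10, 40)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fit_table(fit, path, E0 = 0.081)
  expect_identical(readLines(path, n = 1),
                   "S0_g_per_L,Km_g_per_L,Vmax_g_per_L_min,k2_per_min,r_squared,n_points")
  tab <- read.csv(path)
  expect_equal(tab$k2_per_min, fit$Vmax_hat / 0.081)
})
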