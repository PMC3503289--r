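test_that("rate law satisfies its algebraic identities and bounds", {
  k <- mm_kinetics(Km = 2.5, Vmax = 1.7)
  expect_identical(mm_rate(0, k), 0)
  expect_equal(mm_rate(k$Km, k), k$Vmax / 2)
  expect_equal(mm_rate(9 * k$Km, k), 0.9 * k$Vmax)
  S <- sort(10^runif(50, -3, 3))
  v <- mm_rate(S, k)
  expect_true(all(diff(v) >= 0))          # monotone nondecreasing
  expect_true(all(v < k$Vmax))
  expect_error(mm_rate(-1, k), "nonnegative")
})

test_that("parameter set enforces unit conversion and consistency", {
  k <- mm_kinetics(Km = 3.38, Vmax = 0.134, rate_unit = "per_sec")
  expect_equal(k$Vmax, 8.04)
  expect_silent(mm_kinetics(Km = 1, Vmax = 2, k2 = 4, E0 = 0.5))
  expect_error(mm_kinetics(Km = 1, Vmax = 2, k2 = 5, E0 = 0.5), "k2 \\* E0")
  expect_silent(mm_kinetics(Km = 3, Vmax = 1, k2 = 2, E0 = 0.5,
                            k1 = 1, k_minus1 = 1))
  expect_error(mm_kinetics(Km = 4, Vmax = 1, k2 = 2, E0 = 0.5,
                           k1 = 1, k_minus1 = 1), "k_minus1")
  expect_error(mm_kinetics(Km = -1, Vmax = 1), "Km")
  expect_error(mm_kinetics(Km = 1, Vmax = 0), "Vmax")
})

test_that("integrated time evaluates the closed form and its limits", {
  k <- mm_kinetics(Km = 1, Vmax = 1)
  expect_equal(integrated_time(5, 5, k), 0)
  expect_equal(integrated_time(2, 1, k), log(2) + 1)
  # near-zero Km: zero-order regime t -> (S0 - St)/Vmax
  kz <- mm_kinetics(Km = 1e-9, Vmax = 2)
  expect_equal(integrated_time(8, 3, kz), (8 - 3) / 2, tolerance = 1e-6)
  St <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(integrated_time(2, St, k)) < 0))  # antitone in St
  expect_error(integrated_time(2, 0, k), "diverges")
  expect_error(integrated_time(2, 3, k), "exceed")
})

test_that("outlet prediction inverts the integrated law", {
  k <- mm_kinetics(Km = 1, Vmax = 1)
  expect_identical(predict_outlet(2, 0, k), 2)
  expect_equal(predict_outlet(2, log(2) + 1, k), 1, tolerance = 1e-12)
  # first-order limit S0 << Km: St -> S0 exp(-Vmax t / Km)
  kf <- mm_kinetics(Km = 1, Vmax = 0.25)
  S0 <- 1e-3
  expect_equal(predict_outlet(S0, 4, kf), S0 * exp(-0.25 * 4 / 1),
               tolerance = 1e-3)
})

test_that("outlet prediction round-trips over three orders of magnitude", {
  set.seed(11)
  for (Km in c(0.05, 1, 50)) for (Vmax in c(0.02, 0.5, 10)) {
    k <- mm_kinetics(Km = Km, Vmax = Vmax)
    for (S0 in c(0.1, 3, 100)) {
      St <- S0 * runif(3, 1e-6, 1)
      tt <- integrated_time(S0, St, k)
      expect_equal(predict_outlet(S0, tt, k), St, tolerance = 1e-10)
    }
  }
})

test_that("outlet prediction agrees with direct ODE integration", {
  # independent oracle: adaptive integration of dS/dt = -Vmax S / (Km + S)
  set.seed(23)
  for (i in 1:100) {
    Km <- 10^runif(1, -1, 1.5)
    Vmax <- 10^runif(1, -2, 0.5)
    S0 <- 10^runif(1, -1, 2)
    t_end <- runif(1, 1, 60)
    k <- mm_kinetics(Km = Km, Vmax = Vmax)
    ode <- deSolve::ode(y = c(S = S0), times = c(0, t_end),
                        func = function(t, y, p) list(-Vmax * y / (Km + y)),
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    S_ode <- ode[2, "S"]
    if (S_ode > S0 * 1e-6)   # oracle itself loses accuracy at deep conversion
      expect_equal(predict_outlet(S0, t_end, k), unname(S_ode),
                   tolerance = 1e-6)
  }
})

test_that("conversion and turnover number are the stated ratios", {
  expect_equal(conversion(10, 10), 0)
  expect_equal(conversion(10, 0), 1)
  expect_equal(conversion(10, 2.5), 0.75)
  St <- seq(0, 10, by = 1)
  expect_true(all(diff(conversion(10, St)) < 0))  # antitone in St
  expect_error(conversion(10, 11), "exceed")
  expect_equal(turnover_number(1, 1), 1)
  expect_equal(turnover_number(0.162, 0.081), 2)
  expect_equal(turnover_number(3.7 * 0.081, 0.081), 3.7)
  expect_error(turnover_number(1, 0), "positive")
})

test_that("conversion series validates its observations", {
  expect_error(conversion_series(10, c(5, 5), c(9, 8)), "increasing")
  expect_error(conversion_series(10, c(5, 10), c(9, 11)), "exceed")
  expect_error(conversion_series(10, c(-5, 10), c(9, 8)), "positive")
  s <- conversion_series(10, c(5, 10), c(9, 8))
  expect_s3_class(s, "conversion_series")
  expect_equal(s$observations$St, c(9, 8))
})
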