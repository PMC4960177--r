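test_that("polynomial smoothing reproduces nested and interpolating fits", {
  tt <- seq(0, 96, by = 24)
  # linear data under a quadratic model: leading coefficient vanishes
  ts <- culture_timeseries(tt, X = 1e5 + 2e3 * tt, S = 4.8)
  sm <- fit_polynomial_window(ts, "X", degree = 2)
  expect_equal(sm$coefficients[3], 0, tolerance = 1e-9)
  expect_equal(sm$r_squared, 1, tolerance = 1e-12)
  # three points, quadratic: exact interpolation
  ts3 <- culture_timeseries(c(0, 24, 48), X = c(2e5, 5e5, 7e5), S = 4.8)
  sm3 <- fit_polynomial_window(ts3, "X", degree = 2)
  expect_equal(evaluate_profile(sm3, c(0, 24, 48)), c(2e5, 5e5, 7e5))
  expect_equal(sm3$r_squared, 1, tolerance = 1e-12)
  # insufficient points named in the error
  expect_error(fit_polynomial_window(ts3, "X", degree = 6), "degree-6")
})

test_that("higher-degree least squares never fits worse (nested models)", {
  set.seed(42)
  tt <- seq(0, 168, by = 24)
  X <- 2e5 * exp(0.03 * tt) * exp(rnorm(length(tt), 0, 0.05))
  ts <- culture_timeseries(tt, X = X, S = 4.8)
  rss <- function(deg) {
    sm <- fit_polynomial_window(ts, "X", degree = deg)
    sum((evaluate_profile(sm, tt) - X)^2)
  }
  expect_lte(rss(6), rss(5) + 1e-6 * rss(5))
})

test_that("analytic differentiation of smoothed profiles is exact", {
  # 1 + 2t + 3t^2 at t = 2 -> 14
  p <- smoothed_profile(c(1, 2, 3), window = c(0, 10))
  expect_equal(differentiate(p, 2), 14)
  # constant polynomial: zero rate
  expect_equal(differentiate(smoothed_profile(5, c(0, 10)), c(1, 5)), c(0, 0))
  # exact linear recovery through the fitting pipeline
  tt <- seq(0, 96, by = 12)
  ts <- culture_timeseries(tt, X = 2e5 * (1 + 0.1 * tt), S = 4.8)
  sm <- fit_polynomial_window(ts, "X", degree = 2)
  expect_equal(differentiate(sm, c(0, 48, 96)), rep(2e4, 3), tolerance = 1e-9)
  # no extrapolation outside the window
  expect_error(differentiate(sm, 120), "outside the fit window")
})

test_that("polynomial pipeline recovers the derivative of matching-degree data", {
  tt <- seq(0, 100, by = 10)
  coefs <- c(2e5, 3e3, 40, -0.3)  # cubic
  X <- coefs[1] + coefs[2] * tt + coefs[3] * tt^2 + coefs[4] * tt^3
  ts <- culture_timeseries(tt, X = X, S = 4.8)
  sm <- fit_polynomial_window(ts, "X", degree = 3)
  d_true <- coefs[2] + 2 * coefs[3] * tt + 3 * coefs[4] * tt^2
  expect_equal(differentiate(sm, tt), d_true, tolerance = 1e-8)
})

test_that("IVCC is the trapezoidal integral and is additive over windows", {
  # rectangle
  ts <- culture_timeseries(c(0, 24), X = 2e6, S = 1)
  expect_equal(integral_viable_cells(ts), 4.8e7)
  # triangle
  ts2 <- culture_timeseries(c(0, 24), X = c(0, 2e6), S = 1)
  expect_equal(integral_viable_cells(ts2), 2.4e7)
  # exponential vs closed form on a dense grid
  tt <- seq(0, 48, by = 0.5)
  ts3 <- culture_timeseries(tt, X = 2e5 * exp(0.03 * tt), S = 1)
  closed <- 2e5 * (exp(0.03 * 48) - 1) / 0.03
  expect_equal(integral_viable_cells(ts3), closed, tolerance = 5e-3)
  # additivity over adjacent windows
  tt4 <- seq(0, 96, by = 24)
  ts4 <- culture_timeseries(tt4, X = c(2e5, 8e5, 3e6, 6e6, 5e6), S = 1)
  expect_equal(integral_viable_cells(ts4, c(0, 48)) +
                 integral_viable_cells(ts4, c(48, 96)),
               integral_viable_cells(ts4, c(0, 96)))
  expect_error(integral_viable_cells(ts4, c(200, 300)), "fewer than 2")
})

test_that("specific rates carry the conventional signs and units", {
  # glucose: 0.4 g/L drop over 24 h at constant 2e6 cells/mL -> 0.2 ng/cell/day consumed
  ts <- culture_timeseries(c(0, 24), X = 2e6, S = c(1.0, 0.6))
  expect_equal(specific_rate(ts, "S", c(0, 24)), 0.2)
  # no change -> zero
  ts0 <- culture_timeseries(c(0, 24), X = 2e6, S = 1.0)
  expect_equal(specific_rate(ts0, "S", c(0, 24)), 0)
  # lactate consumption at 0.05 ng/cell/day is reported as -0.05
  tt <- seq(0, 72, by = 24)
  lac <- 0.5 - 0.05e-6 * 2e6 * tt / 24
  tsl <- culture_timeseries(tt, X = 2e6, S = 0, Lac = lac)
  expect_equal(specific_rate(tsl, "Lac", c(0, 72)), -0.05)
  # antibody in pg/cell/day: 12 mg/L over 5 days at 2e6 cells/mL
  tsp <- culture_timeseries(c(0, 120), X = 2e6, S = 1, P = c(0, 12))
  expect_equal(specific_rate(tsp, "P", c(0, 120)),
               12 / (2e6 * 120) * 24 * 1e6)
})

test_that("specific rates are invariant to time-unit rescaling after conversion", {
  tt <- seq(0, 72, by = 24)
  X <- c(1e6, 2e6, 3e6, 2.5e6)
  S <- c(2.0, 1.4, 0.9, 0.7)
  q_hours <- specific_rate(culture_timeseries(tt, X, S), "S", c(0, 72))
  # same data sampled twice as densely in time, linearly interpolated
  tt2 <- seq(0, 72, by = 12)
  X2 <- approx(tt, X, tt2)$y
  S2 <- approx(tt, S, tt2)$y
  q_dense <- specific_rate(culture_timeseries(tt2, X2, S2), "S", c(0, 72))
  expect_equal(q_hours, q_dense, tolerance = 1e-12)
})

test_that("phase helpers label windows and suggest the depletion boundary", {
  ph <- culture_phase("II", c(96, 168))
  expect_s3_class(ph, "culture_phase")
  tt <- seq(0, 168, by = 24)
  S <- pmax(4.8 - 0.035 * tt, 0)
  ts <- culture_timeseries(tt, X = 2e6, S = S)
  b <- suggest_phase_boundary(ts, cutoff = 0.58)
  expect_true(is.finite(b) && b > 96 && b < 168)
})
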