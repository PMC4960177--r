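rcho <- get_default_parameters("r-CHO", 33)

test_that("log-linear growth-rate fit recovers exact exponentials", {
  tt <- c(0, 24, 48, 72)
  ts <- culture_timeseries(tt, X = 2e5 * exp(0.035 * tt), S = 4.8)
  fit <- estimate_mu_loglinear(ts)
  expect_equal(unname(fit$estimates["mu"]), 0.035, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_true(fit$valid)
  # constant culture: zero growth rate
  ts0 <- culture_timeseries(tt, X = 2e5, S = 4.8)
  expect_equal(unname(estimate_mu_loglinear(ts0)$estimates["mu"]), 0)
  # non-positive X in the window is an error, not a silent drop
  tsz <- culture_timeseries(tt, X = c(2e5, 0, 3e5, 4e5), S = 4.8)
  expect_error(estimate_mu_loglinear(tsz), "positive")
})

test_that("log-linear fit agrees with an independent regression on logged values", {
  tt <- seq(0, 96, by = 24)
  eps <- 0.01 * c(1, -1, 1, -1, 1)
  X <- 2e5 * exp(0.040 * tt) * (1 + eps)
  ts <- culture_timeseries(tt, X = X, S = 4.8)
  fit <- estimate_mu_loglinear(ts)
  oracle <- unname(coef(lm(log(X) ~ tt))[2])
  expect_equal(unname(fit$estimates["mu"]), oracle, tolerance = 1e-12)
  expect_lt(abs(fit$estimates[["mu"]] - 0.040), 0.001)
})

test_that("exponential-window selection matches brute-force enumeration", {
  # exponential for 4 days then plateau
  tt <- seq(0, 168, by = 24)
  X <- c(2e5 * exp(0.035 * tt[1:5]), rep(2e5 * exp(0.035 * 96), 3))
  ts <- culture_timeseries(tt, X = X, S = 4.8)
  win <- select_exponential_window(ts, min_points = 3, r2_floor = 0.98)
  # independent brute force over all contiguous windows
  brute <- NULL; brute_len <- -Inf
  for (i in 1:(length(tt) - 2)) for (j in (i + 2):length(tt)) {
    f <- lm(log(X[i:j]) ~ tt[i:j])
    r2 <- suppressWarnings(summary(f)$r.squared)  # exact fits warn
    if (is.nan(r2)) r2 <- 1  # constant segment fitted exactly
    if (r2 >= 0.98 && (j - i) > brute_len) { brute_len <- j - i; brute <- c(tt[i], tt[j]) }
  }
  expect_equal(win, brute)
  expect_equal(win, c(0, 96))
  # pure exponential: any floor returns the full series
  tsx <- culture_timeseries(tt, X = 2e5 * exp(0.03 * tt), S = 4.8)
  expect_equal(select_exponential_window(tsx, r2_floor = 0.999), c(0, 168))
  # too few samples
  ts2 <- culture_timeseries(c(0, 24), X = c(2e5, 4e5), S = 4.8)
  expect_error(select_exponential_window(ts2, min_points = 3), "at least 3")
})

test_that("Lineweaver-Burk round trip is exact for any positive parameter triple", {
  S0 <- c(4.8, 3.6, 2.4, 1.2)
  cases <- list(c(0.040, 0.664, 0.58),   # producing line
                c(0.050, 2.058, 0.60),   # naive line, alternate source
                c(0.025, 0.15, 0.30),
                c(0.060, 3.0, 0.9))
  for (cs in cases) {
    p <- kinetic_parameters(cs[1], cs[2], cs[3], 1e6)
    tbl <- data.frame(S0 = S0, mu = monod_mu(S0, p))
    fit <- fit_monod_lineweaver_burk(tbl, S_t = cs[3])
    expect_equal(unname(fit$estimates["mu_max"]), cs[1], tolerance = 1e-9)
    expect_equal(unname(fit$estimates["K_s"]), cs[2], tolerance = 1e-9)
    expect_true(fit$valid)
  }
})

test_that("Lineweaver-Burk fit excludes sub-threshold points and handles saturation", {
  p <- kinetic_parameters(0.040, 0.664, 0.58, 1e6)
  tbl <- data.frame(S0 = c(4.8, 3.6, 2.4, 1.2, 0.5), mu = c(monod_mu(c(4.8, 3.6, 2.4, 1.2), p), 0))
  expect_warning(fit <- fit_monod_lineweaver_burk(tbl, S_t = 0.58), "excluded")
  expect_equal(fit$n_points, 4L)
  # all mu equal: saturated limit, K_s -> 0
  sat <- data.frame(S0 = c(4.8, 3.6, 2.4), mu = 0.04)
  fs <- fit_monod_lineweaver_burk(sat, S_t = 0.58)
  expect_equal(unname(fs$estimates["mu_max"]), 0.04, tolerance = 1e-12)
  expect_equal(unname(fs$estimates["K_s"]), 0, tolerance = 1e-12)
  # fewer than 3 usable points
  expect_warning(
    expect_error(
      fit_monod_lineweaver_burk(data.frame(S0 = c(4.8, 0.5, 0.4), mu = c(0.03, 0, 0)), 0.58),
      "at least 3"))
})

test_that("nonlinear Monod cross-check agrees with the linearization on clean data", {
  p <- kinetic_parameters(0.040, 0.664, 0.58, 1e6)
  tbl <- data.frame(S0 = c(4.8, 3.6, 2.4, 1.2), mu = monod_mu(c(4.8, 3.6, 2.4, 1.2), p))
  lb <- fit_monod_lineweaver_burk(tbl, 0.58)
  nl <- fit_monod_nls(tbl, 0.58)
  expect_equal(lb$estimates[["mu_max"]], nl$estimates[["mu_max"]], tolerance = 1e-5)
  expect_equal(lb$estimates[["K_s"]], nl$estimates[["K_s"]], tolerance = 1e-4)
})

test_that("threshold bracketing follows the low-glucose growth screen", {
  sc <- growth_screen(c(0.25, 0.45, 0.65, 1.2), c(FALSE, FALSE, TRUE, TRUE))
  est <- estimate_threshold(sc)
  expect_equal(est$bracket, c(0.45, 0.65))
  expect_equal(est$estimate, 0.55)
  # tight bracket converges on the true threshold
  d <- 1e-4
  sc2 <- growth_screen(c(0.58 - d, 0.58 + d), c(FALSE, TRUE))
  expect_equal(estimate_threshold(sc2)$estimate, 0.58, tolerance = 1e-3)
  # degenerate screens
  expect_error(estimate_threshold(growth_screen(c(1, 2), c(TRUE, TRUE))), "bracket")
  expect_error(growth_screen(c(1, 1), c(TRUE, FALSE)), "distinct")
})

test_that("through-origin yield regression recovers constant-yield rates", {
  # exactly proportional rates
  r_s <- -c(0.01, 0.02, 0.05, 0.08)
  rates <- data.frame(r_x = 2.79e6 * (-r_s), r_s = r_s)
  fit <- estimate_yield(rates)
  expect_equal(unname(fit$estimates["Y_xs"]), 2.79e6)
  expect_true(fit$valid)
  # zero growth -> zero slope
  z <- estimate_yield(data.frame(r_x = c(0, 0, 0), r_s = r_s[1:3]))
  expect_equal(unname(z$estimates["Y_xs"]), 0)
  # no consumption is an error
  expect_error(estimate_yield(data.frame(r_x = c(1, 2, 3), r_s = c(0, 0.1, 0.2))),
               "consumption")
})

test_that("yield through the polynomial-rate pipeline round-trips the simulator", {
  Y_true <- 1.70e6
  p <- update_parameters(rcho, Y_xs = Y_true)
  sim <- simulate_batch(p, X0 = 2e5, S0 = 4.8, t_end = 96, dt = 0.1)
  keep <- sim$time %in% seq(0, 96, by = 24)
  ts <- culture_timeseries(sim$time[keep], sim$X[keep], sim$S[keep])
  fit <- estimate_yield(rate_series(ts))
  expect_equal(unname(fit$estimates["Y_xs"]), Y_true, tolerance = 0.02)
  # invariant to halving the sampling of the exponential window (noiseless)
  keep2 <- sim$time %in% seq(0, 96, by = 48)
  ts2 <- culture_timeseries(sim$time[keep2], sim$X[keep2], sim$S[keep2])
  fit2 <- estimate_yield(rate_series(ts2))
  expect_equal(fit2$estimates[["Y_xs"]], fit$estimates[["Y_xs"]], tolerance = 0.02)
})

test_that("direct Luedeking-Piret regression recovers generating constants", {
  prof <- lp_fixture_profile(dt = 0.5)
  P <- euler_integrate_product(prof, rcho, P0 = 0)
  n <- nrow(prof)
  rates <- data.frame(r_p = diff(P) / diff(prof$time),
                      r_x = prof$r_x[-n], X = prof$X[-n])
  fit <- fit_lp_direct(rates)
  expect_equal(unname(fit$estimates["alpha"]), 7.65e-7, tolerance = 1e-10)
  expect_equal(unname(fit$estimates["beta"]), 7.68e-8, tolerance = 1e-10)
  # beta = 0 generator
  p0 <- update_parameters(rcho, beta = 0)
  P0v <- euler_integrate_product(prof, p0)
  rates0 <- data.frame(r_p = diff(P0v) / diff(prof$time),
                       r_x = prof$r_x[-n], X = prof$X[-n])
  fit0 <- fit_lp_direct(rates0)
  expect_equal(unname(fit0$estimates["beta"]), 0, tolerance = 1e-15)
  expect_equal(unname(fit0$estimates["alpha"]), 7.65e-7, tolerance = 1e-10)
  # pure exponential profile: rank-deficient design
  tt <- seq(0, 96, by = 1)
  X <- 2e5 * exp(0.03 * tt)
  expo <- data.frame(r_p = 1e-7 * 0.03 * X + 1e-8 * X, r_x = 0.03 * X, X = X)
  expect_error(fit_lp_direct(expo), "collinear")
})

test_that("integral Luedeking-Piret fit recovers constants and matches the direct fit", {
  prof <- lp_fixture_profile(dt = 0.5)
  prof$P <- euler_integrate_product(prof, rcho, P0 = 0)
  obs <- prof[prof$time %% 24 == 0, c("time", "P")]
  fit <- fit_lp_integral(prof[c("time", "X", "r_x")], obs)
  expect_equal(unname(fit$estimates["alpha"]), 7.65e-7, tolerance = 1e-3)
  expect_equal(unname(fit$estimates["beta"]), 7.68e-8, tolerance = 1e-3)
  # agreement with the direct estimator on the same generator
  n <- nrow(prof)
  direct <- fit_lp_direct(data.frame(r_p = diff(prof$P) / diff(prof$time),
                                     r_x = prof$r_x[-n], X = prof$X[-n]))
  expect_equal(fit$estimates[["alpha"]], direct$estimates[["alpha"]], tolerance = 0.01)
  expect_equal(fit$estimates[["beta"]], direct$estimates[["beta"]], tolerance = 0.01)
  # constant product, growing biomass: both constants collapse to zero
  flat <- obs; flat$P <- 5
  fitf <- fit_lp_integral(prof[c("time", "X", "r_x")], flat)
  expect_lt(fitf$estimates[["alpha"]] * max(abs(prof$r_x)) * 240, 0.05)
  expect_lt(fitf$estimates[["beta"]] * max(prof$X) * 240, 0.05)
})

test_that("temperature recalibration recovers a perturbed parameter triple", {
  base <- rcho
  truth <- update_parameters(base, mu_max = base$mu_max * 1.25,
                             Y_xs = base$Y_xs * 0.66, beta = base$beta * 0.4)
  sim <- simulate_batch(truth, X0 = 2e5, S0 = 4.8, t_end = 168, dt = 0.5)
  keep <- sim$time %in% seq(0, 168, by = 24)
  ts <- culture_timeseries(sim$time[keep], sim$X[keep], sim$S[keep], P = sim$P[keep])
  rec <- recalibrate_at_temperature(ts, base, dt = 0.5)
  expect_equal(rec$mu_max, truth$mu_max, tolerance = 0.01)
  expect_equal(rec$Y_xs, truth$Y_xs, tolerance = 0.01)
  expect_equal(rec$beta, truth$beta, tolerance = 0.01)
  # held-fixed parameters are untouched by construction
  expect_identical(rec$S_t, base$S_t)
  expect_identical(rec$alpha, base$alpha)
})

test_that("recalibration is a fixed point on data simulated from the base set", {
  base <- rcho
  sim <- simulate_batch(base, X0 = 2e5, S0 = 4.8, t_end = 168, dt = 0.5)
  keep <- sim$time %in% seq(0, 168, by = 24)
  ts <- culture_timeseries(sim$time[keep], sim$X[keep], sim$S[keep], P = sim$P[keep])
  rec <- recalibrate_at_temperature(ts, base, dt = 0.5)
  expect_equal(rec$mu_max, base$mu_max, tolerance = 0.01)
  expect_equal(rec$Y_xs, base$Y_xs, tolerance = 0.01)
  expect_equal(rec$beta, base$beta, tolerance = 0.02)
})

test_that("recalibrated beta lands in the published high-temperature range", {
  base <- rcho
  truth <- update_parameters(base, mu_max = 0.040, Y_xs = 1.70e6, beta = 2e-8)
  sim <- simulate_batch(truth, X0 = 2e5, S0 = 4.8, t_end = 168, dt = 0.5)
  keep <- sim$time %in% seq(0, 168, by = 24)
  ts <- culture_timeseries(sim$time[keep], sim$X[keep], sim$S[keep], P = sim$P[keep])
  rec <- recalibrate_at_temperature(ts, base, dt = 0.5)
  rng <- beta_range_37C()
  expect_gte(rec$beta, rng[1])
  expect_lte(rec$beta, rng[2])
})
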