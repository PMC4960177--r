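rcho <- get_default_parameters("r-CHO", 33)
registry <- cho_parameter_registry()

test_that("batch simulation conserves the yield balance without death or maintenance", {
  sim <- simulate_batch(rcho, X0 = 2e5, S0 = 4.8, t_end = 240, dt = 0.1)
  defect <- abs((sim$X - 2e5) - rcho$Y_xs * (4.8 - sim$S))
  expect_lt(max(defect) / max(sim$X), 1e-12)
  # substrate exhausts to the growth threshold, so the terminal biomass is
  # fixed by the closed-form mass balance
  sim2 <- simulate_batch(rcho, X0 = 2e5, S0 = 4.755, t_end = 1200, dt = 0.1)
  expect_equal(tail(sim2$X, 1) - 2e5, rcho$Y_xs * (4.755 - 0.58), tolerance = 1e-3)
  expect_equal(tail(sim2$S, 1), 0.58, tolerance = 1e-3)
})

test_that("below the threshold the culture is static and production is biomass-driven", {
  sim <- simulate_batch(rcho, X0 = 2e5, S0 = 0.5, t_end = 120, dt = 0.1)
  expect_true(all(abs(sim$X - 2e5) < 1e-6))
  # P grows linearly at beta * X0
  expect_equal(tail(sim$P, 1), rcho$beta * 2e5 * 120, tolerance = 1e-9)
  expect_true(all(diff(sim$P) > 0))
})

test_that("product is non-decreasing while growth is non-negative", {
  sim <- simulate_batch(rcho, X0 = 2e5, S0 = 4.8, t_end = 240, dt = 0.1)
  expect_true(all(diff(sim$P) >= -1e-12))
})

test_that("RK4 shows fourth-order convergence and matches an independent integrator", {
  # smooth regime: glucose stays above threshold for 48 h
  ref <- simulate_batch(rcho, 2e5, 4.8, t_end = 48, dt = 0.003125)
  err <- function(dt) {
    s <- simulate_batch(rcho, 2e5, 4.8, t_end = 48, dt = dt)
    abs(tail(s$X, 1) - tail(ref$X, 1))
  }
  ratio <- err(0.4) / err(0.2)
  expect_gt(ratio, 10); expect_lt(ratio, 30)   # ~16x per halving
  # forward Euler is first order
  refE <- simulate_batch(rcho, 2e5, 4.8, 48, dt = 0.003125, method = "euler")
  errE <- function(dt) {
    s <- simulate_batch(rcho, 2e5, 4.8, 48, dt = dt, method = "euler")
    abs(tail(s$X, 1) - tail(refE$X, 1))
  }
  ratioE <- errE(0.4) / errE(0.2)
  expect_gt(ratioE, 1.7); expect_lt(ratioE, 2.3)
  # independent oracle: deSolve fixed-step rk4 on the same right-hand side
  skip_if_not_installed("deSolve")
  f <- function(t, y, parms) {
    mu <- monod_mu(y[2], rcho)
    list(c(mu * y[1], -mu * y[1] / rcho$Y_xs))
  }
  o <- deSolve::ode(c(X = 2e5, S = 4.8), seq(0, 48, 0.1), f, NULL, method = "rk4")
  s <- simulate_batch(rcho, 2e5, 4.8, 48, dt = 0.1)
  expect_equal(s$X, unname(o[, "X"]), tolerance = 1e-10)
  expect_equal(s$S, unname(o[, "S"]), tolerance = 1e-10)
})

test_that("death and maintenance extensions deplete glucose and kill the culture", {
  p <- fixture_parameters("r-CHO", 33)
  sim <- simulate_batch(p, 2e5, 4.8, t_end = 168, dt = 0.1)
  expect_equal(min(sim$S), 0)                       # full depletion
  ipeak <- which.max(sim$X)
  expect_lt(ipeak, nrow(sim))                       # a death phase exists
  expect_lt(tail(sim$X, 1), max(sim$X))
  # lactate: produced during growth, consumed after depletion, never negative
  expect_true(all(sim$Lac >= 0))
  expect_lt(tail(sim$Lac, 1), max(sim$Lac))
  expect_lt(max(sim$Lac), 1.0)
})

test_that("invalid simulation settings are rejected", {
  expect_error(simulate_batch(rcho, X0 = 0, S0 = 4.8, t_end = 24), "X0")
  expect_error(simulate_batch(rcho, X0 = 2e5, S0 = -1, t_end = 24), "S0")
  expect_error(simulate_batch(rcho, X0 = 2e5, S0 = 4.8, t_end = 24, dt = 48),
               "dt")
})

test_that("feed events follow the mixing balance and conserve glucose mass", {
  fb <- simulate_fed_batch(registry, "r-CHO", X0 = 1e5, S0 = 1.0, V0 = 1000,
                           feeds = list(feed_event(0.2, 100, 10)),
                           t_end = 0.4, dt = 0.1, temperature0 = 33)
  log <- attr(fb, "feed_log")
  expect_equal(nrow(log), 1L)
  # S = (1.0 * 1000 + 10 * 100) / 1100 = 1.818 g/L at the event
  expect_equal(log$S_after, (1000 * log$S_before + 100 * 10) / 1100, tolerance = 1e-12)
  expect_equal(log$V_after, 1100)
  # cells and product are diluted by the same factor
  expect_equal(log$X_after / log$X_before, 1000 / 1100, tolerance = 1e-12)
  expect_equal(log$P_after / log$P_before, 1000 / 1100, tolerance = 1e-12)
  # glucose mass after the event = mass before + V_f * C_feed (exact)
  expect_equal(log$S_after * log$V_after, log$S_before * 1000 + 100 * 10,
               tolerance = 1e-14)
  # the recorded trajectory carries the post-mix state at the event time
  i <- which(fb$time == 0.2)
  expect_equal(fb$S[i], log$S_after)
  expect_equal(fb$V[i], 1100)
})

test_that("an event-free fed batch reduces to the batch simulation", {
  fb <- simulate_fed_batch(registry, "r-CHO", X0 = 2e5, S0 = 4.8, V0 = 1000,
                           feeds = list(), shifts = list(), t_end = 96,
                           dt = 0.1, temperature0 = 33)
  b <- simulate_batch(registry_lookup(registry, "r-CHO", 33),
                      X0 = 2e5, S0 = 4.8, t_end = 96, dt = 0.1)
  expect_equal(fb$X, b$X, tolerance = 1e-12)
  expect_equal(fb$S, b$S, tolerance = 1e-12)
  expect_true(all(fb$V == 1000))
})

test_that("temperature shifts swap parameter sets and missing entries fail fast", {
  # a shift to an unknown temperature fails before integration
  expect_error(
    simulate_fed_batch(registry, "r-CHO", 2e5, 4.8, 1000,
                       shifts = list(temperature_shift(24, 31)),
                       t_end = 48, temperature0 = 33),
    "available keys")
  # growth slows after shifting the naive line from 37 to 33 (lower mu_max)
  fb <- simulate_fed_batch(registry, "n-CHO", 2e5, 4.8, 1000,
                           shifts = list(temperature_shift(48, 33)),
                           t_end = 96, dt = 0.1, temperature0 = 37)
  expect_equal(unique(fb$temperature[fb$time < 48]), 37)
  expect_equal(unique(fb$temperature[fb$time > 48.05]), 33)
  x_at <- function(t) fb$X[which.min(abs(fb$time - t))]
  mu_before <- log(x_at(47.9) / x_at(24)) / (47.9 - 24)
  mu_after <- log(x_at(96) / x_at(49)) / (96 - 49)
  expect_gt(mu_before, mu_after)
})

test_that("the default fed-batch protocol raises volume 1.5x and prolongs production", {
  fb <- simulate_fed_batch(registry, "r-CHO", X0 = 2e5, S0 = 4.8, V0 = 1000,
                           feeds = default_feed_schedule(1000),
                           shifts = list(temperature_shift(7 * 24, 33)),
                           t_end = 480, dt = 0.1, temperature0 = 37)
  expect_equal(tail(fb$V, 1), 1500)
  b <- simulate_batch(registry_lookup(registry, "r-CHO", 37), 2e5, 4.8,
                      t_end = 240, dt = 0.1)
  expect_gt(tail(fb$P, 1), tail(b$P, 1))
})
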