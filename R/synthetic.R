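#' Measurement-noise model for synthetic datasets
#'
#' Noise is applied to sampled values after simulation, never inside the
#' ODE: it emulates assay error (flow-cytometric counting, HPLC, ELISA), not
#' process variability. Cell counts and antibody titers get multiplicative
#' lognormal noise (mean-unbiased, so the expected measurement equals the
#' simulated value); glucose and lactate get additive Gaussian noise clamped
#' at zero. The same seed always reproduces the same dataset bit for bit.
#'
#' @param cv_X Coefficient of variation for cell counts (default 0.05).
#' @param sd_S,sd_Lac Additive noise SD for glucose and lactate (g/L,
#'   default 0.05).
#' @param cv_P Coefficient of variation for antibody titers (default 0.10).
#' @param seed RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv_X = 0.05, sd_S = 0.05, sd_Lac = 0.05, cv_P = 0.10,
                        seed = 1L) {
  stopifnot(cv_X >= 0, sd_S >= 0, sd_Lac >= 0, cv_P >= 0)
  structure(list(cv_X = cv_X, sd_S = sd_S, sd_Lac = sd_Lac, cv_P = cv_P,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' A noise model with every component switched off
#' @return A `noise_model` with all noise magnitudes zero.
#' @export
no_noise <- function() noise_model(cv_X = 0, sd_S = 0, sd_Lac = 0, cv_P = 0)

lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

apply_noise <- function(series, noise) {
  n <- nrow(series)
  series$X <- series$X * lognormal_factor(n, noise$cv_X)
  if (noise$sd_S > 0) series$S <- pmax(series$S + stats::rnorm(n, 0, noise$sd_S), 0)
  if (noise$sd_Lac > 0 && any(is.finite(series$Lac))) {
    series$Lac <- pmax(series$Lac + stats::rnorm(n, 0, noise$sd_Lac), 0)
  }
  if (any(is.finite(series$P))) {
    series$P <- series$P * lognormal_factor(n, noise$cv_P)
  }
  series
}

#' Default lag time for a culture condition
#'
#' The producing line shows no lag phase; the naive line shows lags that
#' lengthen as the initial glucose concentration decreases. Defaults: 0 h at
#' full-strength medium, then 24, 48 and 72 h as the medium is diluted.
#'
#' @param cell_line `"r-CHO"` or `"n-CHO"`.
#' @param S0 Initial glucose (g/L).
#' @return Lag time (h).
#' @export
default_lag <- function(cell_line, S0) {
  if (cell_line != "n-CHO") return(0)
  if (S0 >= 4.8) 0 else if (S0 >= 3.6) 24 else if (S0 >= 2.4) 48 else 72
}

#' Batch experiment design
#'
#' The sampled batch shake-flask design: four initial glucose levels spanning
#' medium dilutions from full strength to one quarter, seeding at about
#' 2e5 cells/mL, triplicates, daily sampling, 7-day duration for the
#' producing line and 10-day for the naive line (which also gets
#' concentration-dependent lag phases by default).
#'
#' @param cell_line `"r-CHO"` or `"n-CHO"`.
#' @param temperature Culture temperature (degrees C).
#' @param S0_levels Initial glucose levels (g/L).
#' @param X0 Seeding density (cells/mL).
#' @param replicates Replicates per level (>= 1).
#' @param sampling_interval Sampling interval (h).
#' @param duration Culture duration (h); defaults to 168 (r-CHO) or 240
#'   (n-CHO).
#' @param lag Function `(cell_line, S0) -> hours` giving the lag phase;
#'   defaults to [default_lag()].
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(cell_line = "r-CHO", temperature = 33,
                              S0_levels = c(4.8, 3.6, 2.4, 1.2), X0 = 2e5,
                              replicates = 3L, sampling_interval = 24,
                              duration = NULL, lag = default_lag) {
  stopifnot(all(S0_levels > 0), replicates >= 1L, X0 > 0, sampling_interval > 0)
  if (is.null(duration)) duration <- if (cell_line == "n-CHO") 240 else 168
  structure(list(cell_line = cell_line, temperature = temperature,
                 S0_levels = S0_levels, X0 = X0,
                 replicates = as.integer(replicates),
                 sampling_interval = sampling_interval, duration = duration,
                 lag = lag),
            class = "experiment_design")
}

#' Fixture parameter sets for realistic synthetic trajectories
#'
#' The shipped registry values augmented with the scaffolding the published
#' equations do not carry but real batch trajectories show: a first-order
#' death phase after glucose depletion (`k_d = 0.01` 1/h), a maintenance
#' consumption term sized so glucose runs out around day 6 rather than
#' asymptoting at the growth threshold (`m_s = 4e-9` mg/cell/h), and a
#' two-regime lactate sub-model scaled so growth-phase production is about
#' 0.1 ng/cell/day and post-depletion consumption 0.05 ng/cell/day with peak
#' lactate below 1 g/L.
#'
#' @inheritParams get_default_parameters
#' @return A [kinetic_parameters()] object.
#' @export
fixture_parameters <- function(cell_line, temperature, source = "table2") {
  base <- get_default_parameters(cell_line, temperature, source)
  update_parameters(base, k_d = 0.01, m_s = 4e-9,
                    y_lac_x = 1.2e-7, q_lac_cons = 0.05)
}

simulate_condition <- function(design, params, S0, dt, substrate_dynamics) {
  grid <- seq(0, design$duration, by = design$sampling_interval)
  t_lag <- design$lag(design$cell_line, S0)
  lag_rows <- grid[grid < t_lag]
  post <- grid[grid >= t_lag] - t_lag
  if (substrate_dynamics) {
    sim <- simulate_batch(params, X0 = design$X0, S0 = S0,
                          t_end = max(design$duration - t_lag, dt), dt = dt,
                          temperature = design$temperature)
    idx <- vapply(post, function(tp) which.min(abs(sim$time - tp)), integer(1))
    sampled <- as.data.frame(sim)[idx, ]
  } else {
    # estimation-model-consistent trajectories: constant mu(S0) exponential
    # growth with the yield balance for glucose (no death, no maintenance)
    mu <- monod_mu(S0, params)
    X <- design$X0 * exp(mu * post)
    S <- pmax(S0 - (X - design$X0) / params$Y_xs, 0)
    prof <- data.frame(time = post, X = X, r_x = mu * X)
    P <- euler_integrate_product(prof, params, P0 = 0)
    sampled <- data.frame(X = X, S = S, P = P, Lac = NA_real_)
  }
  n_lag <- length(lag_rows)
  lac_lag <- if (all(!is.finite(sampled$Lac))) rep(NA_real_, n_lag) else rep(0, n_lag)
  data.frame(time = grid,
             X = c(rep(design$X0, n_lag), sampled$X),
             S = c(rep(S0, n_lag), sampled$S),
             Lac = c(lac_lag, sampled$Lac),
             P = c(rep(0, n_lag), sampled$P))
}

#' Generate a design-matched batch dataset
#'
#' For each initial-glucose level and replicate, simulates a batch trajectory
#' (holding the culture at its seeding state through the lag phase), samples
#' it on the design grid, and applies the measurement-noise model. The whole
#' dataset is a deterministic function of the noise seed.
#'
#' With `substrate_dynamics = FALSE` the generator instead produces
#' exponential trajectories at constant `mu(S0)` with the yield balance for
#' glucose - the generating model the log-linear/Lineweaver-Burk estimators
#' assume - which is the right fixture for exact round-trip tests.
#'
#' @param design An [experiment_design()].
#' @param params A [kinetic_parameters()] object (see [fixture_parameters()]).
#' @param noise A [noise_model()]; `NULL` or [no_noise()] for noiseless data.
#' @param dt Integration step (h).
#' @param substrate_dynamics Simulate the full ODE (default) or the
#'   constant-mu estimation model.
#' @return A list of [culture_timeseries()] objects, one per
#'   (level, replicate), each carrying attributes `S0` and `t_lag`.
#' @export
generate_batch_dataset <- function(design, params, noise = NULL, dt = 0.1,
                                   substrate_dynamics = TRUE) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "kinetic_parameters"))
  if (dt >= design$sampling_interval) {
    stop("integration step dt must be smaller than the sampling interval",
         call. = FALSE)
  }
  if (is.null(noise)) noise <- no_noise()
  noisy <- noise$cv_X > 0 || noise$sd_S > 0 || noise$sd_Lac > 0 || noise$cv_P > 0
  if (noisy) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(noise$seed)
  }
  out <- list()
  for (S0 in design$S0_levels) {
    clean <- simulate_condition(design, params, S0, dt, substrate_dynamics)
    for (rep_i in seq_len(design$replicates)) {
      d <- if (noisy) apply_noise(clean, noise) else clean
      ts <- culture_timeseries(time = d$time, X = d$X, S = d$S, Lac = d$Lac,
                               P = d$P, temperature = design$temperature,
                               cell_line = design$cell_line,
                               condition = sprintf("S0=%.3g", S0),
                               replicate = rep_i)
      attr(ts, "S0") <- S0
      attr(ts, "t_lag") <- design$lag(design$cell_line, S0)
      out[[sprintf("S0=%.3g/rep%d", S0, rep_i)]] <- ts
    }
  }
  out
}

#' Generate a design-matched fed-batch dataset
#'
#' As [generate_batch_dataset()] with [simulate_fed_batch()] underneath:
#' a single bioreactor culture with the given feed and temperature-shift
#' schedule, sampled on the design grid, with measurement noise. Default
#' duration 480 h (20 days).
#'
#' @param design An [experiment_design()]; its first `S0_level` and `X0` seed
#'   the reactor.
#' @param registry A [parameter_registry()] with entries for every scheduled
#'   temperature.
#' @param V0 Initial working volume (mL).
#' @param feeds,shifts Event schedules (see [simulate_fed_batch()]).
#' @param noise A [noise_model()] or `NULL`.
#' @param duration Culture duration (h), default 480.
#' @param dt Integration step (h).
#' @param temperature0,source Passed to [simulate_fed_batch()].
#' @return A single [culture_timeseries()] sampled on the design grid.
#' @export
generate_fedbatch_dataset <- function(design, registry, V0 = 1000,
                                      feeds = default_feed_schedule(V0),
                                      shifts = list(temperature_shift(7 * 24, 33)),
                                      noise = NULL, duration = 480, dt = 0.1,
                                      temperature0 = 37, source = "table2") {
  stopifnot(inherits(design, "experiment_design"))
  if (is.null(noise)) noise <- no_noise()
  noisy <- noise$cv_X > 0 || noise$sd_S > 0 || noise$sd_Lac > 0 || noise$cv_P > 0
  sim <- simulate_fed_batch(registry, design$cell_line, X0 = design$X0,
                            S0 = design$S0_levels[1], V0 = V0, feeds = feeds,
                            shifts = shifts, t_end = duration, dt = dt,
                            temperature0 = temperature0, source = source)
  grid <- seq(0, duration, by = design$sampling_interval)
  idx <- vapply(grid, function(tp) {
    cand <- which(abs(sim$time - tp) < 1e-6)
    if (length(cand)) cand[length(cand)] else which.min(abs(sim$time - tp))
  }, integer(1))
  d <- as.data.frame(sim)[idx, ]
  d$time <- grid
  if (noisy) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(noise$seed)
    d <- apply_noise(d, noise)
  }
  ts <- culture_timeseries(time = d$time, X = d$X, S = d$S, Lac = d$Lac,
                           P = d$P, V = d$V, temperature = d$temperature,
                           cell_line = design$cell_line,
                           condition = "fed-batch", replicate = 1L)
  attr(ts, "S0") <- design$S0_levels[1]
  ts
}

#' Analytic viable-cell fixture for production-kinetics round trips
#'
#' A smooth logistic-growth-then-first-order-decline cell profile with its
#' exact analytic growth rate, the canonical fixture for Luedeking-Piret
#' round trips: logistic rise from the seeding density towards a plateau
#' (reaching about 98 percent of it by `t_peak`), then exponential decline.
#' Because the profile mixes growth and decline, `r_x` is not proportional
#' to `X` and the direct two-parameter regression is well-conditioned.
#'
#' @param t_end Duration (h), default 240.
#' @param dt Grid step (h), default 0.1.
#' @param X0 Seeding density (cells/mL).
#' @param K Logistic plateau (cells/mL), default 7e6.
#' @param r Logistic rate (1/h), default 0.08.
#' @param t_peak Time of the growth-to-decline switch (h), default 96.
#' @param k_decline First-order decline rate (1/h), default 0.02.
#' @return A data.frame with columns `time`, `X`, `r_x`.
#' @export
lp_fixture_profile <- function(t_end = 240, dt = 0.1, X0 = 2e5, K = 7e6,
                               r = 0.08, t_peak = 96, k_decline = 0.02) {
  tt <- seq(0, t_end, by = dt)
  A <- (K - X0) / X0
  X <- numeric(length(tt)); r_x <- numeric(length(tt))
  up <- tt <= t_peak
  X[up] <- K / (1 + A * exp(-r * tt[up]))
  r_x[up] <- r * X[up] * (1 - X[up] / K)
  X_peak <- K / (1 + A * exp(-r * t_peak))
  X[!up] <- X_peak * exp(-k_decline * (tt[!up] - t_peak))
  r_x[!up] <- -k_decline * X[!up]
  data.frame(time = tt, X = X, r_x = r_x)
}

#' Write the noiseless golden fixtures
#'
#' Writes the plain-text fixtures used by the validation suite, with a
#' manifest of the generating parameters:
#' \itemize{
#'   \item `monod_mu_table.csv`: model growth rate vs initial glucose for
#'     every registry entry;
#'   \item `lp_product_profile.csv`: the [lp_fixture_profile()] viable-cell
#'     profile with the forward-Euler product curve under the producing
#'     line's constants;
#'   \item `yield_phase.csv`: a noiseless exponential-phase batch trajectory
#'     (no death, no maintenance) for the yield pipeline;
#'   \item `manifest.toml`: the generating parameter registry.
#' }
#'
#' @param path Directory to write into (created if needed).
#' @param S0_levels Glucose levels for the growth-rate table (g/L).
#' @param dt Grid step for the product profile (h).
#' @return Invisibly, the vector of files written.
#' @export
make_golden_fixtures <- function(path, S0_levels = c(4.8, 3.6, 2.4, 1.2),
                                 dt = 0.5) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  reg <- cho_parameter_registry()
  mu_rows <- list()
  for (key in names(reg)) {
    e <- reg[[key]]
    mu_rows[[key]] <- data.frame(
      cell_line = e$cell_line, temperature = e$temperature, source = e$source,
      S0 = S0_levels, mu = monod_mu(S0_levels, e$params))
  }
  mu_tab <- do.call(rbind, c(mu_rows, make.row.names = FALSE))
  f1 <- file.path(path, "monod_mu_table.csv")
  utils::write.csv(mu_tab, f1, row.names = FALSE)

  p <- registry_lookup(reg, "r-CHO", 33)
  prof <- lp_fixture_profile(dt = dt)
  prof$P <- euler_integrate_product(prof, p, P0 = 0)
  f2 <- file.path(path, "lp_product_profile.csv")
  utils::write.csv(prof, f2, row.names = FALSE)

  yield_p <- update_parameters(p, Y_xs = cho_yield_table()$Y_xs[
    cho_yield_table()$cell_line == "r-CHO" & cho_yield_table()$S0 == 4.8])
  sim <- simulate_batch(yield_p, X0 = 2e5, S0 = 4.8, t_end = 96, dt = 0.1)
  keep <- sim$time %in% seq(0, 96, by = 24)
  f3 <- file.path(path, "yield_phase.csv")
  utils::write.csv(as.data.frame(sim)[keep, c("time", "X", "S")], f3,
                   row.names = FALSE)

  f4 <- file.path(path, "manifest.toml")
  write_registry(reg, f4)
  invisible(c(f1, f2, f3, f4))
}
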