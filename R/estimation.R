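#' Select the exponential-phase window of a culture
#'
#' Scans all contiguous windows of at least `min_points` samples and returns
#' the longest one whose log-linear regression of `ln X` on time reaches the
#' requested coefficient of determination, mirroring the manual practice of
#' restricting the growth-rate fit to the initial, first-order portion of the
#' exponential phase. Ties are broken in favour of the earliest start.
#'
#' @param series A [culture_timeseries()].
#' @param min_points Minimum number of samples in a window (>= 2).
#' @param r2_floor Required r^2 of the log-linear fit (default 0.98).
#' @return `c(t_start, t_end)` of the selected window (h).
#' @export
select_exponential_window <- function(series, min_points = 3L, r2_floor = 0.98) {
  stopifnot(min_points >= 2L)
  ok <- is.finite(series$X) & series$X > 0
  tt <- series$time[ok]
  xx <- series$X[ok]
  n <- length(tt)
  if (n < min_points) {
    stop(sprintf("only %d usable samples with X > 0; need at least %d", n, min_points),
         call. = FALSE)
  }
  lx <- log(xx)
  best <- NULL
  best_len <- -Inf
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq(i + min_points - 1L, n)) {
      fit <- stats::lm.fit(cbind(1, tt[i:j]), lx[i:j])
      r2 <- r_squared_of(lx[i:j], lx[i:j] - fit$residuals)
      if (r2 >= r2_floor) {
        len <- j - i + 1L
        if (len > best_len) {   # strict: ties keep the earliest start
          best_len <- len
          best <- c(tt[i], tt[j])
        }
      }
    }
  }
  if (is.null(best)) {
    stop(sprintf(
      "no contiguous window of >= %d samples reaches r^2 >= %g on the log scale; consider a lower floor",
      min_points, r2_floor), call. = FALSE)
  }
  best
}

#' Log-linear specific growth rate
#'
#' First-order growth integrates to `ln X = mu t + ln X_0`; the specific
#' growth rate is the least-squares slope of `ln X` on time over the supplied
#' window. The r^2 is computed on the log scale and the published validity
#' gate (r^2 > 0.97) applies.
#'
#' @param series A [culture_timeseries()].
#' @param window `c(t_start, t_end)` (h); defaults to the full series.
#' @return A [fit_result()] with estimates `mu` (1/h) and `ln_X0`.
#' @export
estimate_mu_loglinear <- function(series, window = range(series$time)) {
  rows <- window_rows(series, window)
  tt <- series$time[rows]
  xx <- series$X[rows]
  keep <- is.finite(xx)
  tt <- tt[keep]; xx <- xx[keep]
  if (length(tt) < 2L) stop("need at least 2 samples in the window", call. = FALSE)
  if (any(xx <= 0)) {
    stop("all viable-cell densities in the window must be positive for a log-linear fit",
         call. = FALSE)
  }
  lx <- log(xx)
  fit <- stats::lm(lx ~ tt)
  est <- stats::coef(fit)
  fit_result(
    estimates = c(mu = unname(est[2]), ln_X0 = unname(est[1])),
    r_squared = r_squared_of(lx, stats::fitted(fit)),
    n_points = length(tt),
    residuals = unname(stats::residuals(fit)),
    gated = TRUE
  )
}

#' Lineweaver-Burk fit of the threshold-Monod parameters
#'
#' With the threshold supplied (it is estimated separately, by a low-glucose
#' growth screen), the Monod law linearizes on reciprocal coordinates:
#' \deqn{\frac{1}{\mu} = \frac{K_s}{\mu_{max}}\frac{1}{S_0 - S_t} +
#'       \frac{1}{\mu_{max}},}
#' so an ordinary regression of `1/mu` on `1/(S0 - S_t)` yields
#' `mu_max = 1/intercept` and `K_s = slope/intercept`. Points at or below the
#' threshold, or with non-positive growth, cannot appear on this plot and are
#' excluded with a warning. The published validity gate (r^2 > 0.97 on the
#' reciprocal scale) applies.
#'
#' @param mu_by_S0 A data.frame with columns `S0` (g/L) and `mu` (1/h), one
#'   row per initial-glucose condition.
#' @param S_t Threshold glucose concentration (g/L).
#' @return A [fit_result()] with estimates `mu_max` (1/h) and `K_s` (g/L).
#' @examples
#' p <- get_default_parameters("r-CHO", 33)
#' tbl <- data.frame(S0 = c(4.8, 3.6, 2.4, 1.2))
#' tbl$mu <- monod_mu(tbl$S0, p)
#' fit_monod_lineweaver_burk(tbl, S_t = p$S_t)
#' @export
fit_monod_lineweaver_burk <- function(mu_by_S0, S_t) {
  stopifnot(all(c("S0", "mu") %in% names(mu_by_S0)), S_t >= 0)
  usable <- mu_by_S0$S0 > S_t & mu_by_S0$mu > 0 &
    is.finite(mu_by_S0$S0) & is.finite(mu_by_S0$mu)
  if (any(!usable)) {
    warning(sprintf(
      "%d point(s) at or below the threshold (or with mu <= 0) excluded from the Lineweaver-Burk plot",
      sum(!usable)), call. = FALSE)
  }
  d <- mu_by_S0[usable, , drop = FALSE]
  if (nrow(d) < 3L) {
    stop("need at least 3 usable (S0 > S_t, mu > 0) points for the Lineweaver-Burk fit",
         call. = FALSE)
  }
  x <- 1 / (d$S0 - S_t)
  y <- 1 / d$mu
  fit <- stats::lm(y ~ x)
  intercept <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  if (!(intercept > 0)) {
    stop(sprintf(
      "Lineweaver-Burk intercept %.4g is not positive; no physical mu_max exists for these data",
      intercept), call. = FALSE)
  }
  fit_result(
    estimates = c(mu_max = 1 / intercept, K_s = slope / intercept),
    r_squared = r_squared_of(y, stats::fitted(fit)),
    n_points = nrow(d),
    residuals = unname(stats::residuals(fit)),
    gated = TRUE,
    details = list(intercept = intercept, slope = slope, S_t = S_t)
  )
}

#' Direct nonlinear Monod cross-check fit
#'
#' Nonlinear least squares of `mu` on `S0` under the threshold-Monod law,
#' offered as a diagnostic cross-check of the reciprocal-scale fit (which is
#' the default procedure). Not gated.
#'
#' @inheritParams fit_monod_lineweaver_burk
#' @param start Optional named start values `c(mu_max, K_s)`.
#' @return A [fit_result()] with estimates `mu_max` and `K_s`.
#' @export
fit_monod_nls <- function(mu_by_S0, S_t, start = NULL) {
  d <- mu_by_S0[mu_by_S0$S0 > S_t & mu_by_S0$mu > 0, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 usable points", call. = FALSE)
  if (is.null(start)) start <- c(mu_max = max(d$mu) * 1.2, K_s = stats::median(d$S0 - S_t))
  Sstar <- d$S0 - S_t
  fit <- stats::nls(mu ~ mu_max * Sstar / (K_s + Sstar),
                    data = data.frame(mu = d$mu, Sstar = Sstar),
                    start = as.list(start),
                    control = stats::nls.control(maxiter = 200, scaleOffset = 1))
  est <- stats::coef(fit)
  fit_result(estimates = c(mu_max = unname(est["mu_max"]), K_s = unname(est["K_s"])),
             r_squared = r_squared_of(d$mu, stats::fitted(fit)),
             n_points = nrow(d), residuals = unname(stats::residuals(fit)))
}

#' Growth screen for the threshold glucose concentration
#'
#' @param S0 Initial glucose levels screened (g/L), distinct and positive.
#' @param grew Logical: did the culture grow at that level?
#' @param mu Optional growth-rate estimates for the conditions that grew.
#' @return An object of class `growth_screen` (a data.frame).
#' @export
growth_screen <- function(S0, grew, mu = NA_real_) {
  stopifnot(length(S0) == length(grew))
  if (any(S0 <= 0)) stop("screened glucose levels must be positive", call. = FALSE)
  if (anyDuplicated(S0)) stop("screened glucose levels must be distinct", call. = FALSE)
  structure(data.frame(S0 = S0, grew = as.logical(grew), mu = mu),
            class = c("growth_screen", "data.frame"))
}

#' Threshold estimate from a growth screen
#'
#' The threshold is bracketed between the highest glucose level with no
#' growth and the lowest level with growth; the point estimate is the bracket
#' midpoint. This is the two-stage procedure's first stage: the threshold is
#' then held fixed in the Lineweaver-Burk fit.
#'
#' @param screen A [growth_screen()].
#' @return A list with `estimate` (g/L) and `bracket` (`c(lower, upper)`).
#' @examples
#' sc <- growth_screen(c(0.25, 0.45, 0.65, 1.2), c(FALSE, FALSE, TRUE, TRUE))
#' estimate_threshold(sc)  # bracket (0.45, 0.65), estimate 0.55
#' @export
estimate_threshold <- function(screen) {
  stopifnot(inherits(screen, "growth_screen"))
  no <- screen$S0[!screen$grew]
  yes <- screen$S0[screen$grew]
  if (!length(no) || !length(yes)) {
    stop("screen must contain at least one growing and one non-growing level to bracket the threshold",
         call. = FALSE)
  }
  lo <- max(no); hi <- min(yes)
  if (lo >= hi) {
    stop(sprintf(
      "inconsistent screen: no growth at %g g/L but growth at %g g/L", lo, hi),
      call. = FALSE)
  }
  list(estimate = (lo + hi) / 2, bracket = c(lo, hi))
}

#' Zero-growth glucose boundary of a parameter set
#'
#' Bisects the glucose axis for the transition between zero and positive
#' model growth rate; for the threshold-Monod law the boundary is the
#' shipped `S_t` by construction, so this is a model-consistency probe used
#' in validation.
#'
#' @param params A [kinetic_parameters()] object.
#' @param interval Search interval `c(lo, hi)` (g/L).
#' @param tol Bisection tolerance (g/L).
#' @return Boundary glucose concentration (g/L).
#' @export
zero_growth_boundary <- function(params, interval = c(0, 4.8), tol = 1e-6) {
  lo <- interval[1]; hi <- interval[2]
  if (monod_mu(lo, params) > 0) return(lo)
  if (monod_mu(hi, params) == 0) {
    stop("no growth anywhere in the interval; cannot bracket the boundary", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (monod_mu(mid, params) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Yield coefficient from rate series
#'
#' The substrate balance `r_s = r_x / Y_xs` has no intercept, so the yield is
#' the through-origin least-squares slope of the cell production rate against
#' the (sign-flipped) glucose consumption rate over the exponential phase.
#' A free-intercept variant is available for diagnostics via
#' `intercept = TRUE`; the through-origin fit is the reported procedure.
#'
#' @param rates A data.frame with columns `r_x` (cells/mL/h) and `r_s`
#'   (g/L/h, signed; negative while glucose is consumed), e.g. from
#'   [rate_series()].
#' @param intercept Fit a free intercept (diagnostic only)?
#' @return A [fit_result()] with estimate `Y_xs` (cells/mg).
#' @export
estimate_yield <- function(rates, intercept = FALSE) {
  stopifnot(all(c("r_x", "r_s") %in% names(rates)))
  keep <- is.finite(rates$r_x) & is.finite(rates$r_s)
  d <- rates[keep, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 rate points", call. = FALSE)
  if (!any(d$r_s < 0)) {
    stop("no glucose consumption in the rate series (all r_s >= 0); yield undefined",
         call. = FALSE)
  }
  x <- -d$r_s                               # consumption rate, mg/mL/h
  if (intercept) {
    fit <- stats::lm(d$r_x ~ x)
    slope <- unname(stats::coef(fit)[2])
    fitted_v <- stats::fitted(fit)
  } else {
    slope <- sum(d$r_x * x) / sum(x^2)
    fitted_v <- slope * x
  }
  ss_tot <- sum(d$r_x^2)
  r2 <- if (ss_tot <= .Machine$double.eps) 1 else 1 - sum((d$r_x - fitted_v)^2) / ss_tot
  fit_result(estimates = c(Y_xs = slope), r_squared = r2,
             n_points = nrow(d), residuals = d$r_x - fitted_v,
             details = list(intercept_fit = intercept))
}

#' Direct Luedeking-Piret fit from rate series
#'
#' Two-parameter linear least squares of the product formation rate on the
#' cell growth rate and the viable cell density, with no intercept:
#' `r_p = alpha r_x + beta X`. When the cell profile is exactly exponential,
#' `r_x` is proportional to `X` and the design matrix is rank deficient; this
#' is detected and reported as an error advising the integral fit.
#'
#' @param rates A data.frame with columns `r_p` (mg/L/h), `r_x` (cells/mL/h)
#'   and `X` (cells/mL) at common times.
#' @return A [fit_result()] with estimates `alpha` (ug/cell) and `beta`
#'   (ug/cell/h).
#' @export
fit_lp_direct <- function(rates) {
  stopifnot(all(c("r_p", "r_x", "X") %in% names(rates)))
  keep <- is.finite(rates$r_p) & is.finite(rates$r_x) & is.finite(rates$X)
  d <- rates[keep, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 time points", call. = FALSE)
  n1 <- sqrt(sum(d$r_x^2)); n2 <- sqrt(sum(d$X^2))
  if (n1 == 0 || n2 == 0) {
    stop("degenerate design: r_x or X identically zero", call. = FALSE)
  }
  sv <- svd(cbind(d$r_x / n1, d$X / n2))$d
  if (sv[2] / sv[1] < 1e-7) {
    stop(paste("r_x and X are collinear (the cell profile is exponential);",
               "the direct fit is ill-posed - use fit_lp_integral instead"),
         call. = FALSE)
  }
  fit <- stats::lm(r_p ~ 0 + r_x + X, data = d)
  est <- stats::coef(fit)
  ss_tot <- sum(d$r_p^2)
  r2 <- if (ss_tot <= .Machine$double.eps) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  fit_result(estimates = c(alpha = unname(est["r_x"]), beta = unname(est["X"])),
             r_squared = r2, n_points = nrow(d),
             residuals = unname(stats::residuals(fit)))
}

golden_section_min <- function(f, lo, hi, tol = 1e-12, maxit = 200L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  for (it in seq_len(maxit)) {
    if (b - a < tol * (1 + abs(a) + abs(b))) break
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
  }
  if (f1 < f2) c1 else c2
}

#' Integral Luedeking-Piret fit
#'
#' Chooses `alpha` and `beta` (both constrained non-negative) so that the
#' forward-Euler integration of the production law over the supplied
#' viable-cell profile best matches the observed product concentrations, in
#' the least-squares sense. The optimizer is deterministic given the starting
#' guess: coordinate descent with golden-section line searches, stopping when
#' the relative objective change over a sweep falls below `tol`.
#'
#' This mirrors the practice of tuning the two constants until the integrated
#' product curve overlays the measured titers, and remains well-posed on
#' exactly exponential cell profiles where the direct regression is not.
#'
#' @param profile A data.frame with columns `time`, `X`, `r_x` (the
#'   integration grid; see [euler_integrate_product()]).
#' @param observations A data.frame with columns `time` (h) and `P` (mg/L);
#'   at least 4 points, all inside the profile's time span.
#' @param guess Starting values `c(alpha, beta)`.
#' @param P0 Initial product concentration; defaults to the first observation.
#' @param tol Relative objective-change tolerance (default 1e-10).
#' @param max_sweeps Iteration cap; exceeding it without convergence is an
#'   error reporting the objective trace.
#' @return A [fit_result()] with estimates `alpha` and `beta`.
#' @export
fit_lp_integral <- function(profile, observations, guess = c(1e-7, 1e-8),
                            P0 = NULL, tol = 1e-10, max_sweeps = 500L) {
  stopifnot(all(c("time", "P") %in% names(observations)))
  obs <- observations[is.finite(observations$P), , drop = FALSE]
  if (nrow(obs) < 4L) stop("need at least 4 product observations", call. = FALSE)
  if (min(obs$time) < min(profile$time) - 1e-9 ||
      max(obs$time) > max(profile$time) + 1e-9) {
    stop("viable-cell profile must cover the product observation times", call. = FALSE)
  }
  if (is.null(P0)) P0 <- obs$P[which.min(obs$time)]
  predict_P <- function(alpha, beta) {
    pars <- kinetic_parameters(mu_max = 1, K_s = 1, S_t = 0, Y_xs = 1,
                               alpha = alpha, beta = beta)
    P <- euler_integrate_product(profile, pars, P0 = P0)
    stats::approx(profile$time, P, xout = obs$time)$y
  }
  objective <- function(alpha, beta) sum((predict_P(alpha, beta) - obs$P)^2)

  # scale-derived upper bounds for the line searches
  span <- max(obs$P) - min(obs$P) + max(obs$P) * 0.1 + 1e-12
  dX <- max(abs(diff(range(profile$X)))) + 1e-12
  intX <- sum(diff(profile$time) * (utils::head(profile$X, -1L) +
                                      utils::tail(profile$X, -1L)) / 2) + 1e-12
  hi_alpha <- max(10 * span / dX, 10 * guess[1], 1e-12)
  hi_beta <- max(10 * span / intX, 10 * guess[2], 1e-12)

  alpha <- min(max(guess[1], 0), hi_alpha)
  beta <- min(max(guess[2], 0), hi_beta)
  obj <- objective(alpha, beta)
  trace <- obj
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    alpha <- golden_section_min(function(a) objective(a, beta), 0, hi_alpha)
    beta <- golden_section_min(function(b) objective(alpha, b), 0, hi_beta)
    new_obj <- objective(alpha, beta)
    trace <- c(trace, new_obj)
    if (obj - new_obj <= tol * (abs(obj) + 1e-300)) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  if (!converged) {
    stop(sprintf(
      "integral Luedeking-Piret fit did not converge within %d sweeps; objective trace tail: %s",
      max_sweeps, paste(signif(utils::tail(trace, 5L), 6), collapse = ", ")),
      call. = FALSE)
  }
  fitted_v <- predict_P(alpha, beta)
  fit_result(estimates = c(alpha = alpha, beta = beta),
             r_squared = r_squared_of(obs$P, fitted_v),
             n_points = nrow(obs), residuals = obs$P - fitted_v,
             details = list(objective = obj, sweeps = sweep, P0 = P0))
}

#' Recalibrate growth and production parameters at a new temperature
#'
#' Re-fits `mu_max`, `Y_xs` and `beta` against an observed culture at a new
#' temperature while holding `S_t` and `alpha` at their base values - the
#' published procedure for transferring a 33-degree parameter set to
#' 37-degree data. The three free parameters minimize the combined squared
#' error between a batch simulation and the observed `X`, `S` and `P`
#' series, with each variable normalized by its observed maximum so the
#' cell-count scale (1e6) cannot swamp the substrate and product scales.
#'
#' @param series A [culture_timeseries()] with `X`, `S` and `P` observed.
#' @param base The starting [kinetic_parameters()] (the 33-degree set).
#' @param dt Integration step for the embedded simulations (h).
#' @param control Passed to [stats::optim()] (Nelder-Mead on log scale).
#' @return A `kinetic_parameters` object: `base` with `mu_max`, `Y_xs`,
#'   `beta` replaced; the optimizer diagnostics are in attribute `fit`.
#' @export
recalibrate_at_temperature <- function(series, base, dt = 0.25,
                                       control = list(maxit = 4000, reltol = 1e-12)) {
  stopifnot(inherits(base, "kinetic_parameters"))
  obs_t <- series$time
  need <- c("X", "S", "P")
  for (nm in need) {
    if (all(!is.finite(series[[nm]]))) {
      stop("recalibration needs observed X, S and P; '", nm, "' is all missing",
           call. = FALSE)
    }
  }
  X0 <- series$X[1]; S0 <- series$S[1]
  P0 <- if (is.finite(series$P[1])) series$P[1] else 0
  t_end <- max(obs_t)
  norms <- vapply(need, function(nm) max(series[[nm]], na.rm = TRUE), numeric(1))
  norms[norms <= 0] <- 1
  sim_error <- function(theta) {
    cand <- update_parameters(base, mu_max = exp(theta[1]), Y_xs = exp(theta[2]),
                              beta = exp(theta[3]))
    sim <- simulate_batch(cand, X0 = X0, S0 = S0, t_end = t_end, dt = dt, P0 = P0)
    err <- 0
    for (nm in need) {
      pred <- stats::approx(sim$time, sim[[nm]], xout = obs_t)$y
      ok <- is.finite(series[[nm]])
      err <- err + sum(((pred[ok] - series[[nm]][ok]) / norms[[nm]])^2)
    }
    if (!is.finite(err)) err <- 1e12
    err
  }
  beta0 <- if (base$beta > 0) base$beta else 1e-9
  theta0 <- log(c(base$mu_max, base$Y_xs, beta0))
  opt <- stats::optim(theta0, sim_error, method = "Nelder-Mead", control = control)
  if (opt$convergence != 0 || !is.finite(opt$value)) {
    stop("temperature recalibration optimizer failed (code ", opt$convergence,
         "); base parameters retained", call. = FALSE)
  }
  out <- update_parameters(base, mu_max = exp(opt$par[1]), Y_xs = exp(opt$par[2]),
                           beta = exp(opt$par[3]))
  attr(out, "fit") <- list(objective = opt$value, counts = opt$counts)
  out
}

#' Growth-stage estimation pipeline over a batch dataset
#'
#' Runs the standard growth analysis on a collection of replicated batch
#' cultures: per-replicate exponential-window selection and log-linear
#' growth-rate fit, per-condition averaging, and the Lineweaver-Burk
#' threshold-Monod fit across initial glucose levels.
#'
#' Per-replicate growth-rate fits that fail the published r^2 > 0.97 validity
#' rule are excluded before the per-condition averaging (`gate = TRUE`),
#' exactly as only valid linear regressions were carried forward in the
#' original procedure; if gating would leave fewer than three glucose levels,
#' all fits are kept and a warning is issued. When no window in a replicate
#' reaches the r^2 floor, the replicate falls back to the best-r^2 window of
#' `min_points` samples, so one noisy triplicate member does not abort a
#' whole screen.
#'
#' The default `min_points = 5` asks for at least five daily samples
#' (four days) in the growth-rate window: with an exponential phase of about
#' five days, shorter windows make the r^2 criterion nearly vacuous and the
#' slope estimate unstable.
#'
#' @param dataset A list of [culture_timeseries()] objects with `condition`
#'   attributes encoding the initial glucose level (numeric `S0` attribute
#'   set by the generator, or parsed from the condition label).
#' @param S_t Threshold used in the Lineweaver-Burk stage (g/L).
#' @param min_points,r2_floor Window-selection settings.
#' @param gate Apply the r^2 > 0.97 validity rule to per-replicate fits?
#' @return A list with `mu_table` (S0, mean mu, n replicates), `per_replicate`
#'   (all per-replicate fits with their validity flags) and `monod_fit`
#'   (a [fit_result()]).
#' @export
estimate_growth_parameters <- function(dataset, S_t, min_points = 5L,
                                       r2_floor = 0.98, gate = TRUE) {
  per <- lapply(dataset, function(ts) {
    S0 <- attr(ts, "S0")
    if (is.null(S0)) S0 <- suppressWarnings(as.numeric(sub(".*=", "", attr(ts, "condition"))))
    win <- tryCatch(
      select_exponential_window(ts, min_points = min_points, r2_floor = r2_floor),
      error = function(e) best_effort_window(ts, min_points)
    )
    fit <- estimate_mu_loglinear(ts, win)
    data.frame(S0 = S0, replicate = attr(ts, "replicate"),
               mu = unname(fit$estimates["mu"]), r_squared = fit$r_squared,
               valid = fit$valid, t_start = win[1], t_end = win[2])
  })
  per <- do.call(rbind, per)
  used <- if (gate) per[per$valid, , drop = FALSE] else per
  if (gate && length(unique(used$S0)) < 3L) {
    warning("fewer than 3 glucose levels have valid growth-rate fits; using all fits",
            call. = FALSE)
    used <- per
  }
  mu_table <- stats::aggregate(mu ~ S0, data = used, FUN = mean)
  mu_table$n <- stats::aggregate(mu ~ S0, data = used, FUN = length)$mu
  monod_fit <- fit_monod_lineweaver_burk(mu_table, S_t = S_t)
  list(mu_table = mu_table[order(-mu_table$S0), ],
       per_replicate = per, monod_fit = monod_fit)
}

# longest-window fallback: best log-linear r^2 among windows of exactly
# min_points samples starting anywhere (used only when the floor is unmet)
best_effort_window <- function(series, min_points) {
  ok <- is.finite(series$X) & series$X > 0
  tt <- series$time[ok]; lx <- log(series$X[ok])
  n <- length(tt)
  if (n < min_points) stop("not enough positive samples", call. = FALSE)
  best <- c(tt[1], tt[min_points]); best_r2 <- -Inf
  for (i in seq_len(n - min_points + 1L)) {
    j <- i + min_points - 1L
    fit <- stats::lm.fit(cbind(1, tt[i:j]), lx[i:j])
    r2 <- r_squared_of(lx[i:j], lx[i:j] - fit$residuals)
    if (r2 > best_r2) { best_r2 <- r2; best <- c(tt[i], tt[j]) }
  }
  best
}
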