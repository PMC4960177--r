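#' Polynomial smoothing of a measured profile
#'
#' Measured concentration profiles are smoothed by ordinary least-squares
#' polynomials over a stated time window, and rates are obtained by analytic
#' differentiation of the fitted polynomial (see [differentiate()]). The
#' conventional choices are degree 2 for the exponential-phase cell and
#' glucose profiles, and degree 6 for the full-culture cell profile used in
#' production fitting.
#'
#' Internally the polynomial basis is centred at the window midpoint; the
#' `center` field records the shift. This is purely numerical conditioning
#' (raw powers of times up to a few hundred hours at degree 6 are badly
#' scaled) and does not change the fitted curve.
#'
#' @param series A [culture_timeseries()].
#' @param variable One of `"X"`, `"S"`, `"Lac"`, `"P"`.
#' @param degree Polynomial degree (>= 1).
#' @param window `c(t_start, t_end)` in hours; defaults to the full series.
#' @return An object of class `smoothed_profile`.
#' @export
fit_polynomial_window <- function(series, variable = "X", degree = 2L,
                                  window = range(series$time)) {
  stopifnot(variable %in% c("X", "S", "Lac", "P"), degree >= 1L)
  rows <- window_rows(series, window)
  tt <- series$time[rows]
  yy <- series[[variable]][rows]
  keep <- is.finite(yy) & is.finite(tt)
  tt <- tt[keep]; yy <- yy[keep]
  if (length(tt) < degree + 1L) {
    stop(sprintf(
      "window [%g, %g] h has %d non-missing '%s' points; a degree-%d polynomial needs at least %d",
      window[1], window[2], length(tt), variable, degree, degree + 1L), call. = FALSE)
  }
  center <- mean(window)
  tau <- tt - center
  fit <- stats::lm(yy ~ stats::poly(tau, degree = degree, raw = TRUE))
  coefs <- unname(stats::coef(fit))
  coefs[is.na(coefs)] <- 0
  structure(
    list(variable = variable, coefficients = coefs, center = center,
         window = as.numeric(window),
         r_squared = r_squared_of(yy, stats::fitted(fit)),
         n_points = length(tt)),
    class = "smoothed_profile"
  )
}

#' Construct a smoothed profile from known coefficients
#'
#' @param coefficients Polynomial coefficients, ascending degree, in the
#'   (possibly centred) time variable `t - center`.
#' @param window `c(t_start, t_end)` validity window (h).
#' @param variable Variable name the polynomial describes.
#' @param r_squared Goodness of fit; 1 for an exact polynomial.
#' @param center Time shift of the polynomial basis (h); 0 for raw time.
#' @return A `smoothed_profile`.
#' @export
smoothed_profile <- function(coefficients, window, variable = "X",
                             r_squared = 1, center = 0) {
  stopifnot(length(coefficients) >= 1L, length(window) == 2L)
  structure(
    list(variable = variable, coefficients = as.numeric(coefficients),
         center = center, window = as.numeric(window),
         r_squared = r_squared, n_points = NA_integer_),
    class = "smoothed_profile"
  )
}

#' @export
print.smoothed_profile <- function(x, ...) {
  cat(sprintf("Degree-%d polynomial smooth of '%s' on [%g, %g] h (r^2 = %.5f)\n",
              length(x$coefficients) - 1L, x$variable,
              x$window[1], x$window[2], x$r_squared))
  invisible(x)
}

#' Evaluate a smoothed profile
#'
#' @param profile A `smoothed_profile`.
#' @param times Times (h) inside the fit window.
#' @return Fitted values at `times`.
#' @export
evaluate_profile <- function(profile, times) {
  check_in_window(profile, times)
  tau <- times - profile$center
  horner(profile$coefficients, tau)
}

#' Analytic derivative of a smoothed profile
#'
#' Differentiates the fitted polynomial exactly and evaluates it at the
#' requested times. Evaluation outside the fit window is an error: the
#' derivative of a high-degree polynomial diverges off-window and must never
#' be extrapolated.
#'
#' @param profile A `smoothed_profile`.
#' @param times Times (h) inside the fit window.
#' @return Derivative values at `times` (units of the variable per hour).
#' @examples
#' p <- smoothed_profile(c(1, 2, 3), window = c(0, 10))
#' differentiate(p, 2)  # d/dt (1 + 2t + 3t^2) at t = 2 -> 14
#' @export
differentiate <- function(profile, times) {
  check_in_window(profile, times)
  cf <- profile$coefficients
  if (length(cf) == 1L) return(rep(0, length(times)))
  dcf <- cf[-1] * seq_len(length(cf) - 1L)
  horner(dcf, times - profile$center)
}

check_in_window <- function(profile, times) {
  stopifnot(inherits(profile, "smoothed_profile"))
  w <- profile$window
  if (any(times < w[1] - 1e-9 | times > w[2] + 1e-9)) {
    stop(sprintf("times outside the fit window [%g, %g] h; refusing to extrapolate",
                 w[1], w[2]), call. = FALSE)
  }
  invisible(TRUE)
}

horner <- function(coefs, x) {
  out <- rep(coefs[length(coefs)], length(x))
  if (length(coefs) > 1L) {
    for (k in rev(seq_len(length(coefs) - 1L))) out <- out * x + coefs[k]
  }
  out
}

#' Rate series from polynomial smooths
#'
#' Convenience wrapper building the time-aligned derivative series
#' (`r_x`, `r_s`, and optionally `r_p`) from per-variable polynomial smooths
#' over a common window. `r_s` is kept signed (negative while glucose is
#' consumed); presentation layers flip the sign for reporting specific
#' consumption as positive.
#'
#' @param series A [culture_timeseries()].
#' @param window `c(t_start, t_end)` (h).
#' @param degree_X,degree_S,degree_P Polynomial degrees per variable.
#' @param times Evaluation times; defaults to the sampled times in the window.
#' @param include_P Also differentiate the product profile?
#' @return A data.frame with columns `time`, `X` (smoothed), `r_x`, `r_s`
#'   (and `r_p`), carrying the smooths as attribute `profiles`.
#' @export
rate_series <- function(series, window = range(series$time),
                        degree_X = 2L, degree_S = 2L, degree_P = 2L,
                        times = NULL, include_P = FALSE) {
  if (is.null(times)) times <- series$time[window_rows(series, window)]
  px <- fit_polynomial_window(series, "X", degree_X, window)
  ps <- fit_polynomial_window(series, "S", degree_S, window)
  out <- data.frame(time = times,
                    X = evaluate_profile(px, times),
                    r_x = differentiate(px, times),
                    r_s = differentiate(ps, times))
  profiles <- list(X = px, S = ps)
  if (include_P) {
    pp <- fit_polynomial_window(series, "P", degree_P, window)
    out$r_p <- differentiate(pp, times)
    profiles$P <- pp
  }
  attr(out, "profiles") <- profiles
  out
}

#' Integral of viable cell concentration
#'
#' Trapezoidal integral of the viable cell density over a window (IVCC,
#' cell h/mL): the normalizer that turns volumetric concentration changes
#' into per-cell ("specific") rates. Additive over adjacent windows.
#'
#' @param series A [culture_timeseries()].
#' @param window `c(t_start, t_end)` (h); defaults to the full series.
#' @return IVCC in cell h/mL.
#' @export
integral_viable_cells <- function(series, window = range(series$time)) {
  rows <- window_rows(series, window)
  tt <- series$time[rows]
  xx <- series$X[rows]
  keep <- is.finite(xx)
  tt <- tt[keep]; xx <- xx[keep]
  if (length(tt) < 2L) {
    stop(sprintf("window [%g, %g] h has fewer than 2 viable-cell samples",
                 window[1], window[2]), call. = FALSE)
  }
  sum(diff(tt) * (utils::head(xx, -1L) + utils::tail(xx, -1L)) / 2)
}

#' Culture phase window
#'
#' A labelled time window used to split a culture into metabolic phases
#' (e.g. exponential growth, late exponential, post-depletion). Phase
#' boundaries are an analyst's choice; [suggest_phase_boundary()] offers a
#' heuristic but is never applied silently.
#'
#' @param label Phase label, e.g. `"I"`.
#' @param window `c(t_start, t_end)` (h).
#' @return An object of class `culture_phase`.
#' @export
culture_phase <- function(label, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  structure(list(label = label, window = as.numeric(window)),
            class = "culture_phase")
}

#' Heuristic phase boundary: smoothed glucose-depletion time
#'
#' Suggests the time at which smoothed glucose first drops below a cutoff
#' (default: the model threshold is a natural choice), as a candidate
#' boundary between the consumption and post-depletion phases. A convenience
#' only; phase windows remain the caller's decision.
#'
#' @param series A [culture_timeseries()].
#' @param cutoff Glucose level (g/L) defining depletion.
#' @param degree Smoothing degree for the glucose profile.
#' @return Suggested boundary time (h), or `NA` if glucose never crosses.
#' @export
suggest_phase_boundary <- function(series, cutoff = 0.1, degree = 2L) {
  ps <- fit_polynomial_window(series, "S", degree, range(series$time))
  grid <- seq(min(series$time), max(series$time), length.out = 481L)
  sm <- evaluate_profile(ps, grid)
  below <- which(sm < cutoff)
  if (!length(below)) return(NA_real_)
  grid[below[1]]
}

#' Specific (per-cell) consumption or production rate over a phase
#'
#' The concentration change over the phase divided by the integral of viable
#' cells, converted to a per-day rate:
#' \deqn{q = \frac{C(t_{end}) - C(t_{start})}{IVCC},}
#' reported with the conventional signs and units:
#' \itemize{
#'   \item glucose (`"S"`): consumption positive, ng/cell/day;
#'   \item lactate (`"Lac"`): production positive, consumption negative,
#'     ng/cell/day;
#'   \item antibody (`"P"`): production positive, pg/cell/day.
#' }
#'
#' @param series A [culture_timeseries()].
#' @param variable One of `"S"`, `"Lac"`, `"P"`.
#' @param phase A [culture_phase()] or a plain `c(t_start, t_end)` window.
#' @return Specific rate (ng/cell/day; pg/cell/day for antibody).
#' @examples
#' ts <- culture_timeseries(time = c(0, 24), X = 2e6, S = c(1.0, 0.6))
#' specific_rate(ts, "S", c(0, 24))  # 0.2 ng/cell/day consumed
#' @export
specific_rate <- function(series, variable, phase) {
  stopifnot(variable %in% c("S", "Lac", "P"))
  window <- if (inherits(phase, "culture_phase")) phase$window else as.numeric(phase)
  rows <- window_rows(series, window)
  tt <- series$time[rows]
  cc <- series[[variable]][rows]
  keep <- is.finite(cc)
  if (sum(keep) < 2L) {
    stop("phase must contain at least 2 non-missing samples of ", variable,
         call. = FALSE)
  }
  tt <- tt[keep]; cc <- cc[keep]
  ivcc <- integral_viable_cells(series, window)
  if (ivcc <= 0) stop("IVCC is zero over the phase; specific rate undefined", call. = FALSE)
  dC <- cc[length(cc)] - cc[1]            # g/L == mg/mL (or mg/L == ug/mL for P)
  q_per_h <- dC / ivcc                    # mg (or ug) per cell per hour
  q_per_day <- q_per_h * 24
  if (variable == "S") {
    -q_per_day * 1e6                      # mg -> ng; consumption positive
  } else if (variable == "Lac") {
    q_per_day * 1e6                       # mg -> ng; production positive
  } else {
    q_per_day * 1e6                       # ug -> pg; production positive
  }
}
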