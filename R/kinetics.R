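#' Threshold-modified Monod specific growth rate
#'
#' The specific growth rate follows Monod saturation kinetics in the glucose
#' concentration in excess of a threshold `S_t` below which no growth is
#' observed:
#' \deqn{\mu(S) = \mu_{max} \frac{S - S_t}{K_s + (S - S_t)} \quad (S > S_t),
#'       \qquad \mu(S) = 0 \quad (S \le S_t).}
#' The function is continuous at the threshold, non-decreasing in `S`, and
#' approaches `mu_max` from below as `S` grows.
#'
#' @param S Glucose concentration(s), g/L. Must be non-negative.
#' @param params A [kinetic_parameters()] object.
#' @return Specific growth rate(s), 1/h, in `[0, mu_max)`.
#' @examples
#' p <- get_default_parameters("r-CHO", 33)
#' monod_mu(c(0.58, 1.244, 4.8), p)
#' @export
monod_mu <- function(S, params) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (any(S < 0, na.rm = TRUE)) {
    stop("glucose concentration must be non-negative", call. = FALSE)
  }
  S_star <- S - params$S_t
  out <- ifelse(S > params$S_t,
                params$mu_max * S_star / (params$K_s + S_star),
                0)
  out[is.na(S)] <- NA_real_
  out
}

#' Luedeking-Piret product formation rate
#'
#' Mixed-mode production kinetics: the volumetric antibody formation rate is
#' the sum of a growth-associated term and a biomass-associated term,
#' \deqn{r_p = \alpha\, r_x + \beta\, X.}
#' With the package's canonical units (`alpha` ug/cell, `beta` ug/cell/h,
#' `r_x` cells/mL/h, `X` cells/mL) the result is in ug/mL/h, identical to
#' mg/L/h, with no conversion factor.
#'
#' `r_x` may be negative during the death phase; by default the literal model
#' is applied and a declining population reduces `r_p`. Set `clamp_rx = TRUE`
#' to floor the growth-associated term at zero instead.
#'
#' @param r_x Cell growth rate (cells/mL/h); may be negative.
#' @param X Viable cell density (cells/mL), non-negative.
#' @param params A [kinetic_parameters()] object supplying `alpha` and `beta`.
#' @param clamp_rx If `TRUE`, use `max(r_x, 0)` in the growth-associated term.
#' @return Product formation rate, mg/L/h.
#' @export
luedeking_piret_rate <- function(r_x, X, params, clamp_rx = FALSE) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (any(X < 0, na.rm = TRUE)) {
    stop("viable cell density must be non-negative", call. = FALSE)
  }
  if (clamp_rx) r_x <- pmax(r_x, 0)
  params$alpha * r_x + params$beta * X
}

#' Forward-Euler integration of the Luedeking-Piret equation
#'
#' Steps the product balance over a sampled viable-cell profile:
#' \deqn{P_n = P_{n-1} + (\alpha r_{x,n-1} + \beta X_{n-1})\,\Delta t,}
#' with the left-endpoint rate, so the growth-associated contribution
#' telescopes to `alpha * (X_n - X_0)` when `r_x` is supplied as forward
#' finite differences of `X`. The product is clamped at zero (no degradation
#' model; a negative concentration is unphysical).
#'
#' @param profile A data.frame with columns `time` (h, strictly increasing),
#'   `X` (cells/mL) and `r_x` (cells/mL/h).
#' @param params A [kinetic_parameters()] object supplying `alpha` and `beta`.
#' @param P0 Initial product concentration (mg/L), non-negative.
#' @param clamp_rx Passed to [luedeking_piret_rate()].
#' @return Numeric vector of product concentrations (mg/L) aligned with
#'   `profile$time`.
#' @export
euler_integrate_product <- function(profile, params, P0 = 0, clamp_rx = FALSE) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (is.null(profile) || nrow(profile) == 0L) {
    stop("empty viable-cell profile", call. = FALSE)
  }
  req <- c("time", "X", "r_x")
  if (!all(req %in% names(profile))) {
    stop("profile must have columns time, X, r_x", call. = FALSE)
  }
  if (P0 < 0) stop("P0 must be non-negative", call. = FALSE)
  tt <- profile$time
  if (length(tt) > 1L && any(diff(tt) <= 0)) {
    stop("profile times must be strictly increasing", call. = FALSE)
  }
  n <- length(tt)
  if (n == 1L) return(P0)
  dt <- diff(tt)
  rate <- luedeking_piret_rate(profile$r_x, profile$X, params, clamp_rx = clamp_rx)
  incr <- rate[-n] * dt
  P <- P0 + c(0, cumsum(incr))
  if (any(P < 0)) {
    # re-step with the clamp active; only needed when increments go negative
    P <- numeric(n)
    P[1] <- P0
    for (i in 2:n) P[i] <- max(P[i - 1] + incr[i - 1], 0)
  }
  P
}
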