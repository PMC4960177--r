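#' Feed event for a fed-batch culture
#'
#' An intermittent bolus addition of cell-free, product-free feed medium,
#' characterized by its glucose concentration only. At the event the vessel
#' volume increases and every concentration is diluted by the mixing balance
#' `C <- (C V + C_feed V_f) / (V + V_f)`, with `C_feed = 0` for cells,
#' product and lactate.
#'
#' @param time Event time (h).
#' @param volume Volume added (mL), > 0.
#' @param glucose Feed glucose concentration (g/L).
#' @return An object of class `feed_event`.
#' @export
feed_event <- function(time, volume, glucose) {
  stopifnot(volume > 0, glucose >= 0, time >= 0)
  structure(list(time = time, volume = volume, glucose = glucose),
            class = "feed_event")
}

#' Temperature shift event
#'
#' At the event the kinetic parameter set switches to the registry entry for
#' the new temperature; the registry must contain that entry, which is
#' checked before integration starts.
#'
#' @param time Event time (h).
#' @param temperature New culture temperature (degrees C).
#' @return An object of class `temperature_shift`.
#' @export
temperature_shift <- function(time, temperature) {
  stopifnot(time >= 0)
  structure(list(time = time, temperature = temperature),
            class = "temperature_shift")
}

#' Default fed-batch feed schedule
#'
#' Five daily bolus additions of 10 percent of the initial working volume on
#' days 1-5. The feed glucose concentration defaults to 45 g/L, a typical
#' level for concentrated commercial CHO feed media (the published protocol
#' names the feed but not its glucose content).
#'
#' @param V0 Initial working volume (mL).
#' @param glucose Feed glucose concentration (g/L).
#' @param days Feed days.
#' @return A list of [feed_event()]s.
#' @export
default_feed_schedule <- function(V0, glucose = 45, days = 1:5) {
  lapply(days, function(d) feed_event(time = d * 24, volume = 0.1 * V0,
                                      glucose = glucose))
}

# --- core fixed-step integrator --------------------------------------------

# state = c(X, S, P, Lac); params fixed within a segment
culture_derivs <- function(state, p, lactate) {
  X <- state[1]; S <- state[2]
  S_star <- S - p$S_t
  mu <- if (S > p$S_t) p$mu_max * S_star / (p$K_s + S_star) else 0
  growth <- mu * X
  death <- if (S <= p$S_t) p$k_d * X else 0
  dX <- growth - death
  dS <- -growth / p$Y_xs - p$m_s * X
  dP <- p$alpha * dX + p$beta * X
  dLac <- if (!lactate) 0
  else if (S > p$S_t) p$y_lac_x * growth
  else -(p$q_lac_cons * 1e-6 / 24) * X    # ng/cell/day -> mg/cell/h
  c(dX, dS, dP, dLac)
}

clamp_state <- function(state) {
  # X, S, P, Lac are all concentrations; negatives are integration artefacts
  pmax(state, 0)
}

integrate_segment <- function(state0, t0, t1, dt, p, method, lactate) {
  if (t1 <= t0 + 1e-12) {
    return(list(time = numeric(0), states = matrix(numeric(0), ncol = 4L)))
  }
  n_steps <- max(1L, round((t1 - t0) / dt))
  # keep the grid uniform; the last step absorbs rounding
  times <- t0 + (seq_len(n_steps)) * ((t1 - t0) / n_steps)
  h <- (t1 - t0) / n_steps
  states <- matrix(NA_real_, nrow = n_steps, ncol = 4L)
  s <- state0
  for (i in seq_len(n_steps)) {
    if (method == "euler") {
      s <- s + h * culture_derivs(s, p, lactate)
    } else {
      k1 <- culture_derivs(s, p, lactate)
      k2 <- culture_derivs(s + h / 2 * k1, p, lactate)
      k3 <- culture_derivs(s + h / 2 * k2, p, lactate)
      k4 <- culture_derivs(s + h * k3, p, lactate)
      s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    s <- clamp_state(s)
    if (any(!is.finite(s))) {
      stop(sprintf(
        "non-finite state at t = %.3f h (step %d of %d): X=%g S=%g P=%g Lac=%g",
        times[i], i, n_steps, s[1], s[2], s[3], s[4]), call. = FALSE)
    }
    states[i, ] <- s
  }
  list(time = times, states = states)
}

#' Simulate a batch culture
#'
#' Integrates the coupled balances
#' \deqn{dX/dt = \mu(S) X - k_d X \mathbf{1}[S \le S_t], \quad
#'       dS/dt = -\mu(S) X / Y_{x/s} - m_s X, \quad
#'       dP/dt = \alpha\, dX/dt + \beta X,}
#' with `mu(S)` the threshold-Monod law, by fixed-step 4th-order Runge-Kutta
#' (default) or forward Euler. Substrate, product and lactate are clamped at
#' zero. With the optional lactate sub-model, lactate is produced in
#' proportion to growth while glucose is above the threshold and consumed at
#' a constant specific rate after depletion.
#'
#' With `k_d = m_s = 0` the linear invariant `X + Y_xs S` is conserved
#' exactly by both integrators, so `X - X0 = Y_xs (S0 - S)` holds at every
#' output time up to floating-point error.
#'
#' @param params A [kinetic_parameters()] object.
#' @param X0 Inoculum density (cells/mL), > 0.
#' @param S0 Initial glucose (g/L), >= 0.
#' @param t_end Duration (h).
#' @param dt Integration step (h), default 0.1.
#' @param P0,Lac0 Initial product (mg/L) and lactate (g/L).
#' @param method `"rk4"` (default) or `"euler"`.
#' @param lactate Integrate the lactate sub-model? Requires `y_lac_x` and
#'   `q_lac_cons` in `params`. Default: on when both are set.
#' @param temperature Temperature label stored in the output (degrees C).
#' @return A [culture_timeseries()] on the integration grid (first row is the
#'   initial condition).
#' @export
simulate_batch <- function(params, X0, S0, t_end, dt = 0.1, P0 = 0, Lac0 = 0,
                           method = c("rk4", "euler"), lactate = NULL,
                           temperature = NA_real_) {
  method <- match.arg(method)
  stopifnot(inherits(params, "kinetic_parameters"))
  if (!(X0 > 0)) stop("X0 must be positive", call. = FALSE)
  if (S0 < 0) stop("S0 must be non-negative", call. = FALSE)
  if (!(dt > 0)) stop("dt must be positive", call. = FALSE)
  if (dt > t_end) stop("dt exceeds the simulation span", call. = FALSE)
  if (is.null(lactate)) {
    lactate <- is.finite(params$y_lac_x) && is.finite(params$q_lac_cons)
  }
  if (lactate && (!is.finite(params$y_lac_x) || !is.finite(params$q_lac_cons))) {
    stop("lactate sub-model requested but y_lac_x / q_lac_cons are not set",
         call. = FALSE)
  }
  seg <- integrate_segment(c(X0, S0, P0, if (lactate) Lac0 else 0),
                           0, t_end, dt, params, method, lactate)
  culture_timeseries(
    time = c(0, seg$time),
    X = c(X0, seg$states[, 1]),
    S = c(S0, seg$states[, 2]),
    P = c(P0, seg$states[, 3]),
    Lac = if (lactate) c(Lac0, seg$states[, 4]) else NA_real_,
    temperature = temperature
  )
}

#' Simulate a fed-batch culture
#'
#' Between events the dynamics are identical to [simulate_batch()]. At a
#' [feed_event()] the vessel volume increases and all concentrations are
#' updated by the mixing balance (glucose gains feed substrate; cells,
#' product and lactate are diluted). At a [temperature_shift()] the kinetic
#' parameters swap to the registry entry for the new temperature. All
#' registry entries needed by the schedule are resolved before integration
#' starts, so a missing entry fails fast.
#'
#' @param registry A [parameter_registry()].
#' @param cell_line Cell line whose registry entries to use.
#' @param X0,S0 Initial cell density (cells/mL) and glucose (g/L).
#' @param V0 Initial working volume (mL), > 0.
#' @param feeds List of [feed_event()]s, sorted by time.
#' @param shifts List of [temperature_shift()]s, sorted by time.
#' @param t_end Duration (h).
#' @param dt Integration step (h).
#' @param temperature0 Starting temperature (degrees C); must have a registry
#'   entry.
#' @param source Registry source tag.
#' @param P0,Lac0,method,lactate As in [simulate_batch()].
#' @return A [culture_timeseries()] including the volume profile `V` (mL) and
#'   the active `temperature`. The row recorded at a feed time carries the
#'   post-mix state; attribute `feed_log` is a data.frame with the exact
#'   pre- and post-mix states and volumes at every feed event.
#' @export
simulate_fed_batch <- function(registry, cell_line, X0, S0, V0,
                               feeds = list(), shifts = list(),
                               t_end, dt = 0.1, temperature0 = 37,
                               source = "table2", P0 = 0, Lac0 = 0,
                               method = c("rk4", "euler"), lactate = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(registry, "parameter_registry"), V0 > 0)
  if (inherits(feeds, "feed_event")) feeds <- list(feeds)
  if (inherits(shifts, "temperature_shift")) shifts <- list(shifts)
  # resolve every parameter set up front: a missing entry must fail before
  # any integration happens
  params_at <- list()
  params_at[[as.character(temperature0)]] <-
    registry_lookup(registry, cell_line, temperature0, source)
  for (sh in shifts) {
    stopifnot(inherits(sh, "temperature_shift"))
    params_at[[as.character(sh$temperature)]] <-
      registry_lookup(registry, cell_line, sh$temperature, source)
  }
  for (fd in feeds) stopifnot(inherits(fd, "feed_event"))
  events <- c(
    lapply(feeds, function(f) list(time = f$time, kind = "feed", event = f)),
    lapply(shifts, function(s) list(time = s$time, kind = "shift", event = s))
  )
  ev_times <- vapply(events, `[[`, numeric(1), "time")
  if (is.unsorted(ev_times)) {
    stop("feed and shift events must be supplied sorted by time", call. = FALSE)
  }
  events <- events[order(ev_times)]
  p <- params_at[[as.character(temperature0)]]
  if (is.null(lactate)) lactate <- is.finite(p$y_lac_x) && is.finite(p$q_lac_cons)

  temp_now <- temperature0
  state <- c(X0, S0, P0, if (lactate) Lac0 else 0)
  event_log <- list()
  V <- V0
  t_now <- 0
  time_out <- 0
  states_out <- matrix(state, nrow = 1L)
  V_out <- V
  temp_out <- temp_now

  step_to <- function(t_target) {
    seg <- integrate_segment(state, t_now, t_target, dt, p, method, lactate)
    if (length(seg$time)) {
      time_out <<- c(time_out, seg$time)
      states_out <<- rbind(states_out, seg$states)
      V_out <<- c(V_out, rep(V, length(seg$time)))
      temp_out <<- c(temp_out, rep(temp_now, length(seg$time)))
      state <<- seg$states[nrow(seg$states), ]
    }
    t_now <<- t_target
  }

  for (ev in events) {
    if (ev$time > t_end) break
    step_to(ev$time)
    if (ev$kind == "feed") {
      f <- ev$event
      Vf <- f$volume
      before <- state; V_before <- V
      mix <- V / (V + Vf)
      state[1] <- state[1] * mix                                 # cells: feed is cell-free
      state[2] <- (state[2] * V + f$glucose * Vf) / (V + Vf)     # glucose
      state[3] <- state[3] * mix                                 # product
      if (lactate) state[4] <- state[4] * mix
      V <- V + Vf
      event_log[[length(event_log) + 1L]] <- data.frame(
        time = t_now, volume_added = Vf, feed_glucose = f$glucose,
        V_before = V_before, V_after = V,
        X_before = before[1], X_after = state[1],
        S_before = before[2], S_after = state[2],
        P_before = before[3], P_after = state[3])
      # overwrite the event-time record with the post-mix state so the
      # output carries the dilution discontinuity
      time_out <- c(time_out, t_now)
      states_out <- rbind(states_out, state)
      V_out <- c(V_out, V)
      temp_out <- c(temp_out, temp_now)
    } else {
      temp_now <- ev$event$temperature
      p <- params_at[[as.character(temp_now)]]
    }
  }
  step_to(t_end)

  # collapse duplicate time stamps at feed events (keep the post-mix row)
  keep <- rev(!duplicated(rev(time_out)))
  out <- culture_timeseries(
    time = time_out[keep],
    X = states_out[keep, 1],
    S = states_out[keep, 2],
    P = states_out[keep, 3],
    Lac = if (lactate) states_out[keep, 4] else NA_real_,
    V = V_out[keep],
    temperature = temp_out[keep],
    cell_line = cell_line
  )
  attr(out, "feed_log") <- if (length(event_log)) do.call(rbind, event_log) else NULL
  out
}
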