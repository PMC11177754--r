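# Control law: nonlinear error shaping -> parallel PID -> output limiter,
# executed on a fixed update grid against a low-pass filtered MAP signal.

#' Controller configuration
#'
#' Bundles the gains, bounds and timing of the closed-loop norepinephrine
#' (NE) controller. Defaults are the published values of the canine system:
#' a target MAP of 60 mmHg, parallel-form PID gains
#' \eqn{K_p = 0.004} ug/kg/min/mmHg, \eqn{K_i = 0.006} 1/s, \eqn{K_d = 96} s,
#' a 2-s update interval, an output clamp to \[0, 1\] ug/kg/min, and a
#' hypertensive shut-off that forces a zero rate whenever the measured MAP
#' exceeds the target by more than 10 mmHg.
#'
#' @param tmap Target mean arterial pressure (mmHg).
#' @param kp Proportional gain (ug/kg/min per mmHg).
#' @param ki Integral gain (1/s); the PID law is
#'   \eqn{u = K_p (\Delta + K_i I + K_d D)} with \eqn{I} the running
#'   time-integral of the transformed error (mmHg s) and \eqn{D} its
#'   backward-difference derivative (mmHg/s).
#' @param kd Derivative gain (s).
#' @param dt_update Control update interval (s).
#' @param rate_min,rate_max Bounds on the commanded NE rate (ug/kg/min).
#' @param shutoff_margin MAP excess above `tmap` (mmHg) that forces a zero
#'   infusion rate regardless of the PID output.
#' @param lpf_tau Time constant (s) of the first-order low-pass filter applied
#'   to the measured pressure before it enters the controller.
#' @param antiwindup If `TRUE`, the error integral is frozen on updates where
#'   the unclamped PID output falls outside `[rate_min, rate_max]`
#'   (conditional integration). The published system ran without it.
#'
#' @return An object of class `controller_config`.
#' @seealso [controller_update()], [nl_transform()], [limit_rate()]
#' @export
#' @examples
#' cfg <- controller_config()
#' cfg$tmap
controller_config <- function(tmap = 60, kp = 0.004, ki = 0.006, kd = 96,
                              dt_update = 2, rate_min = 0, rate_max = 1,
                              shutoff_margin = 10, lpf_tau = 10,
                              antiwindup = FALSE) {
  num <- list(tmap = tmap, kp = kp, ki = ki, kd = kd, dt_update = dt_update,
              rate_min = rate_min, rate_max = rate_max,
              shutoff_margin = shutoff_margin, lpf_tau = lpf_tau)
  for (nm in names(num)) {
    if (!is.numeric(num[[nm]]) || length(num[[nm]]) != 1 || !is.finite(num[[nm]])) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (rate_min > rate_max) stop("`rate_min` must not exceed `rate_max`", call. = FALSE)
  if (dt_update <= 0) stop("`dt_update` must be positive", call. = FALSE)
  if (lpf_tau <= 0) stop("`lpf_tau` must be positive", call. = FALSE)
  if (kp < 0 || ki < 0 || kd < 0) stop("gains must be non-negative", call. = FALSE)
  structure(c(num, list(antiwindup = isTRUE(antiwindup))),
            class = "controller_config")
}

#' Controller state
#'
#' Initial memory of the PID controller: zero error integral, no previous
#' error (the derivative term is zero on the first update), and a zero last
#' command. The integrator is reset to zero at system activation; there is no
#' bumpless-transfer logic.
#'
#' @param cfg A [controller_config()].
#' @return An object of class `controller_state` with fields `integral`
#'   (mmHg s), `prev_error` (mmHg, `NA` before the first update),
#'   `prev_command` (ug/kg/min), `filter_state` (mmHg) and `t` (s).
#' @export
controller_state <- function(cfg = controller_config()) {
  stopifnot(inherits(cfg, "controller_config"))
  structure(list(integral = 0, prev_error = NA_real_,
                 prev_command = cfg$rate_min, filter_state = NA_real_, t = 0),
            class = "controller_state")
}

#' Asymmetric nonlinear error transformer
#'
#' Converts the control error into the shaped error \eqn{\Delta MAP} that
#' feeds the PID controller. When the measured MAP is at or above target the
#' error is passed through untouched
#' (\eqn{\Delta = tMAP - MAP}); below target the raw error is boosted by a
#' bounded sigmoid,
#' \deqn{\Delta = (tMAP - MAP) + 10 - \frac{10}{1 + e^{1.5((tMAP - MAP) - 5)}},}
#' so hypotension is corrected more aggressively than hypertension. The boost
#' saturates at +10 mmHg and nearly vanishes at the branch point
#' (residue \eqn{10/(1+e^{7.5}) \approx 0.0055} mmHg), so the transform is
#' continuous to well under 0.01 mmHg and strictly decreasing in the
#' measured pressure.
#'
#' @param tmap Target MAP (mmHg).
#' @param map_meas Measured (filtered) MAP (mmHg); may be a vector.
#' @return The shaped error (mmHg), same length as `map_meas`.
#' @export
#' @examples
#' nl_transform(60, 70)   # hypertensive branch: raw error -10
#' nl_transform(60, 55)   # raw error 5 boosted to 10
nl_transform <- function(tmap, map_meas) {
  if (!is.numeric(tmap) || !all(is.finite(tmap))) {
    stop("`tmap` must be finite", call. = FALSE)
  }
  if (!is.numeric(map_meas) || !all(is.finite(map_meas))) {
    stop("`map_meas` must be finite", call. = FALSE)
  }
  if (any(map_meas <= 0)) stop("`map_meas` must be positive", call. = FALSE)
  e <- tmap - map_meas
  boosted <- e + 10 - 10 / (1 + exp(1.5 * (e - 5)))
  ifelse(e <= 0, e, boosted)
}

#' One PID update
#'
#' Advances the controller state by one update interval and returns the raw
#' (unclamped) infusion rate \eqn{u = K_p(\Delta + K_i I + K_d D)}.
#' Discretization: forward-Euler integral (the integral is advanced by
#' \eqn{\Delta \cdot dt} and the advanced value is used in the same update)
#' and backward-difference derivative
#' \eqn{D = (\Delta - \Delta_{prev})/dt}. On the first update after
#' activation the derivative term is zero.
#'
#' @param delta_map Shaped error from [nl_transform()] (mmHg).
#' @param state A [controller_state()].
#' @param cfg A [controller_config()].
#' @return A list with `rate` (the unclamped rate, ug/kg/min) and the
#'   advanced `state`.
#' @export
pid_step <- function(delta_map, state, cfg) {
  if (!inherits(state, "controller_state")) {
    stop("`state` must be a `controller_state` (see `controller_state()`)",
         call. = FALSE)
  }
  stopifnot(inherits(cfg, "controller_config"))
  if (!is.numeric(delta_map) || length(delta_map) != 1 || !is.finite(delta_map)) {
    stop("`delta_map` must be a single finite number", call. = FALSE)
  }
  dt <- cfg$dt_update
  state$integral <- state$integral + delta_map * dt
  d <- if (is.na(state$prev_error)) 0 else (delta_map - state$prev_error) / dt
  state$prev_error <- delta_map
  state$t <- state$t + dt
  rate <- cfg$kp * (delta_map + cfg$ki * state$integral + cfg$kd * d)
  list(rate = rate, state = state)
}

#' Output limiter with hypertensive shut-off
#'
#' If the measured MAP exceeds `tmap + shutoff_margin` the infusion rate is
#' forced to zero regardless of the PID output; otherwise the raw rate is
#' clamped to `[rate_min, rate_max]` (negative computed rates clamp to the
#' lower bound).
#'
#' @param raw_rate Unclamped PID output (ug/kg/min).
#' @param map_meas Measured (filtered) MAP (mmHg).
#' @param cfg A [controller_config()].
#' @return The commanded rate (ug/kg/min), within `[rate_min, rate_max]`.
#' @export
#' @examples
#' limit_rate(0.5, 75, controller_config())  # shut-off: 0
#' limit_rate(1.5, 55, controller_config())  # cap: 1
limit_rate <- function(raw_rate, map_meas, cfg) {
  stopifnot(inherits(cfg, "controller_config"))
  ifelse(map_meas > cfg$tmap + cfg$shutoff_margin, cfg$rate_min,
         pmin(pmax(raw_rate, cfg$rate_min), cfg$rate_max))
}

#' First-order low-pass filter of a pressure series
#'
#' Discrete exponential smoother
#' \eqn{y_k = y_{k-1} + (dt/\tau)(x_k - y_{k-1})} applied to a uniformly
#' sampled pressure series; the digitized arterial pressure smoothed this way
#' (time constant 10 s) is what the closed loop uses as MAP. A constant input
#' is a fixed point; a step input follows \eqn{1 - e^{-t/\tau}} to within
#' the Euler discretization error (requires \eqn{dt \ll \tau}).
#'
#' @param samples Numeric vector of pressure samples (mmHg).
#' @param tau Filter time constant (s).
#' @param dt Sampling interval of `samples` (s).
#' @param init Initial filter output; defaults to the first sample.
#' @return Smoothed series, same length as `samples`.
#' @export
lowpass_map <- function(samples, tau, dt, init = samples[1]) {
  if (length(samples) == 0) stop("`samples` must be non-empty", call. = FALSE)
  if (!is.numeric(samples) || !all(is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  stopifnot(tau > 0, dt > 0)
  a <- dt / tau
  y <- numeric(length(samples))
  prev <- init
  for (k in seq_along(samples)) {
    prev <- prev + a * (samples[k] - prev)
    y[k] <- prev
  }
  y
}

#' One closed-loop controller update
#'
#' Composes [nl_transform()], [pid_step()] and [limit_rate()] on an
#' already-filtered pressure sample; call on the `dt_update` grid. With
#' `cfg$antiwindup = TRUE`, the integral is not advanced on updates where the
#' unclamped rate lies outside `[rate_min, rate_max]` (the output is then
#' recomputed with the frozen integral before clamping).
#'
#' @inheritParams pid_step
#' @param map_meas Filtered measured MAP (mmHg).
#' @return A list with `rate` (the commanded, clamped rate) and the advanced
#'   `state` (whose `prev_command` holds the emitted rate).
#' @export
controller_update <- function(map_meas, state, cfg) {
  if (!is.numeric(map_meas) || length(map_meas) != 1 || !is.finite(map_meas)) {
    stop("`map_meas` must be a single finite number", call. = FALSE)
  }
  delta <- nl_transform(cfg$tmap, map_meas)
  old_integral <- state$integral
  stepped <- pid_step(delta, state, cfg)
  raw <- stepped$rate
  state <- stepped$state
  if (cfg$antiwindup && (raw < cfg$rate_min || raw > cfg$rate_max)) {
    # conditional integration: revert the integral and remove its
    # contribution from the output (P and D terms are unaffected)
    raw <- raw - cfg$kp * cfg$ki * (state$integral - old_integral)
    state$integral <- old_integral
  }
  rate <- limit_rate(raw, map_meas, cfg)
  state$prev_command <- rate
  state$filter_state <- map_meas
  list(rate = rate, state = state)
}
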