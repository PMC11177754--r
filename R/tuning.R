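# Gain-tuning pathway: open-loop NE step response, two-point
# first-order-plus-dead-time (FOPDT) fit, and Chien-Hrones-Reswick (CHR)
# PID rules converted to the controller's parallel form.

#' Open-loop NE step response of a virtual dog
#'
#' From the steady state at `baseline_iso`, a constant NE infusion of
#' `u_step` starts at t = 0 and the MAP response is recorded — the
#' preliminary experiment the controller gains were tuned from (a
#' 0.25 ug/kg/min step). Noise-free by default, which is what [fit_fopdt()]
#' expects.
#'
#' @param dog A [dog_params()].
#' @param u_step Step amplitude (ug/kg/min).
#' @param baseline_iso Isoflurane concentration (%) held throughout.
#' @param duration_s Recording length (s).
#' @param log_dt Sampling interval of the returned series (s).
#' @param noise_sd Measurement noise SD (mmHg).
#' @param seed Optional seed (only relevant with noise).
#' @return A tibble of class `step_response` with columns `time_s`,
#'   `map_mmhg` and attribute `u_step`.
#' @export
step_response <- function(dog, u_step = 0.25, baseline_iso = 1.5,
                          duration_s = 1800, log_dt = 2, noise_sd = 0,
                          seed = NULL) {
  stopifnot(inherits(dog, "dog_params"), u_step >= 0)
  tl <- timeline(0, baseline_iso, FALSE, duration_s = duration_s,
                 init_iso = baseline_iso)
  # reuse the trial engine with a constant forced infusion: emulate by a
  # closed-loop config pinned to u_step via rate bounds
  cfg <- controller_config(rate_min = u_step, rate_max = u_step,
                           shutoff_margin = 1e6)
  tl$active <- TRUE
  rec <- sim_engine(dog, tl, cfg = cfg, sim_dt = 0.05, log_dt = log_dt,
                    seed = seed, noise_sd = noise_sd)
  out <- tibble::tibble(time_s = rec$time_s, map_mmhg = rec$map_meas_mmhg)
  if (noise_sd == 0) out$map_mmhg <- rec$map_true_mmhg
  structure(out, u_step = u_step,
            class = c("step_response", class(out)))
}

#' Fit a first-order-plus-dead-time model to a step response
#'
#' Two-point method: the process gain is \eqn{K = \Delta MAP_{ss}/u_{step}};
#' the times \eqn{t_{28}} and \eqn{t_{63}} at which the response first
#' crosses 28.3% and 63.2% of its total change give the time constant
#' \eqn{T = 1.5 (t_{63} - t_{28})} and dead time \eqn{L = t_{63} - T}
#' (clamped at zero). The baseline is the pre-step level (samples at
#' \eqn{t \le 0}, else the first sample); the steady level is the mean of
#' the final 5% of samples, and the fit is rejected if the response has not
#' settled (final 10% of samples deviating from that level by more than 2%
#' of the total change).
#'
#' @param resp A `step_response` tibble (columns `time_s`, `map_mmhg`), or
#'   any data frame with those columns.
#' @param u_step Step amplitude (ug/kg/min); defaults to the attribute
#'   stored by [step_response()].
#' @return An object of class `fopdt` with fields `gain_k` (mmHg per
#'   ug/kg/min), `tconst` (s), `dead_time` (s), `baseline`, `delta_ss`
#'   (mmHg), `rms_residual` (mmHg, model vs data), and `data`.
#' @export
#' @examples
#' resp <- step_response(calibrate_defaults())
#' fit_fopdt(resp)
fit_fopdt <- function(resp, u_step = attr(resp, "u_step")) {
  stopifnot(is.data.frame(resp),
            all(c("time_s", "map_mmhg") %in% names(resp)))
  if (is.null(u_step) || !is.numeric(u_step) || length(u_step) != 1) {
    stop("`u_step` (the step amplitude) is required", call. = FALSE)
  }
  if (u_step == 0) stop("`u_step` must be non-zero", call. = FALSE)
  t <- resp$time_s; m <- resp$map_mmhg
  pre <- m[t <= 0]
  baseline <- if (length(pre) > 0) mean(pre) else m[1]
  n <- length(m)
  tail_idx <- seq.int(max(1, ceiling(0.95 * n)), n)
  ss <- mean(m[tail_idx])
  delta <- ss - baseline
  if (abs(delta) < 1e-9) stop("flat response: no step change to fit", call. = FALSE)
  settle_idx <- seq.int(max(1, ceiling(0.9 * n)), n)
  if (max(abs(m[settle_idx] - ss)) > 0.02 * abs(delta)) {
    stop("response has not settled; extend the recording", call. = FALSE)
  }
  cross <- function(frac) {
    target <- baseline + frac * delta
    above <- if (delta > 0) m >= target else m <= target
    k <- which(above & t > 0)[1]
    if (is.na(k)) stop("response never crosses ", frac * 100,
                       "% of its change", call. = FALSE)
    if (k == 1) return(t[1])
    # linear interpolation between the bracketing samples
    t[k - 1] + (target - m[k - 1]) / (m[k] - m[k - 1]) * (t[k] - t[k - 1])
  }
  t28 <- cross(0.283); t63 <- cross(0.632)
  tconst <- 1.5 * (t63 - t28)
  dead_time <- max(t63 - tconst, 0)
  gain_k <- delta / u_step
  fitted <- baseline + fopdt_response(gain_k, tconst, dead_time, u_step, t)
  structure(list(gain_k = gain_k, tconst = tconst, dead_time = dead_time,
                 baseline = baseline, delta_ss = delta,
                 rms_residual = sqrt(mean((fitted - m)^2)),
                 data = tibble::tibble(time_s = t, map_mmhg = m,
                                       fitted_mmhg = fitted)),
            class = "fopdt")
}

#' Analytic FOPDT step response
#'
#' \eqn{K u (1 - e^{-(t - L)/T})} for \eqn{t > L}, zero before the dead
#' time elapses.
#'
#' @param gain_k Process gain (mmHg per ug/kg/min).
#' @param tconst Time constant (s), positive.
#' @param dead_time Dead time (s), non-negative.
#' @param u Step amplitude (ug/kg/min).
#' @param t Time grid (s).
#' @return Response (mmHg change from baseline).
#' @export
fopdt_response <- function(gain_k, tconst, dead_time, u, t) {
  stopifnot(tconst > 0, dead_time >= 0)
  ifelse(t > dead_time, gain_k * u * (1 - exp(-(t - dead_time) / tconst)), 0)
}

#' @export
print.fopdt <- function(x, digits = 4, ...) {
  cat("<fopdt> K =", signif(x$gain_k, digits), "mmHg/(ug/kg/min), T =",
      signif(x$tconst, digits), "s, L =", signif(x$dead_time, digits),
      "s (RMS residual", signif(x$rms_residual, 3), "mmHg)\n")
  invisible(x)
}

#' @rdname tidy.perf_summary
#' @export
tidy.fopdt <- function(x, ...) {
  tibble::tibble(term = c("gain_k", "tconst", "dead_time"),
                 estimate = c(x$gain_k, x$tconst, x$dead_time),
                 unit = c("mmHg/(ug/kg/min)", "s", "s"))
}

#' @rdname tidy.perf_summary
#' @export
glance.fopdt <- function(x, ...) {
  tibble::tibble(gain_k = x$gain_k, tconst = x$tconst,
                 dead_time = x$dead_time, rms_residual = x$rms_residual,
                 n = nrow(x$data))
}

#' Chien-Hrones-Reswick PID gains from an FOPDT model
#'
#' The CHR setpoint-tracking rules (Chien, Hrones and Reswick's classical
#' table): for 0% overshoot \eqn{K_c = 0.6 T/(K L)}, \eqn{T_i = T},
#' \eqn{T_d = 0.5 L}; for 20% overshoot \eqn{K_c = 0.95 T/(K L)},
#' \eqn{T_i = 1.357 T}, \eqn{T_d = 0.473 L}. The result is converted to
#' this controller's parallel form \eqn{u = K_p(e + K_i \int e + K_d
#' \dot e)} via \eqn{K_p = K_c}, \eqn{K_i = 1/T_i}, \eqn{K_d = T_d}.
#'
#' @param m An `fopdt` model with strictly positive dead time.
#' @param variant `"setpoint_0"` (no-overshoot, the default) or
#'   `"setpoint_20"`.
#' @return A one-row tibble with `kp`, `ki`, `kd` and the variant.
#' @seealso [controller_config()] to run the gains.
#' @export
#' @examples
#' m <- structure(list(gain_k = 1, tconst = 1, dead_time = 1), class = "fopdt")
#' chr_gains(m)   # kp 0.6, ki 1, kd 0.5
chr_gains <- function(m, variant = c("setpoint_0", "setpoint_20")) {
  variant <- match.arg(variant)
  stopifnot(inherits(m, "fopdt"))
  if (m$dead_time <= 0) {
    stop("CHR rules need a positive dead time; fit the response over a ",
         "grid fine enough to resolve the delay", call. = FALSE)
  }
  k <- m$gain_k; tt <- m$tconst; l <- m$dead_time
  if (variant == "setpoint_0") {
    kc <- 0.6 * tt / (k * l); ti <- tt; td <- 0.5 * l
  } else {
    kc <- 0.95 * tt / (k * l); ti <- 1.357 * tt; td <- 0.473 * l
  }
  tibble::tibble(kp = kc, ki = 1 / ti, kd = td, variant = variant)
}
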