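# Independent oracles, deliberately written apart from the package code.

# Hand-stepped Euler PID: advance integral first, then use it; backward
# difference for the derivative (zero on the first step).
pid_oracle <- function(deltas, kp = 0.004, ki = 0.006, kd = 96, dt = 2,
                       integral0 = 0, prev0 = NA_real_) {
  integral <- integral0
  prev <- prev0
  out <- numeric(length(deltas))
  for (i in seq_along(deltas)) {
    integral <- integral + deltas[i] * dt
    d <- if (is.na(prev)) 0 else (deltas[i] - prev) / dt
    prev <- deltas[i]
    out[i] <- kp * (deltas[i] + ki * integral + kd * d)
  }
  out
}

# Least-squares slope via lm(), the reference for the divergence formula.
ols_slope <- function(pe, t_min) {
  unname(stats::coef(stats::lm(pe ~ t_min))[2])
}

# Noise-free first-order-plus-dead-time step response (the fixture for
# parameter-recovery tests), written from the closed form.
fopdt_data <- function(k, tt, l, u, t) {
  tibble::tibble(time_s = t,
                 map_mmhg = 70 + ifelse(t > l, k * u * (1 - exp(-(t - l) / tt)), 0))
}

# A calibrated noise-free dog, shared across tests.
quiet_dog <- function() calibrate_defaults(noise_sd = 0)
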