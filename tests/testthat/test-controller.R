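test_that("nonlinear transformer matches its closed form on both branches", {
  # hypertensive branch is the raw error
  expect_equal(nl_transform(60, 70), -10)
  expect_equal(nl_transform(60, 60), 0)
  # at raw error 5 the sigmoid sits at its midpoint: boost exactly +5
  expect_equal(nl_transform(60, 55), 10)
  # the boost saturates at +10 for large errors
  expect_lt(abs(nl_transform(60, 40) - 30), 1e-8)
  expect_lt(nl_transform(60, 40), 30)
  # boost lies strictly in (0, 10) on the hypotensive branch
  maps <- seq(20, 59.9, by = 0.1)
  boost <- nl_transform(60, maps) - (60 - maps)
  expect_true(all(boost > 0 & boost <= 10 + 1e-9))  # saturates to 10 in double
  expect_lt(max(nl_transform(60, seq(40, 59.9, by = 0.1)) -
                  (60 - seq(40, 59.9, by = 0.1))), 10)
})

test_that("nonlinear transformer is continuous at target and strictly decreasing", {
  expect_lt(abs(nl_transform(60, 60 - 1e-9) - nl_transform(60, 60 + 1e-9)), 0.01)
  maps <- seq(20, 120, by = 0.05)
  expect_true(all(diff(nl_transform(60, maps)) < 0))
})

test_that("nonlinear transformer rejects bad pressures by name", {
  expect_error(nl_transform(60, NaN), "map_meas")
  expect_error(nl_transform(Inf, 70), "tmap")
  expect_error(nl_transform(60, -5), "map_meas")
})

test_that("pid_step reproduces hand-stepped Euler examples", {
  cfg <- controller_config()
  st <- controller_state(cfg)
  # zero error forever stays at zero
  for (i in 1:5) {
    out <- pid_step(0, st, cfg)
    st <- out$state
    expect_equal(out$rate, 0)
  }
  # held error with pre-loaded memory: I 20 -> 40, D = 0
  st <- controller_state(cfg)
  st$integral <- 20; st$prev_error <- 10
  out <- pid_step(10, st, cfg)
  expect_equal(out$rate, 0.004 * (10 + 0.006 * 40), tolerance = 1e-12)
  expect_equal(out$rate, 0.04096)
  expect_equal(out$state$integral, 40)
  # error jump from rest: D = 1, I = 4
  st <- controller_state(cfg)
  st$prev_error <- 0
  out <- pid_step(2, st, cfg)
  expect_equal(out$rate, 0.392096, tolerance = 1e-12)
})

test_that("pid_step equals the Euler oracle on random error sequences", {
  cfg <- controller_config()
  set.seed(42)
  for (rep in 1:10) {
    deltas <- rnorm(sample(5:100, 1), sd = 20)
    st <- controller_state(cfg)
    got <- vapply(deltas, function(d) {
      out <- pid_step(d, st, cfg)
      st <<- out$state
      out$rate
    }, numeric(1))
    expect_equal(got, pid_oracle(deltas), tolerance = 1e-12)
  }
})

test_that("pid_step rejects an uninitialized state", {
  cfg <- controller_config()
  expect_error(pid_step(1, list(integral = 0), cfg), "controller_state")
  expect_error(pid_step(NA_real_, controller_state(cfg), cfg), "finite")
})

test_that("limiter clamps, caps, and obeys the hypertensive shut-off", {
  cfg <- controller_config()
  expect_equal(limit_rate(0.5, 75, cfg), 0)    # MAP > tmap + 10
  expect_equal(limit_rate(1.5, 55, cfg), 1)    # cap at 1
  expect_equal(limit_rate(-0.2, 55, cfg), 0)   # negative clamps to 0
  expect_equal(limit_rate(0.4, 55, cfg), 0.4)  # pass-through in band
})

test_that("limiter bounds and shut-off dominance hold under fuzzing", {
  cfg <- controller_config()
  set.seed(7)
  raw <- runif(2000, -5, 5)
  maps <- runif(2000, 0, 200)
  rates <- limit_rate(raw, maps, cfg)
  expect_true(all(rates >= 0 & rates <= 1))
  expect_true(all(rates[maps > 70] == 0))
})

test_that("low-pass filter has the exponential step response", {
  # constant input is a fixed point
  expect_equal(lowpass_map(rep(80, 50), tau = 10, dt = 0.1), rep(80, 50))
  # unit step: 63.2% at one time constant, 86.5% at two
  dt <- 0.1; tau <- 10
  t <- seq(dt, 30, by = dt)
  y <- lowpass_map(rep(100, length(t)), tau = tau, dt = dt, init = 0)
  expect_equal(y[100], 100 * (1 - exp(-1)), tolerance = 0.005)
  expect_equal(y[200], 100 * (1 - exp(-2)), tolerance = 0.005)
  # whole trajectory within 0.5% of the analytic response for dt/tau = 1e-2
  expect_lt(max(abs(y - 100 * (1 - exp(-t / tau)))) / 100, 0.005)
  expect_error(lowpass_map(numeric(0), 10, 0.1), "non-empty")
})

test_that("controller_update composes transform, PID and limiter", {
  cfg <- controller_config()
  # shut-off dominates any state
  st <- controller_state(cfg)
  st$integral <- 5000
  expect_equal(controller_update(75, st, cfg)$rate, 0)
  # at target from rest: zero command
  expect_equal(controller_update(60, controller_state(cfg), cfg)$rate, 0)
  # deep sustained hypotension saturates the command at the cap
  st <- controller_state(cfg)
  rate <- 0
  for (i in 1:700) {
    out <- controller_update(40, st, cfg)
    st <- out$state
    rate <- out$rate
  }
  expect_equal(rate, 1)
})

test_that("anti-windup freezes the integral while the output saturates", {
  cfg_aw <- controller_config(antiwindup = TRUE)
  st <- controller_state(cfg_aw)
  st$prev_error <- 0                   # derivative kick saturates the output
  out1 <- controller_update(40, st, cfg_aw)
  expect_equal(out1$state$integral, 0)           # frozen
  expect_equal(out1$rate, 1)
  # default mode accumulates regardless
  cfg <- controller_config()
  st <- controller_state(cfg)
  st$prev_error <- 0
  out2 <- controller_update(40, st, cfg)
  expect_equal(out2$rate, 1)
  expect_gt(out2$state$integral, 0)
  # unsaturated updates advance the integral in both modes identically
  out3 <- controller_update(59, controller_state(cfg_aw), cfg_aw)
  expect_gt(out3$state$integral, 0)
})
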