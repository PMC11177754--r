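test_that("calibrated defaults reproduce the printed anchors", {
  p <- calibrate_defaults()
  expect_equal(iso_steady_map(1.5, p), 92, tolerance = 0.1 / 92)
  expect_equal(iso_steady_map(4, p), 41, tolerance = 0.1 / 41)
  expect_equal(ne_steady_effect(0.33, p), 19, tolerance = 0.1 / 19)
  expect_equal(iso_steady_map(0, p), p$map0)
  expect_equal(ne_steady_effect(0, p), 0)
  # NE anchor inverts in closed form with the pressor ceiling fixed at 60
  expect_equal(p$ne_u50, 0.712, tolerance = 1e-3)
  # saturation toward the ceiling
  expect_equal(ne_steady_effect(1e9, p), p$ne_emax, tolerance = 1e-6)
})

test_that("closed-form isoflurane calibration agrees with a grid-search oracle", {
  p <- calibrate_defaults()
  # brute force over (emax, ec50^h) minimizing the anchor residuals
  grid <- expand.grid(emax = seq(60, 120, by = 0.05),
                      x = seq(5, 80, by = 0.05))
  sse <- (100 - grid$emax * 1.5^3 / (1.5^3 + grid$x) - 92)^2 +
    (100 - grid$emax * 4^3 / (4^3 + grid$x) - 41)^2
  best <- grid[which.min(sse), ]
  expect_equal(p$iso_emax, best$emax, tolerance = 0.002)
  expect_equal(p$iso_ec50^3, best$x, tolerance = 0.005)
})

test_that("infeasible or contradictory anchors are rejected", {
  bad <- tibble::tibble(channel = c("iso", "iso", "ne"),
                        input = c(1.5, 1.5, 0.33), target = c(92, 50, 19))
  expect_error(calibrate_defaults(bad), "infeasible|anchors")
  rising <- tibble::tibble(channel = c("iso", "iso", "ne"),
                           input = c(1.5, 4, 0.33), target = c(41, 92, 19))
  expect_error(calibrate_defaults(rising), "depression must increase")
  big_ne <- tibble::tibble(channel = c("iso", "iso", "ne"),
                           input = c(1.5, 4, 0.33), target = c(92, 41, 75))
  expect_error(calibrate_defaults(big_ne), "NE anchor")
  expect_error(iso_steady_map(-1, calibrate_defaults()), "non-negative")
  expect_error(ne_steady_effect(-0.1, calibrate_defaults()), "non-negative")
})

test_that("steady-state MAP is monotone and the 4% operating range covers the target", {
  p <- calibrate_defaults()
  cc <- seq(0, 6, by = 0.05)
  expect_true(all(diff(iso_steady_map(cc, p)) < 0))
  lo <- iso_steady_map(4, p)
  hi <- lo + ne_steady_effect(1, p)
  expect_lt(lo, 60)
  expect_gt(hi, 60)   # NE within [0, 1] can restore the target
})

test_that("plant_step reaches the algebraic steady state and honors dead time", {
  p <- calibrate_defaults(noise_sd = 0)
  st <- dog_state(p, iso_init = 1.5)
  # constant inputs long past every time constant
  for (k in 1:20000) {
    out <- plant_step(st, c_iso = 4, u_ne = 0.33, dt = 0.1, p = p)
    st <- out$state
  }
  expect_equal(out$map_true, iso_steady_map(4, p) + ne_steady_effect(0.33, p),
               tolerance = 0.1 / 60)
  # dead time: an NE step leaves MAP untouched until lag_ne elapses
  st <- dog_state(p, iso_init = 4)
  for (k in 1:100) {  # 10 s < lag_ne = 20 s
    out <- plant_step(st, c_iso = 4, u_ne = 1, dt = 0.1, p = p)
    st <- out$state
  }
  expect_equal(out$map_true, iso_steady_map(4, p), tolerance = 1e-6)
  expect_equal(st$ne_effect, 0)
  expect_error(plant_step(st, 4, 0, dt = 200, p = p), "dt")
})

test_that("measurement noise has the configured spread and seeds reproduce", {
  p <- calibrate_defaults(noise_sd = 2)
  st <- dog_state(p, iso_init = 4)
  set.seed(99)
  resid <- replicate(1e4, {
    out <- plant_step(st, 4, 0, dt = 0.1, p = p)
    st <<- out$state
    out$map_meas - out$map_true
  })
  expect_gt(sd(resid), 1.8)
  expect_lt(sd(resid), 2.2)
  # identical seeds, identical trajectories
  one <- plant_step(dog_state(p), 4, 0.5, dt = 0.1, p = p, rng_seed = 5)
  two <- plant_step(dog_state(p), 4, 0.5, dt = 0.1, p = p, rng_seed = 5)
  expect_identical(one$map_meas, two$map_meas)
})

test_that("the trial engine agrees with repeated plant_step calls", {
  p <- calibrate_defaults(noise_sd = 0)
  rec <- run_open_loop_trial(p, timeline_hypotension(duration_s = 120),
                             sim_dt = 0.1)
  st <- dog_state(p, iso_init = 1.5)
  map_at <- numeric(0)
  for (k in 1:1200) {
    out <- plant_step(st, 4, 0, dt = 0.1, p = p)
    st <- out$state
    if (k %% 100 == 0) map_at <- c(map_at, out$map_true)
  }
  expect_equal(rec$map_true_mmhg, map_at, tolerance = 1e-10)
})

test_that("cohort sampling is deterministic, mean-preserving and spread-calibrated", {
  p <- calibrate_defaults()
  same <- sample_population(4, p, cv = 0)
  expect_true(all(vapply(seq_len(4), function(i) {
    identical(unclass(as_dog_params(same[i, ])), unclass(p))
  }, logical(1))))
  a <- sample_population(5, p, cv = 0.2, seed = 11)
  b <- sample_population(5, p, cv = 0.2, seed = 11)
  expect_identical(a, b)
  big <- sample_population(1000, p, cv = 0.2, seed = 3)
  emp_cv <- sd(big$ne_emax) / mean(big$ne_emax)
  expect_gt(emp_cv, 0.17)
  expect_lt(emp_cv, 0.23)
  # untouched fields are copied verbatim
  expect_true(all(big$weight == p$weight))
  expect_error(sample_population(3, p, cv = 0.7), "cv")
})
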