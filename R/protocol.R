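# Study-protocol replay: timelines of isoflurane concentration and
# controller activation, the coupled plant/controller simulation engine,
# and cohort experiments.

#' Build a protocol timeline
#'
#' A timeline is an ordered table of events; each event sets the inhaled
#' isoflurane concentration, the controller-active flag and the target MAP
#' from its time until the next event. The animal starts at the steady
#' state of `init_iso` (its anesthetic plane before the first event), so a
#' timeline whose first event commands 4% on a dog equilibrated at 1.5%
#' reproduces the study's step increase.
#'
#' @param time_s Event times (s), strictly increasing, first at 0.
#' @param iso_pct Isoflurane concentration (%) from each event on.
#' @param active Logical: closed-loop NE control active from each event on.
#' @param tmap_mmhg Target MAP (mmHg) from each event on.
#' @param duration_s Total duration (s) of the protocol.
#' @param init_iso Isoflurane concentration (%) whose steady state the
#'   animal occupies at t = 0.
#' @return A tibble of class `timeline` with attributes `duration_s` and
#'   `init_iso`.
#' @export
timeline <- function(time_s, iso_pct, active, tmap_mmhg = 60,
                     duration_s = max(time_s) + 600, init_iso = 1.5) {
  n <- length(time_s)
  if (n == 0) stop("a timeline needs at least one event", call. = FALSE)
  if (time_s[1] != 0) stop("the first event must be at t = 0", call. = FALSE)
  if (n > 1 && any(diff(time_s) <= 0)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  if (duration_s <= max(time_s)) {
    stop("`duration_s` must exceed the last event time", call. = FALSE)
  }
  tl <- tibble::tibble(time_s = time_s, iso_pct = iso_pct,
                       active = as.logical(active),
                       tmap_mmhg = rep_len(tmap_mmhg, n))
  structure(tl, duration_s = duration_s, init_iso = init_iso,
            class = c("timeline", class(tl)))
}

#' Canonical study timelines
#'
#' `timeline_hypotension()` is the open-loop hypotension trial: the
#' concentration steps from the 1.5% baseline to 4% at t = 0 with the
#' controller off. `timeline_activation()` is the closed-loop trial: the
#' same step with the feedback loop closed simultaneously at t = 0
#' (target 60 mmHg); `observe_s > 0` appends a deactivated observation
#' period at unchanged isoflurane after `duration_s`.
#' `timeline_full_protocol()` chains the two with a 5-min washout at 1.5%
#' in between and a 10-min post-deactivation observation.
#'
#' @param iso Isoflurane concentration (%) during the hypotensive phase.
#' @param duration_s Length (s) of the (active) phase.
#' @param tmap Target MAP (mmHg).
#' @param observe_s Deactivated observation period (s) appended after the
#'   active phase.
#' @param init_iso Baseline concentration (%) the animal starts from.
#' @return A [timeline()].
#' @export
timeline_hypotension <- function(iso = 4, duration_s = 600, init_iso = 1.5) {
  timeline(0, iso, FALSE, duration_s = duration_s, init_iso = init_iso)
}

#' @rdname timeline_hypotension
#' @export
timeline_activation <- function(iso = 4, duration_s = 1800, tmap = 60,
                                observe_s = 0, init_iso = 1.5) {
  if (observe_s > 0) {
    timeline(c(0, duration_s), c(iso, iso), c(TRUE, FALSE), tmap,
             duration_s = duration_s + observe_s, init_iso = init_iso)
  } else {
    timeline(0, iso, TRUE, tmap, duration_s = duration_s, init_iso = init_iso)
  }
}

#' @rdname timeline_hypotension
#' @export
timeline_full_protocol <- function(iso = 4, tmap = 60) {
  timeline(time_s = c(0, 600, 900, 2700),
           iso_pct = c(iso, 1.5, iso, iso),
           active = c(FALSE, FALSE, TRUE, FALSE),
           tmap_mmhg = tmap, duration_s = 3300, init_iso = 1.5)
}

# Piecewise-constant lookup of timeline values on the inner grid.
timeline_segments <- function(tl, times) {
  idx <- findInterval(times, tl$time_s)
  idx[idx < 1] <- 1
  list(iso = tl$iso_pct[idx], active = tl$active[idx], tmap = tl$tmap_mmhg[idx])
}

# Coupled plant/controller simulation. Inner explicit-Euler step `sim_dt`
# (plant dynamics, measurement noise, low-pass filter); controller on its
# own dt_update grid with zero-order hold between updates; analysis log
# every `log_dt`. Implements the same update equations as plant_step() /
# controller_update() in one flat loop for speed.
sim_engine <- function(p, tl, cfg = NULL, sim_dt = 0.05, log_dt = 10,
                       seed = NULL, noise_sd = p$noise_sd) {
  stopifnot(inherits(p, "dog_params"), inherits(tl, "timeline"))
  duration <- attr(tl, "duration_s")
  n <- round(duration / sim_dt)
  if (n < 1) stop("timeline duration too short for the simulation step",
                  call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  closed <- !is.null(cfg)
  if (closed) stopifnot(inherits(cfg, "controller_config"))
  seg <- timeline_segments(tl, (seq_len(n) - 1) * sim_dt)
  if (!closed && any(seg$active)) {
    stop("open-loop run requested on a timeline with active control",
         call. = FALSE)
  }
  ec50h <- p$iso_ec50^p$iso_hill
  iso_ch <- seg$iso^p$iso_hill
  iso_target <- p$iso_emax * iso_ch / (iso_ch + ec50h)
  lag_steps <- max(1L, round(p$lag_ne / sim_dt))
  ctrl_every <- max(1L, round((if (closed) cfg$dt_update else 2) / sim_dt))
  log_every <- max(1L, round(log_dt / sim_dt))
  noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  hr_noise <- if (noise_sd > 0) stats::rnorm(n, 0, 3) else numeric(n)

  iso_eff <- p$map0 - iso_steady_map(attr(tl, "init_iso"), p)
  ne_eff <- 0
  y <- p$map0 - iso_eff                      # filter starts at the true MAP
  a_lpf <- if (closed) sim_dt / cfg$lpf_tau else sim_dt / 10
  u_hist <- numeric(n + lag_steps)           # commanded rate per inner step
  integral <- 0; prev_err <- NA_real_; u <- 0
  was_active <- FALSE
  n_log <- floor(n / log_every)
  l_t <- l_mt <- l_mm <- l_hr <- l_iso <- l_u <- numeric(n_log)
  j <- 0L
  for (k in seq_len(n)) {
    u_delayed <- u_hist[k]                   # commanded lag_ne seconds ago
    iso_eff <- iso_eff + sim_dt / p$tau_iso * (iso_target[k] - iso_eff)
    ne_target <- p$ne_emax * u_delayed / (u_delayed + p$ne_u50)
    ne_eff <- ne_eff + sim_dt / p$tau_ne * (ne_target - ne_eff)
    map_true <- p$map0 - iso_eff + ne_eff
    map_raw <- map_true + noise[k]
    y <- y + a_lpf * (map_raw - y)
    if (closed && seg$active[k]) {
      if (!was_active) {                     # activation: reset controller
        integral <- 0; prev_err <- NA_real_
        was_active <- TRUE
      }
      if (k %% ctrl_every == 0L) {
        e <- nl_transform(seg$tmap[k], y)
        i_try <- integral + e * cfg$dt_update
        d <- if (is.na(prev_err)) 0 else (e - prev_err) / cfg$dt_update
        prev_err <- e
        raw <- cfg$kp * (e + cfg$ki * i_try + cfg$kd * d)
        if (cfg$antiwindup && (raw < cfg$rate_min || raw > cfg$rate_max)) {
          raw <- raw - cfg$kp * cfg$ki * (i_try - integral)
        } else {
          integral <- i_try
        }
        u <- if (y > seg$tmap[k] + cfg$shutoff_margin) cfg$rate_min
             else min(max(raw, cfg$rate_min), cfg$rate_max)
      }
    } else {
      u <- 0
      if (was_active) was_active <- FALSE    # deactivation drops the loop
    }
    u_hist[k + lag_steps] <- u
    if (k %% log_every == 0L) {
      j <- j + 1L
      l_t[j] <- k * sim_dt; l_mt[j] <- map_true; l_mm[j] <- y
      l_hr[j] <- 123 + 0.4 * ne_eff + hr_noise[k]
      l_iso[j] <- seg$iso[k]; l_u[j] <- u
    }
  }
  rec <- tibble::tibble(time_s = l_t, map_true_mmhg = l_mt,
                        map_meas_mmhg = l_mm, hr_bpm = l_hr,
                        iso_pct = l_iso, ne_ug_kg_min = l_u)
  new_trial_record(rec, meta = list(seed = seed, sim_dt = sim_dt,
                                    log_dt = log_dt, noise_sd = noise_sd,
                                    params = p, cfg = cfg, timeline = tl))
}

new_trial_record <- function(rec, meta) {
  structure(rec, meta = meta, class = c("trial_record", class(rec)))
}

#' @export
print.trial_record <- function(x, ...) {
  meta <- attr(x, "meta")
  cat("<trial_record> ", nrow(x), " points every ", meta$log_dt,
      " s (seed ", if (is.null(meta$seed)) "none" else meta$seed, ")\n",
      sep = "")
  NextMethod()
}

#' Run an open-loop trial
#'
#' Simulates the plant under the timeline with the NE infusion held at zero
#' throughout (the initial-hypotension trial: MAP falls from its 1.5%
#' baseline of 92 mmHg toward 41 mmHg at 4%).
#'
#' @param dog A [dog_params()].
#' @param tl A [timeline()] with the controller inactive throughout.
#' @param seed Optional integer seed; identical seeds give bitwise-identical
#'   records.
#' @param sim_dt Inner simulation step (s); plant dynamics, noise and the
#'   measurement filter run at this resolution (default 20 Hz).
#' @param log_dt Analysis sampling interval (s); the study logged every 10 s.
#' @param noise_sd Measurement noise SD (mmHg); defaults to the dog's.
#' @return A `trial_record`: a tibble with columns `time_s`,
#'   `map_true_mmhg`, `map_meas_mmhg` (the low-pass-filtered measured MAP
#'   the system works with), `hr_bpm`, `iso_pct`, `ne_ug_kg_min`, with the
#'   run's metadata attached as attribute `meta`.
#' @export
#' @examples
#' p <- calibrate_defaults(noise_sd = 0)
#' rec <- run_open_loop_trial(p, timeline_hypotension())
#' tail(rec, 2)  # MAP settled near 41 mmHg
run_open_loop_trial <- function(dog, tl = timeline_hypotension(), seed = NULL,
                                sim_dt = 0.05, log_dt = 10,
                                noise_sd = dog$noise_sd) {
  sim_engine(dog, tl, cfg = NULL, sim_dt = sim_dt, log_dt = log_dt,
             seed = seed, noise_sd = noise_sd)
}

#' Run a closed-loop trial
#'
#' Simulates the plant coupled to the controller. The controller runs on its
#' own `dt_update` grid (2 s by default) on the low-pass-filtered measured
#' pressure; commands are zero-order-held between updates; the integrator is
#' reset at each activation edge.
#'
#' @inheritParams run_open_loop_trial
#' @param tl A [timeline()]; control is applied wherever `active` is `TRUE`.
#' @param cfg A [controller_config()].
#' @return A `trial_record` (see [run_open_loop_trial()]) including the
#'   commanded NE rate trace.
#' @export
#' @examples
#' p <- calibrate_defaults(noise_sd = 0)
#' rec <- run_closed_loop_trial(p, timeline_activation(duration_s = 600))
run_closed_loop_trial <- function(dog, tl = timeline_activation(),
                                  cfg = controller_config(), seed = NULL,
                                  sim_dt = 0.05, log_dt = 10,
                                  noise_sd = dog$noise_sd) {
  sim_engine(dog, tl, cfg = cfg, sim_dt = sim_dt, log_dt = log_dt,
             seed = seed, noise_sd = noise_sd)
}

#' Per-dog isoflurane titration
#'
#' The study adjusted the isoflurane concentration slightly according to the
#' individual animal's MAP response. This helper reproduces that clinical
#' step: starting from `base_iso`, the concentration is raised in 0.25%
#' steps (up to `max_iso`) while the dog's steady-state MAP stays above the
#' hypotension threshold of 60 mmHg, and lowered in 0.25% steps (down to
#' `min_iso`) while the steady-state MAP falls below `floor_map` -- the
#' anesthetist lightens the plane rather than leave an animal in
#' unsurvivable hypotension.
#'
#' @param dog A [dog_params()].
#' @param base_iso Starting concentration (%).
#' @param max_iso,min_iso Concentration bounds (%).
#' @param floor_map Lowest tolerated steady-state MAP (mmHg).
#' @return The titrated concentration (%).
#' @export
titrate_iso <- function(dog, base_iso = 4, max_iso = 6, min_iso = 2,
                        floor_map = 35) {
  c_iso <- base_iso
  while (iso_steady_map(c_iso, dog) > 60 && c_iso < max_iso) {
    c_iso <- c_iso + 0.25
  }
  while (iso_steady_map(c_iso, dog) < floor_map && c_iso > min_iso) {
    c_iso <- c_iso - 0.25
  }
  c_iso
}

#' Run a simulated cohort through the closed-loop protocol
#'
#' Samples `n` virtual dogs around the reference animal
#' ([sample_population()]), titrates each dog's isoflurane concentration
#' ([titrate_iso()]), runs each through the activation protocol, and
#' summarizes the performance metrics per dog and across the cohort
#' (median and linear-interpolation quartiles, the study's convention).
#'
#' @param n Number of dogs.
#' @param cv Inter-dog coefficient of variation (see [sample_population()]).
#' @param base Reference [dog_params()].
#' @param cfg A [controller_config()].
#' @param duration_s Active closed-loop period (s).
#' @param window Analysis window (s), passed to [summarize_trial()].
#' @param seed Integer seed; drives both the cohort sampling and each dog's
#'   measurement noise, so the whole experiment is reproducible.
#' @param titrate If `TRUE`, apply [titrate_iso()] per dog; otherwise all
#'   dogs get 4%.
#' @param sim_dt Inner simulation step (s).
#' @return An object of class `cohort_result`: a list with `dogs` (the
#'   sampled parameter tibble plus the titrated `iso_pct`), `trials` (list
#'   of `trial_record`s), `per_dog` (one row of metrics per dog) and
#'   `summary` (cohort median and IQR of each metric).
#' @export
#' @examples
#' \donttest{
#' coh <- run_cohort(n = 2, cv = 0.1, seed = 1, duration_s = 900,
#'                   window = c(450, 900))
#' coh$summary
#' }
run_cohort <- function(n = 6, cv = 0.2, base = calibrate_defaults(),
                       cfg = controller_config(), duration_s = 1800,
                       window = c(900, 1800), seed = NULL, titrate = TRUE,
                       sim_dt = 0.05) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dogs <- sample_population(n, base, cv)
  dog_seeds <- sample.int(.Machine$integer.max %/% 2, n)
  trials <- vector("list", n)
  iso_used <- numeric(n)
  per_dog <- vector("list", n)
  for (i in seq_len(n)) {
    p_i <- as_dog_params(dogs[i, ])
    iso_used[i] <- if (titrate) titrate_iso(p_i) else 4
    tl <- timeline_activation(iso = iso_used[i], duration_s = duration_s,
                              tmap = cfg$tmap)
    trials[[i]] <- run_closed_loop_trial(p_i, tl, cfg, seed = dog_seeds[i],
                                         sim_dt = sim_dt)
    s <- summarize_trial(trials[[i]], window = window, tmap = cfg$tmap)
    per_dog[[i]] <- tibble::add_column(glance(s), dog_id = i, .before = 1)
  }
  per_dog <- dplyr::bind_rows(per_dog)
  dogs$iso_pct <- iso_used
  metrics <- c("mdpe", "mdape", "wobble", "divergence", "time_in_range")
  summary <- tidyr::pivot_longer(per_dog[, c("dog_id", metrics)],
                                 -"dog_id", names_to = "metric")
  summary <- dplyr::summarise(
    dplyr::group_by(summary, .data$metric),
    median = stats::median(.data$value),
    q1 = stats::quantile(.data$value, 0.25, names = FALSE),
    q3 = stats::quantile(.data$value, 0.75, names = FALSE),
    .groups = "drop")
  structure(list(dogs = dogs, trials = trials, per_dog = per_dog,
                 summary = summary, seed = seed, window = window, cfg = cfg),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> ", nrow(x$dogs), " dogs, window ",
      x$window[1] / 60, "-", x$window[2] / 60, " min\n", sep = "")
  print(x$summary)
  invisible(x)
}
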