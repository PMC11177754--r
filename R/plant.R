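# Virtual-dog pharmacodynamic plant: sigmoid Emax statics for the
# isoflurane depressor and norepinephrine pressor effects, first-order
# effect dynamics with transport dead time on the NE path, additive
# Gaussian measurement noise, and log-normal inter-animal variability.

#' Virtual-dog pharmacodynamic parameters
#'
#' The plant's steady-state model is
#' \deqn{MAP = map_0 - E_{iso}\frac{c^h}{c^h + EC_{50}^h}
#'            + E_{ne}\frac{u}{u + U_{50}}}
#' with \eqn{c} the inhaled isoflurane concentration (%) and \eqn{u} the NE
#' infusion rate (ug/kg/min). Both effects relax toward their steady-state
#' values with first-order time constants, and the NE command additionally
#' passes through a pure transport dead time. The functional form is this
#' package's model of the animal; the study measured real dogs.
#'
#' Prefer [calibrate_defaults()], which fills in `iso_emax`, `iso_ec50` and
#' `ne_u50` so that the plant reproduces the study's printed medians
#' (MAP 92 mmHg at 1.5% isoflurane, 41 mmHg at 4%, and a +19 mmHg pressor
#' effect at 0.33 ug/kg/min of NE).
#'
#' @param map0 Drug-free reference MAP (mmHg).
#' @param iso_emax Maximal isoflurane MAP depression (mmHg).
#' @param iso_ec50 Isoflurane concentration at half-maximal depression (%).
#' @param iso_hill Hill exponent of the isoflurane curve (dimensionless).
#' @param ne_emax Maximal NE pressor effect (mmHg).
#' @param ne_u50 NE rate at half-maximal pressor effect (ug/kg/min).
#' @param tau_iso,tau_ne Effect time constants (s).
#' @param lag_ne NE transport dead time (s): venous transit plus pump start.
#' @param noise_sd Measurement noise SD (mmHg) added to the true MAP.
#' @param weight Body mass (kg).
#' @return An object of class `dog_params`.
#' @export
dog_params <- function(map0 = 100, iso_emax = 60, iso_ec50 = 3, iso_hill = 3,
                       ne_emax = 60, ne_u50 = 0.7, tau_iso = 120, tau_ne = 30,
                       lag_ne = 20, noise_sd = 2, weight = 9.1) {
  p <- list(map0 = map0, iso_emax = iso_emax, iso_ec50 = iso_ec50,
            iso_hill = iso_hill, ne_emax = ne_emax, ne_u50 = ne_u50,
            tau_iso = tau_iso, tau_ne = tau_ne, lag_ne = lag_ne,
            noise_sd = noise_sd, weight = weight)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]])) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (any(unlist(p[setdiff(names(p), "noise_sd")]) <= 0)) {
    stop("all `dog_params` fields except `noise_sd` must be positive",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(p, class = "dog_params")
}

#' @export
print.dog_params <- function(x, ...) {
  cat("<dog_params>\n")
  print(tibble::as_tibble(unclass(x)))
  invisible(x)
}

#' Default calibration anchors
#'
#' The three printed medians the default virtual dog is calibrated to:
#' steady MAP of 92 mmHg at 1.5% isoflurane, 41 mmHg at 4%, and an NE
#' pressor effect of +19 mmHg (= 60 - 41, i.e. enough to restore the target)
#' at 0.33 ug/kg/min.
#'
#' @return A tibble with columns `channel` ("iso" or "ne"), `input` (% or
#'   ug/kg/min) and `target` (mmHg: absolute MAP for "iso" rows, pressor
#'   effect for the "ne" row).
#' @export
default_anchors <- function() {
  tibble::tibble(channel = c("iso", "iso", "ne"),
                 input = c(1.5, 4, 0.33),
                 target = c(92, 41, 19))
}

#' Calibrate the default virtual dog to the printed medians
#'
#' Solves the Hill-curve parameters so the plant reproduces the calibration
#' anchors exactly. With the Hill exponent and `map0` fixed, the two
#' isoflurane anchors give a closed form for `iso_emax` and `iso_ec50`;
#' with `ne_emax` fixed, the single NE anchor inverts to
#' \eqn{U_{50} = E_{ne} u / e - u}. Deterministic; anchors that are
#' contradictory or infeasible (non-positive or non-monotone solutions)
#' are rejected with the residual report.
#'
#' @param anchors A tibble as returned by [default_anchors()]: exactly two
#'   distinct "iso" rows and one "ne" row.
#' @param map0 Drug-free reference MAP (mmHg), held fixed.
#' @param iso_hill Hill exponent, held fixed.
#' @param ne_emax Maximal NE pressor effect (mmHg), held fixed.
#' @param ... Further fields passed to [dog_params()] (e.g. `noise_sd`).
#' @return A [dog_params()] object reproducing every anchor to within
#'   0.1 mmHg (exactly, up to floating point).
#' @export
#' @examples
#' p <- calibrate_defaults()
#' iso_steady_map(c(1.5, 4), p)   # 92, 41
#' ne_steady_effect(0.33, p)      # 19
calibrate_defaults <- function(anchors = default_anchors(), map0 = 100,
                               iso_hill = 3, ne_emax = 60, ...) {
  stopifnot(is.data.frame(anchors),
            all(c("channel", "input", "target") %in% names(anchors)))
  iso <- anchors[anchors$channel == "iso", ]
  ne <- anchors[anchors$channel == "ne", ]
  if (nrow(iso) != 2 || nrow(ne) != 1) {
    stop("calibration needs exactly two isoflurane anchors and one NE anchor",
         call. = FALSE)
  }
  iso <- iso[order(iso$input), ]
  c1 <- iso$input[1]; c2 <- iso$input[2]
  d1 <- map0 - iso$target[1]; d2 <- map0 - iso$target[2]
  if (c1 == c2 || d1 >= d2 || d1 < 0) {
    stop("infeasible isoflurane anchors: depression must increase with ",
         "concentration (residuals: ", paste(signif(c(d1, d2), 4), collapse = ", "),
         " mmHg at ", paste(c(c1, c2), collapse = ", "), " %)", call. = FALSE)
  }
  a1 <- c1^iso_hill; a2 <- c2^iso_hill
  x <- a1 * a2 * (d2 - d1) / (d1 * a2 - d2 * a1)  # = ec50^hill
  if (!is.finite(x) || x <= 0) {
    stop("infeasible isoflurane anchors: no positive EC50 solves them",
         call. = FALSE)
  }
  iso_emax <- d1 * (a1 + x) / a1
  iso_ec50 <- x^(1 / iso_hill)
  u <- ne$input; e <- ne$target
  if (u <= 0 || e <= 0 || e >= ne_emax) {
    stop("infeasible NE anchor: effect must lie in (0, ne_emax)", call. = FALSE)
  }
  ne_u50 <- ne_emax * u / e - u
  p <- dog_params(map0 = map0, iso_emax = iso_emax, iso_ec50 = iso_ec50,
                  iso_hill = iso_hill, ne_emax = ne_emax, ne_u50 = ne_u50, ...)
  resid <- c(iso_steady_map(iso$input, p) - iso$target,
             ne_steady_effect(u, p) - e)
  if (any(abs(resid) > 0.1)) {
    stop("calibration residuals exceed 0.1 mmHg: ",
         paste(signif(resid, 3), collapse = ", "), call. = FALSE)
  }
  p
}

#' Steady-state MAP under isoflurane alone
#'
#' \eqn{map_0 - E_{iso} c^h / (c^h + EC_{50}^h)}; strictly decreasing in the
#' concentration.
#'
#' @param c Inhaled isoflurane concentration (%); may be a vector.
#' @param p A [dog_params()].
#' @return Steady-state MAP (mmHg).
#' @export
iso_steady_map <- function(c, p) {
  stopifnot(inherits(p, "dog_params"))
  if (any(!is.finite(c)) || any(c < 0)) {
    stop("`c` must be a non-negative concentration", call. = FALSE)
  }
  ch <- c^p$iso_hill
  p$map0 - p$iso_emax * ch / (ch + p$iso_ec50^p$iso_hill)
}

#' Steady-state NE pressor effect
#'
#' Saturating hyperbolic dose-response
#' \eqn{E_{ne} u / (u + U_{50})} (mmHg of MAP rise).
#'
#' @param u NE infusion rate (ug/kg/min); may be a vector.
#' @param p A [dog_params()].
#' @return Pressor effect (mmHg).
#' @export
ne_steady_effect <- function(u, p) {
  stopifnot(inherits(p, "dog_params"))
  if (any(!is.finite(u)) || any(u < 0)) {
    stop("`u` must be a non-negative infusion rate", call. = FALSE)
  }
  p$ne_emax * u / (u + p$ne_u50)
}

#' Instantaneous plant state
#'
#' @param p A [dog_params()].
#' @param iso_init Isoflurane concentration (%) whose steady state
#'   initializes the depressor effect (the animal's condition at t = 0).
#' @return An object of class `dog_state` with fields `iso_effect`,
#'   `ne_effect` (mmHg), `ne_pipeline` (pending NE commands implementing the
#'   dead time), and `t` (s).
#' @export
dog_state <- function(p, iso_init = 1.5) {
  stopifnot(inherits(p, "dog_params"))
  structure(list(iso_effect = p$map0 - iso_steady_map(iso_init, p),
                 ne_effect = 0, ne_pipeline = numeric(0), dt = NA_real_,
                 t = 0),
            class = "dog_state")
}

#' Advance the plant by one time step
#'
#' Both effects relax exponentially toward their steady-state values
#' (explicit Euler, step `dt`); the NE command is delayed by `lag_ne` before
#' it drives the pressor effect. True MAP is
#' `map0 - iso_effect + ne_effect`; the measured MAP adds Gaussian noise of
#' SD `noise_sd`. The heart-rate channel is decorative: an affine function
#' of the pressor effect plus noise, for log realism only.
#'
#' `dt` must stay constant across successive calls on the same state (the
#' dead-time pipeline is resolved at `dt`).
#'
#' @param state A [dog_state()].
#' @param c_iso Inhaled isoflurane concentration (%).
#' @param u_ne Commanded NE rate (ug/kg/min).
#' @param dt Time step (s); must be positive and below both time constants.
#' @param p A [dog_params()].
#' @param rng_seed Optional integer; if given, seeds the RNG before drawing
#'   the measurement noise (identical seeds give identical trajectories).
#' @return A list with the advanced `state`, `map_true`, `map_meas` (mmHg)
#'   and `hr` (beats/min).
#' @export
plant_step <- function(state, c_iso, u_ne, dt, p, rng_seed = NULL) {
  stopifnot(inherits(state, "dog_state"), inherits(p, "dog_params"))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0 ||
      dt >= min(p$tau_iso, p$tau_ne)) {
    stop("`dt` must be positive and smaller than both time constants",
         call. = FALSE)
  }
  if (!is.na(state$dt) && state$dt != dt) {
    stop("`dt` must stay constant across steps of one trajectory", call. = FALSE)
  }
  state$dt <- dt
  if (!is.null(rng_seed)) set.seed(rng_seed)
  lag_steps <- round(p$lag_ne / dt)
  pipe <- c(state$ne_pipeline, u_ne)
  if (length(pipe) > lag_steps) {
    u_delayed <- pipe[1]
    pipe <- pipe[-1]
  } else {
    u_delayed <- 0
  }
  state$ne_pipeline <- pipe
  iso_target <- p$map0 - iso_steady_map(c_iso, p)
  ne_target <- ne_steady_effect(u_delayed, p)
  state$iso_effect <- state$iso_effect + dt / p$tau_iso * (iso_target - state$iso_effect)
  state$ne_effect <- state$ne_effect + dt / p$tau_ne * (ne_target - state$ne_effect)
  state$t <- state$t + dt
  map_true <- p$map0 - state$iso_effect + state$ne_effect
  map_meas <- map_true + if (p$noise_sd > 0) stats::rnorm(1, 0, p$noise_sd) else 0
  hr <- 123 + 0.4 * state$ne_effect +
    if (p$noise_sd > 0) stats::rnorm(1, 0, 3) else 0
  list(state = state, map_true = map_true, map_meas = map_meas, hr = hr)
}

#' Sample a virtual cohort around a reference dog
#'
#' Multiplicative log-normal perturbation (mean-preserving, coefficient of
#' variation `cv`) of the sensitivity parameters `iso_emax`, `ne_emax`,
#' `ne_u50`, `tau_iso` and `tau_ne`; the remaining fields are copied.
#'
#' @param n Number of dogs.
#' @param p Reference [dog_params()] (default: the calibrated dog).
#' @param cv Coefficient of variation of the perturbed parameters,
#'   in `[0, 0.5)`.
#' @param seed Optional integer seed for reproducible cohorts.
#' @return A tibble with one row per dog: `dog_id` plus every `dog_params`
#'   field. Convert a row back with [as_dog_params()].
#' @export
#' @examples
#' sample_population(3, cv = 0.2, seed = 1)
sample_population <- function(n, p = calibrate_defaults(), cv = 0.2,
                              seed = NULL) {
  stopifnot(inherits(p, "dog_params"), n >= 1)
  if (cv < 0 || cv >= 0.5) stop("`cv` must lie in [0, 0.5)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  mulog <- -sdlog^2 / 2  # E[factor] = 1
  draw <- function() if (cv == 0) rep(1, n) else stats::rlnorm(n, mulog, sdlog)
  out <- tibble::as_tibble(unclass(p))[rep(1, n), ]
  for (nm in c("iso_emax", "ne_emax", "ne_u50", "tau_iso", "tau_ne")) {
    out[[nm]] <- out[[nm]] * draw()
  }
  tibble::add_column(out, dog_id = seq_len(n), .before = 1)
}

#' Rebuild `dog_params` from one row of a cohort tibble
#'
#' @param row A one-row data frame with the `dog_params` fields (e.g. a row
#'   of [sample_population()] output).
#' @return A [dog_params()] object.
#' @export
as_dog_params <- function(row) {
  stopifnot(is.data.frame(row), nrow(row) == 1)
  fields <- names(formals(dog_params))
  do.call(dog_params, as.list(row[, fields]))
}
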