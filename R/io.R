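# Formats and conversions: dose-to-pump-rate arithmetic, trial-record CSV
# round-tripping, and deterministic fixture generation.

trial_cols <- c("time_s", "map_true_mmhg", "map_meas_mmhg", "hr_bpm",
                "iso_pct", "ne_ug_kg_min")

#' Convert a weight-normalized dose to a syringe-pump rate
#'
#' The pump takes mL/h of a syringe prepared at `conc` ug of NE per mL
#' (the study used 0.5 mg/mL = 500 ug/mL):
#' \eqn{mL/h = rate \times weight \times 60 / conc}.
#'
#' @param rate NE dose rate (ug/kg/min).
#' @param weight Body mass (kg).
#' @param conc Syringe concentration (ug/mL).
#' @return Pump rate (mL/h).
#' @export
#' @examples
#' dose_to_pump_rate(0.33, 9.1)   # 0.36 mL/h
dose_to_pump_rate <- function(rate, weight, conc = 500) {
  if (any(conc <= 0)) stop("`conc` must be positive", call. = FALSE)
  if (any(rate < 0) || any(weight <= 0)) {
    stop("`rate` must be non-negative and `weight` positive", call. = FALSE)
  }
  rate * weight * 60 / conc
}

#' Write / read a trial record as CSV
#'
#' Column order and names are fixed (`time_s`, `map_true_mmhg`,
#' `map_meas_mmhg`, `hr_bpm`, `iso_pct`, `ne_ug_kg_min`); units live in the
#' names so they cannot silently drift. Numeric values round-trip at full
#' precision. Reading validates the header and the time column (strictly
#' increasing); unknown extra columns are kept with a warning (tolerant
#' reader), and malformed cells are reported with their line numbers.
#'
#' @param record A `trial_record` (or data frame with the schema above).
#' @param path File path.
#' @return `write_trial_csv()` returns `path` invisibly; `read_trial_csv()`
#'   returns a `trial_record` tibble.
#' @export
write_trial_csv <- function(record, path) {
  stopifnot(is.data.frame(record))
  missing <- setdiff(trial_cols, names(record))
  if (length(missing) > 0) {
    stop("record is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(as.data.frame(record)[, c(trial_cols,
                                             setdiff(names(record), trial_cols))],
                   path)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  # parse cells as text and convert through base strtod: exact to the ulp,
  # so written records read back bit-identical
  rec <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  for (col in names(rec)) {
    num <- suppressWarnings(as.numeric(rec[[col]]))
    bad <- which(is.na(num) & !is.na(rec[[col]]) & rec[[col]] != "NA")
    if (col %in% trial_cols && length(bad) > 0) {
      stop("malformed values in column `", col, "` of ", path, " (line",
           if (length(bad) > 1) "s", " ",
           paste(utils::head(bad, 5) + 1, collapse = ", "), ")",
           call. = FALSE)
    }
    if (length(bad) == 0) rec[[col]] <- num
  }
  missing <- setdiff(trial_cols, names(rec))
  if (length(missing) > 0) {
    stop(path, " is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(rec), trial_cols)
  if (length(extra) > 0) {
    warning("unknown columns kept: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  if (any(diff(rec$time_s) <= 0)) {
    stop("`time_s` must be strictly increasing in ", path, call. = FALSE)
  }
  new_trial_record(rec, meta = list(source = path, log_dt = NULL,
                                    seed = NULL, cfg = NULL))
}

#' Generate deterministic demo/test fixtures
#'
#' Writes small CSV fixtures produced by the package's own simulator:
#' `"step-response"` (open-loop 0.25 ug/kg/min NE step, columns `time_s`,
#' `map_mmhg`), `"hypotension"` (open-loop 4% isoflurane trial record), or
#' `"closed-loop"` (30-min activation trial record). Identical seeds give
#' byte-identical files.
#'
#' @param kind One of `"step-response"`, `"hypotension"`, `"closed-loop"`.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return The written file path, invisibly.
#' @export
make_fixture <- function(kind = c("step-response", "hypotension", "closed-loop"),
                         dir = tempdir(), seed = 1) {
  kind <- match.arg(kind)
  p <- calibrate_defaults()
  path <- file.path(dir, paste0(gsub("-", "_", kind), "_seed", seed, ".csv"))
  if (kind == "step-response") {
    resp <- step_response(p, u_step = 0.25, log_dt = 10)
    readr::write_csv(tibble::as_tibble(resp), path)
  } else if (kind == "hypotension") {
    rec <- run_open_loop_trial(p, timeline_hypotension(), seed = seed)
    write_trial_csv(rec, path)
  } else {
    rec <- run_closed_loop_trial(p, timeline_activation(), seed = seed)
    write_trial_csv(rec, path)
  }
  invisible(path)
}
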