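# Varvel-style performance evaluation of a controlled-pressure trial:
# percentage performance error and its median summaries, plus the
# time-in-target-range fraction.

#' Percentage performance error
#'
#' \eqn{PE_i = (MAP_i - tMAP)/tMAP \times 100}; pressure below target gives
#' a negative error.
#'
#' @param map_series Measured MAP values (mmHg).
#' @param tmap Target MAP (mmHg), positive.
#' @return PE series (%), same length as `map_series`.
#' @export
#' @examples
#' performance_error(c(57, 60, 66), 60)
performance_error <- function(map_series, tmap) {
  if (length(map_series) == 0) stop("`map_series` must be non-empty", call. = FALSE)
  if (!is.numeric(tmap) || length(tmap) != 1 || tmap <= 0) {
    stop("`tmap` must be a single positive number", call. = FALSE)
  }
  (map_series - tmap) / tmap * 100
}

#' Median performance error (bias)
#'
#' Median of the PE series; negative when the pressure runs below target.
#' With an even number of points the median is the mean of the two central
#' order statistics.
#'
#' @param pe PE series (%), non-empty.
#' @return MDPE (%).
#' @export
mdpe <- function(pe) {
  if (length(pe) == 0) stop("`pe` must be non-empty", call. = FALSE)
  stats::median(pe)
}

#' Median absolute performance error (inaccuracy)
#'
#' Median of |PE|; always at least |MDPE|.
#'
#' @inheritParams mdpe
#' @return MDAPE (%).
#' @export
mdape <- function(pe) {
  if (length(pe) == 0) stop("`pe` must be non-empty", call. = FALSE)
  stats::median(abs(pe))
}

#' Wobble (intra-individual variability)
#'
#' Median of |PE - MDPE|; zero iff the PE series is constant.
#'
#' @inheritParams mdpe
#' @return Wobble (%).
#' @export
wobble <- function(pe) {
  if (length(pe) == 0) stop("`pe` must be non-empty", call. = FALSE)
  stats::median(abs(pe - stats::median(pe)))
}

#' Divergence (trend of the performance error)
#'
#' The ordinary-least-squares slope of the performance error regressed on
#' time in minutes,
#' \deqn{\frac{n\sum T_i PE_i - \sum T_i \sum PE_i}
#'            {n\sum T_i^2 - (\sum T_i)^2},}
#' in %/min; negative means the control error shrinks over the observation
#' period. The published formula regresses the signed PE (the default); the
#' accompanying prose describes the trend of |PE|, so `on = "absolute"`
#' computes that variant instead.
#'
#' @param pe PE series (%), length at least 2.
#' @param t_min Observation times (minutes), strictly increasing.
#' @param on `"signed"` (the printed formula) or `"absolute"`.
#' @return Divergence (%/min).
#' @export
#' @examples
#' divergence(2 * (1:10), 1:10)   # exact linear trend: slope 2
divergence <- function(pe, t_min, on = c("signed", "absolute")) {
  on <- match.arg(on)
  if (length(pe) < 2) stop("`pe` needs at least 2 points", call. = FALSE)
  if (length(t_min) != length(pe)) {
    stop("`pe` and `t_min` must have the same length", call. = FALSE)
  }
  if (any(diff(t_min) <= 0)) {
    stop("`t_min` must be strictly increasing", call. = FALSE)
  }
  if (on == "absolute") pe <- abs(pe)
  n <- length(pe)
  num <- n * sum(t_min * pe) - sum(t_min) * sum(pe)
  den <- n * sum(t_min^2) - sum(t_min)^2
  if (den == 0) stop("`t_min` is constant", call. = FALSE)
  num / den
}

#' Percentage of time in the acceptable pressure range
#'
#' \eqn{100 \times \#\{lo \le MAP_i \le hi\}/n}, bounds inclusive; the study
#' band is the target plus or minus 5 mmHg (55-65 mmHg).
#'
#' @param map_series Measured MAP values (mmHg), non-empty.
#' @param lo,hi Band bounds (mmHg), `lo <= hi`.
#' @return Percentage of points in range.
#' @export
time_in_range <- function(map_series, lo = 55, hi = 65) {
  if (length(map_series) == 0) stop("`map_series` must be non-empty", call. = FALSE)
  if (lo > hi) stop("`lo` must not exceed `hi`", call. = FALSE)
  100 * mean(map_series >= lo & map_series <= hi)
}

#' Summarize controller performance over an analysis window
#'
#' Restricts the record's measured MAP to the analysis window (half-open:
#' `window[1] < time_s <= window[2]`, so the study's 15-30-min window on a
#' 10-s grid contains exactly 90 points), computes the PE series against the
#' target, and returns all Varvel metrics plus time-in-range. Time for the
#' divergence regression is measured in minutes from the window start.
#'
#' @param record A `trial_record` (or any data frame with `time_s` and the
#'   `map_col` column).
#' @param window `c(start, end)` in seconds; must lie within the record.
#'   The study analyzed the second half of the 30-min activation, 900-1800 s.
#' @param tmap Target MAP (mmHg); defaults to the controller target stored
#'   in the record's metadata, else 60.
#' @param band Acceptable range `c(lo, hi)` (mmHg); defaults to `tmap` +/- 5.
#' @param map_col Column holding the analyzed pressure (the filtered
#'   measured MAP by default).
#' @param divergence_on Passed to [divergence()].
#' @return An object of class `perf_summary` with fields `pe` (tibble of
#'   `time_min`, `pe_pct`), `mdpe`, `mdape`, `wobble`, `divergence`,
#'   `time_in_range`, `n_points`, `window`, `band`, `tmap`. Use [tidy()] or
#'   [glance()] for tabular forms.
#' @export
#' @examples
#' p <- calibrate_defaults(noise_sd = 0)
#' rec <- run_closed_loop_trial(p, timeline_activation())
#' summarize_trial(rec)
summarize_trial <- function(record, window = c(900, 1800), tmap = NULL,
                            band = NULL, map_col = "map_meas_mmhg",
                            divergence_on = c("signed", "absolute")) {
  stopifnot(is.data.frame(record), "time_s" %in% names(record),
            map_col %in% names(record))
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("`window` must be c(start, end) with start < end", call. = FALSE)
  }
  if (window[1] < 0 || window[2] > max(record$time_s)) {
    stop("`window` [", window[1], ", ", window[2],
         "] s lies outside the record (0-", max(record$time_s), " s)",
         call. = FALSE)
  }
  if (is.null(tmap)) {
    meta <- attr(record, "meta")
    tmap <- if (!is.null(meta$cfg)) meta$cfg$tmap else 60
  }
  if (is.null(band)) band <- c(tmap - 5, tmap + 5)
  keep <- record$time_s > window[1] & record$time_s <= window[2]
  if (!any(keep)) stop("no record points fall in `window`", call. = FALSE)
  map <- record[[map_col]][keep]
  t_min <- (record$time_s[keep] - window[1]) / 60
  pe <- performance_error(map, tmap)
  out <- structure(list(
    pe = tibble::tibble(time_min = t_min, pe_pct = pe),
    mdpe = mdpe(pe), mdape = mdape(pe), wobble = wobble(pe),
    divergence = divergence(pe, t_min, on = match.arg(divergence_on)),
    time_in_range = time_in_range(map, band[1], band[2]),
    n_points = length(pe), window = window, band = band, tmap = tmap),
    class = "perf_summary")
  out
}

#' @export
print.perf_summary <- function(x, digits = 3, ...) {
  cat("<perf_summary> ", x$n_points, " points, ",
      x$window[1] / 60, "-", x$window[2] / 60, " min, target ",
      x$tmap, " mmHg, band [", x$band[1], ", ", x$band[2], "] mmHg\n",
      sep = "")
  cat(sprintf("  MDPE %s%%  MDAPE %s%%  wobble %s%%  divergence %s%%/min  in-range %s%%\n",
              signif(x$mdpe, digits), signif(x$mdape, digits),
              signif(x$wobble, digits), signif(x$divergence, digits),
              signif(x$time_in_range, digits)))
  invisible(x)
}

#' Tidy a performance summary
#'
#' @param x A `perf_summary`.
#' @param ... Unused.
#' @return `tidy()`: a two-column tibble of metric names and values
#'   (MDPE, MDAPE and wobble in %, divergence in %/min, time-in-range in %).
#'   `glance()`: the same metrics as a one-row tibble together with
#'   `n_points` and the window bounds.
#' @export
tidy.perf_summary <- function(x, ...) {
  tibble::tibble(
    metric = c("mdpe", "mdape", "wobble", "divergence", "time_in_range"),
    value = c(x$mdpe, x$mdape, x$wobble, x$divergence, x$time_in_range))
}

#' @rdname tidy.perf_summary
#' @export
glance.perf_summary <- function(x, ...) {
  tibble::tibble(mdpe = x$mdpe, mdape = x$mdape, wobble = x$wobble,
                 divergence = x$divergence, time_in_range = x$time_in_range,
                 n_points = x$n_points,
                 window_start_s = x$window[1], window_end_s = x$window[2])
}

#' Tidy cohort results
#'
#' @param x A `cohort_result` from [run_cohort()].
#' @param ... Unused.
#' @return `tidy()`: per-dog metrics, one row per dog. `glance()`: cohort
#'   median and interquartile bounds of each metric, one row per metric.
#' @export
tidy.cohort_result <- function(x, ...) x$per_dog

#' @rdname tidy.cohort_result
#' @export
glance.cohort_result <- function(x, ...) x$summary
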