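# ggplot2 views of trials, cohorts and performance summaries.

#' Plot a trial record
#'
#' Stacked panels of MAP (true and filtered measured, with the target line
#' and acceptable band), commanded NE rate, and isoflurane concentration
#' against time in minutes.
#'
#' @param object A `trial_record`.
#' @param tmap Target MAP drawn as the reference line; defaults to the
#'   record's controller target, else 60.
#' @param band Acceptable band (mmHg) shaded around the target.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trial_record <- function(object, tmap = NULL, band = NULL, ...) {
  meta <- attr(object, "meta")
  if (is.null(tmap)) tmap <- if (!is.null(meta$cfg)) meta$cfg$tmap else 60
  if (is.null(band)) band <- c(tmap - 5, tmap + 5)
  long <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(object), time_min = .data$time_s / 60),
    cols = c("map_true_mmhg", "map_meas_mmhg", "ne_ug_kg_min", "iso_pct"),
    names_to = "channel", values_to = "value")
  long$panel <- dplyr::case_match(long$channel,
                                  c("map_true_mmhg", "map_meas_mmhg") ~ "MAP (mmHg)",
                                  "ne_ug_kg_min" ~ "NE rate (ug/kg/min)",
                                  "iso_pct" ~ "isoflurane (%)")
  ref <- tibble::tibble(panel = "MAP (mmHg)", y = tmap,
                        lo = band[1], hi = band[2])
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$value,
                                     colour = .data$channel)) +
    ggplot2::geom_rect(data = ref, ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                       xmin = -Inf, xmax = Inf, inherit.aes = FALSE,
                       fill = "tomato", alpha = 0.12) +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$y),
                        colour = "tomato", linewidth = 0.3) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y",
                        switch = "y") +
    ggplot2::labs(x = "time (min)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom", strip.placement = "outside")
}

#' Plot a cohort's pressure and infusion trajectories
#'
#' Median line and interquartile ribbon of the measured MAP and NE rate
#' across the cohort's dogs, aligned on the analysis grid.
#'
#' @param object A `cohort_result` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_result <- function(object, ...) {
  traces <- purrr::imap(object$trials, function(tr, i) {
    dplyr::mutate(tibble::as_tibble(tr)[, c("time_s", "map_meas_mmhg",
                                            "ne_ug_kg_min")], dog_id = i)
  })
  long <- tidyr::pivot_longer(dplyr::bind_rows(traces),
                              c("map_meas_mmhg", "ne_ug_kg_min"),
                              names_to = "channel")
  agg <- dplyr::summarise(
    dplyr::group_by(long, .data$channel, .data$time_s),
    med = stats::median(.data$value),
    q1 = stats::quantile(.data$value, 0.25, names = FALSE),
    q3 = stats::quantile(.data$value, 0.75, names = FALSE),
    .groups = "drop")
  tmap <- object$cfg$tmap
  ref <- tibble::tibble(channel = "map_meas_mmhg", y = tmap)
  ggplot2::ggplot(agg, ggplot2::aes(.data$time_s / 60, .data$med)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$y),
                        colour = "tomato", linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(map_meas_mmhg = "MAP (mmHg)",
                            ne_ug_kg_min = "NE rate (ug/kg/min)"))) +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a performance-error series
#'
#' The windowed PE series with the MDPE reference line.
#'
#' @param object A `perf_summary` from [summarize_trial()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perf_summary <- function(object, ...) {
  ggplot2::ggplot(object$pe, ggplot2::aes(.data$time_min, .data$pe_pct)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_hline(yintercept = object$mdpe, colour = "tomato",
                        linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time in window (min)", y = "performance error (%)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.trial_record
#' @param record A `trial_record`.
#' @export
plot_trial <- function(record, tmap = NULL, band = NULL) {
  autoplot.trial_record(record, tmap = tmap, band = band)
}
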