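# ggplot2 views mirroring the standard figures of ambient ADL studies: a
# raw sensor raster, stacked per-participant counts (raw or normalised),
# stacked proportions, and a per-day ADL timeline.

#' Raster plot of raw sensor events
#'
#' One point per activation/reading, sensors on the y axis — the visual
#' participants are shown during data-informed briefings.
#'
#' @param events Event tibble (optionally filtered to one participant).
#' @return A ggplot object.
#' @export
plot_sensor_raster <- function(events) {
  ggplot2::ggplot(events,
                  ggplot2::aes(x = .data$timestamp, y = .data$sensor_id)) +
    ggplot2::geom_point(shape = 124, alpha = 0.6) +
    ggplot2::facet_wrap(~participant_id, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL, title = "Raw sensor events") +
    ggplot2::theme_minimal()
}

#' Stacked per-participant ADL counts
#'
#' @param summary An `adl_summary` tibble from [summarize_adl()].
#' @param normalized Plot day-normalised counts instead of raw counts.
#' @return A ggplot object.
#' @export
plot_adl_counts <- function(summary, normalized = FALSE) {
  y <- if (normalized) "n_normalized" else "n_raw"
  lab <- if (normalized) "detections (normalised)" else "detections"
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$participant_id, y = .data[[y]],
                               fill = .data$adl)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = lab, fill = "ADL") +
    ggplot2::theme_minimal()
}

#' Stacked per-participant ADL proportions
#'
#' Proportions (between 0 and 1) of each participant's detections by ADL.
#'
#' @param summary An `adl_summary` tibble.
#' @return A ggplot object.
#' @export
plot_adl_proportions <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$participant_id, y = .data$proportion,
                               fill = .data$adl)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of detections", fill = "ADL") +
    ggplot2::theme_minimal()
}

#' Per-day ADL timeline
#'
#' Detected occurrences as horizontal segments, one row per day — the view
#' clinicians read to see routine (and its disruptions) at a glance.
#'
#' @param detections Detection tibble for one participant.
#' @return A ggplot object.
#' @export
plot_adl_timeline <- function(detections) {
  d <- mutate(detections,
              day = as.Date(.data$window_start),
              t0 = as.numeric(.data$window_start -
                                as.POSIXct(trunc(.data$window_start, "days"),
                                           tz = "UTC"), units = "hours"),
              t1 = .data$t0 + as.numeric(.data$window_end - .data$window_start,
                                         units = "hours"))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$day, yend = .data$day,
                                  x = .data$t0, xend = .data$t1,
                                  colour = .data$adl)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::scale_x_continuous(limits = c(0, 24),
                                breaks = seq(0, 24, 6),
                                name = "hour of day") +
    ggplot2::labs(y = NULL, colour = "ADL") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an association rule set
#'
#' Support/confidence scatter of the mined rules, faceted by ADL and
#' shaped by antecedent size.
#'
#' @param object An `adl_rules` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot adl_rules
#' @export
autoplot.adl_rules <- function(object, ...) {
  d <- mutate(as_tibble(object), size = lengths(.data$antecedent))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$support, y = .data$confidence,
                                  shape = factor(.data$size))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~adl) +
    ggplot2::labs(shape = "antecedent size") +
    ggplot2::theme_minimal()
}

#' Plot a participant summary
#'
#' @param object An `adl_summary` tibble.
#' @param ... Passed to [plot_adl_counts()].
#' @return A ggplot object.
#' @method autoplot adl_summary
#' @export
autoplot.adl_summary <- function(object, ...) {
  plot_adl_counts(object, ...)
}

#' Plot evaluation metrics
#'
#' @param object An `adl_eval` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot adl_eval
#' @export
autoplot.adl_eval <- function(object, ...) {
  d <- tidyr::pivot_longer(
    select(as_tibble(object), "adl", "precision", "recall", "f1"),
    -"adl", names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$adl, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
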