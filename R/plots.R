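#' Diagnostic plot of one trial's trace
#'
#' Acceleration magnitude over time with the stimulus onset, the detected
#' onset and the onset threshold marked. Useful for eyeballing why a trial
#' was (in)valid.
#'
#' @param trace Raw trace tibble.
#' @param stim_onset Stimulus onset in seconds.
#' @param prep A [prep_config()].
#' @param window_s Response window in seconds.
#' @param has_linear_accelerometer Passed to [prepare_trace()].
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, stim_onset, prep = prep_config(),
                       window_s = 2.0, has_linear_accelerometer = FALSE) {
  prepped <- prepare_trace(trace, stim_onset, prep,
                           has_linear_accelerometer = has_linear_accelerometer)
  mag <- acc_magnitude(prepped)
  onset <- detect_onset(prepped$t, mag, stim_onset, window = window_s)
  df <- tibble::tibble(t = prepped$t, mag = mag)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$mag)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_vline(xintercept = stim_onset, linetype = "dashed",
                        colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = expression("|a| (m/s"^2 * ")"),
                  title = "Linear-acceleration magnitude",
                  subtitle = sprintf("status: %s", onset$status))
  if (!is.na(onset$threshold_used)) {
    p <- p + ggplot2::geom_hline(yintercept = onset$threshold_used,
                                 linetype = "dotted", colour = "firebrick")
  }
  if (!is.na(onset$onset_time)) {
    p <- p + ggplot2::geom_vline(xintercept = onset$onset_time,
                                 colour = "firebrick")
  }
  p
}

#' Cell-mean plot: RT or distance by category and direction
#'
#' Participant-averaged cell means with standard-error bars, split by
#' movement direction -- the standard way mAAT condition effects are shown.
#'
#' @param cells Cell table from [aggregate_cells()].
#' @param measure `"rt"` or `"distance"`.
#' @return A ggplot object.
#' @export
plot_cells <- function(cells, measure = c("rt", "distance")) {
  measure <- match.arg(measure)
  col <- if (measure == "rt") "mean_rt_ms" else "mean_distance_m"
  lab <- if (measure == "rt") "mean RT (ms)" else "mean distance (m)"
  summ <- cells |>
    dplyr::group_by(.data$category, .data$direction) |>
    dplyr::summarise(m = mean(.data[[col]]),
                     se = sd(.data[[col]]) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$category, y = .data$m,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$m - .data$se, ymax = .data$m + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = lab, fill = "direction")
}

#' @export
autoplot.maat_rm_anova <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$statistic)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("p = %.3g", .data$p.value)), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "F",
                  title = sprintf("2x2 RM-ANOVA on %s (%s), n = %d",
                                  object$measure,
                                  paste(object$categories, collapse = " vs "),
                                  object$n))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
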