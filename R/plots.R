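#' Plot a pulse waveform
#'
#' @param object A `ppg_waveform` tibble.
#' @param max_seconds Plot at most this many seconds from the start
#'   (default 10; whole recordings are unreadable at 100 Hz).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppg_waveform
#' @export
autoplot.ppg_waveform <- function(object, max_seconds = 10, ...) {
  df <- dplyr::filter(object,
                      .data$time_s <= min(.data$time_s) + max_seconds)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude (ADC units)",
                  title = "Fingertip pulse waveform")
}

#' Plot a time-resolved HRV series with the task phases shaded
#'
#' @param object An `hrv_series` tibble.
#' @param phases Optional [phase_definition()] used to shade the mental-task
#'   phase.
#' @param ... Unused.
#' @return A ggplot object with facets for HR, HF and LF/HF.
#' @method autoplot hrv_series
#' @export
autoplot.hrv_series <- function(object, phases = NULL, ...) {
  long <- tidyr::pivot_longer(
    object, c("hr_bpm", "hf_ms2", "lfhf"),
    names_to = "measure", values_to = "value")
  long$measure <- factor(long$measure, c("hr_bpm", "hf_ms2", "lfhf"),
                         c("HR (bpm)", "HF (ms^2)", "LF/HF"))
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(.data$window_center_s, .data$value))
  if (!is.null(phases)) {
    b <- phases$boundaries
    p <- p + ggplot2::annotate("rect", xmin = b[2], xmax = b[3],
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  p + ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "window center (s)", y = NULL,
                  title = "Sliding-window HRV",
                  subtitle = if (!is.null(phases))
                    "shaded: mental task" else NULL)
}

#' Plot per-subject logit scores of a screening evaluation
#'
#' @param object A `screening_result`.
#' @param ... Unused.
#' @return A ggplot object: scores by true group, colored by prediction,
#'   with the decision threshold.
#' @method autoplot screening_result
#' @export
autoplot.screening_result <- function(object, ...) {
  df <- object$subjects[!is.na(object$subjects$score), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$score,
                                   colour = .data$predicted)) +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "true group", y = "logit score",
                  colour = "predicted",
                  title = "Leave-one-out screening scores")
}

#' Normal quantile-quantile plot of randomized quantile residuals
#'
#' @param object A `residual_diagnostics`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot residual_diagnostics
#' @export
autoplot.residual_diagnostics <- function(object, ...) {
  ggplot2::ggplot(object$residuals, ggplot2::aes(sample = .data$residual)) +
    ggplot2::geom_qq() +
    ggplot2::geom_qq_line(linetype = 2) +
    ggplot2::labs(
      title = "Randomized quantile residuals vs standard normal",
      subtitle = sprintf("Anderson-Darling A = %.3f, p = %.3f",
                         object$statistic, object$p_value))
}
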