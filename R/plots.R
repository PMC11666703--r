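# ggplot2 convenience graphics for the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.ppg_segment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                       y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Amplitude",
                  title = "PPG segment") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ppg_cycle <- function(object, ...) {
  fid <- tryCatch(detect_fiducials(object), error = function(e) NULL)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                            y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time from foot (s)", y = "Normalized amplitude",
                  title = "Pulse cycle") +
    ggplot2::theme_minimal()
  if (!is.null(fid)) {
    fs <- attr(object, "sampling_rate")
    marks <- tibble(
      time_s = (c(fid$max_slope_idx, fid$sys_peak_idx,
                  fid$dia_peak_idx) - 1) / fs,
      amplitude = object$amplitude[c(fid$max_slope_idx, fid$sys_peak_idx,
                                     fid$dia_peak_idx)],
      point = c("max slope", "systolic peak", "diastolic peak"))
    p <- p + ggplot2::geom_point(data = marks,
                                 ggplot2::aes(colour = .data$point),
                                 size = 2)
  }
  p
}

#' Plot a magnitude spectrum
#' @param spectrum Output of [compute_spectrum()].
#' @param max_hz Upper frequency limit to display.
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum, max_hz = 10) {
  ggplot2::ggplot(dplyr::filter(spectrum, .data$frequency_hz <= max_hz),
                  ggplot2::aes(x = .data$frequency_hz,
                               y = .data$magnitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Magnitude",
                  title = "One-sided FFT magnitude spectrum") +
    ggplot2::theme_minimal()
}

#' Plot feature importances
#' @param importances Tibble from [gini_importance()].
#' @param top_n Show the `top_n` strongest features.
#' @return A ggplot.
#' @export
plot_importance <- function(importances, top_n = 20) {
  d <- head(importances[importances$importance > 0, ], top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$feature, .data$importance))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Gini importance", y = NULL,
                  title = "Decision-tree feature importance") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr,
                                             y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$test, ggplot2::aes(x = .data$observed,
                                            y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Measured BP (mmHg)", y = "Predicted BP (mmHg)",
                  title = "Cross-validated test predictions") +
    ggplot2::theme_minimal()
}

#' Correlation heat map of a feature table
#' @param correlations Matrix from [correlation_matrix()].
#' @return A ggplot.
#' @export
plot_correlation <- function(correlations) {
  d <- as.data.frame(as.table(correlations))
  names(d) <- c("x", "y", "r")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Feature correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
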