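#' Plot maximum class probability by classification outcome
#'
#' Box-and-whisker plots of each observation's maximal class-probability
#' (the winning vote fraction) split by true class and by whether the
#' classification was correct. Correct classifications of well-separated
#' classes concentrate near 1; misclassifications sit lower, reflecting the
#' forest's own uncertainty.
#'
#' @param object A `wb_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wb_report <- function(object, ...) {
  df <- object$observations
  df$outcome <- ifelse(df$correct, "correct", "incorrect")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$truth, y = .data$max_class_probability,
    fill = .data$outcome
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_fill_manual(values = c(correct = "#66a182", incorrect = "#d1495b")) +
    ggplot2::labs(
      x = NULL, y = "Maximum class probability", fill = NULL,
      title = "Classification certainty by outcome"
    ) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot feature importance
#'
#' Dot plot of the top features by overall mean decrease in accuracy.
#'
#' @param object A `wb_importance`.
#' @param top_n Number of features shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wb_importance <- function(object, top_n = 10, ...) {
  df <- utils::head(tibble::as_tibble(object), top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mda_overall, y = .data$feature)) +
    ggplot2::geom_point(size = 2, colour = "#2e4057") +
    ggplot2::labs(
      x = "Mean decrease in accuracy", y = NULL,
      title = "Feature importance"
    )
}

#' Plot a mean magnitude spectrum
#'
#' @param object A `wb_spectrum`.
#' @param ... Unused.
#' @return A ggplot of mean magnitude against frequency.
#' @export
autoplot.wb_spectrum <- function(object, ...) {
  df <- tibble::tibble(frequency = object$freqs, magnitude = object$mean_mag)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$magnitude)) +
    ggplot2::geom_line(colour = "#2e4057") +
    ggplot2::labs(x = "Frequency (Hz)", y = "Mean magnitude", title = "Mean spectrum")
}
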