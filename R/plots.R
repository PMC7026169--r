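#' Plot an axis scan
#'
#' Asymmetry curves (baseline-subtracted when available) as a function of
#' the candidate axis position; if an axis has been detected, pass it to
#' draw the detected Ori position.
#'
#' @param object An `edura_scan`.
#' @param axis Optional result of [detect_axis()] to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.edura_scan <- function(object, axis = NULL, ...) {
  long <- tidy(object)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$value,
                                          colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "axis position (bp)", y = "asymmetry",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(axis)) {
    p <- p + ggplot2::geom_vline(xintercept = axis$ori_bp, linetype = 2)
  }
  p
}

#' Plot digital versus analog control strengths
#'
#' @param object An `edura_control_scan`.
#' @param ... Unused.
#' @return A ggplot scatter of the per-contrast CTC pair.
#' @export
autoplot.edura_control_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$analog_ctc,
                                       y = .data$digital_ctc)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "analog control strength (CTC)",
                  y = "digital control strength (CTC)",
                  subtitle = paste0("Spearman = ",
                                    signif(attr(object, "spearman"), 3))) +
    ggplot2::theme_minimal()
}

#' Plot a corrected-importance profile
#'
#' @param object An `edura_importance` from [corrected_importance()].
#' @param ... Unused.
#' @return A ggplot bar chart of corrected importances.
#' @export
autoplot.edura_importance <- function(object, ...) {
  df <- as_tibble(object)
  df$feature <- factor(df$feature, levels = df$feature)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$corrected)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "corrected importance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot importance-CTC correlations
#'
#' Bar chart of the per-feature Spearman correlations with the analog and
#' digital control strengths, colored by feature class (analog / digital /
#' dual), mirroring the standard presentation of this analysis.
#'
#' @param correlations Output of [importance_ctc_correlation()].
#' @return A ggplot.
#' @export
plot_importance_correlation <- function(correlations) {
  long <- tidyr::pivot_longer(correlations,
                              c("spearman_analog", "spearman_digital"),
                              names_to = "against", values_to = "spearman")
  long$against <- sub("spearman_", "", long$against)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature, y = .data$spearman,
                                     fill = .data$feature_class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~against) +
    ggplot2::labs(x = NULL, y = "Spearman correlation", fill = "feature class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
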