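#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ECG segment
#'
#' @param object An [ecg_segment].
#' @param ... Unused.
#' @return A ggplot of amplitude against time.
#' @export
autoplot.ecg_segment <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time [s]", y = "amplitude",
      title = sprintf("%s (%s, %g Hz)", object$source_id, object$label,
                      object$fs)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object An `ecg_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot of TPR against FPR with the chance diagonal.
#' @export
autoplot.ecg_roc <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("ROC (AUC = %.4f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a benchmark's ROC curve
#'
#' @param object A `wafe_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wafe_benchmark <- function(object, ...) {
  autoplot(object$roc) +
    ggplot2::ggtitle(sprintf(
      "CHF vs %s, %s: recognition %.2f%%, AUC %.4f",
      object$params$background_class, toupper(object$params$extractor),
      object$report$recognition_rate, auc(object$roc)
    ))
}

#' Per-class feature profiles
#'
#' Draws every feature vector of a feature table as a line over the
#' terminal-node index, coloured by class: the visual check that vectors
#' of a class share a subband-energy morphology distinct from the other
#' class's.
#'
#' @param features A feature tibble from [extract_features()].
#' @return A ggplot.
#' @export
plot_feature_profiles <- function(features) {
  long <- tidyr::pivot_longer(features,
                              cols = dplyr::matches("^node_\\d+$"),
                              names_to = "node", values_to = "value")
  long$node <- as.integer(sub("node_", "", long$node))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$node, y = .data$value,
                                     group = .data$source_id,
                                     colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.4) +
    ggplot2::labs(x = "terminal node", y = attr(features, "extractor"),
                  colour = "class") +
    ggplot2::theme_minimal()
}
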