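# ggplot2 displays for the pipeline's tabular artifacts.

#' Plot an elimination trace
#'
#' Validation accuracy against the number of removed features, with the
#' selected subset marked.
#'
#' @param object An `fw_rfe_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fw_rfe_result <- function(object, ...) {
  tr <- object$trace
  sel <- object$selection
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$val_accuracy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_vline(xintercept = sel$n_removed, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "features removed", y = "validation accuracy",
                  title = sprintf("%s: %d of %d features retained",
                                  object$extractor, length(sel$features),
                                  length(object$features))) +
    ggplot2::theme_minimal()
}

#' Plot a training log
#'
#' @param object An `ecg_extractor`, `diagnosis_head` or `fwrfe_trained`.
#' @param ... Unused.
#' @return A ggplot of validation accuracy (and loss) per epoch.
#' @export
plot_training_log <- function(object, ...) {
  log <- object$log
  stopifnot(!is.null(log))
  long <- tidyr::pivot_longer(log, c("train_loss", "val_accuracy"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap
#'
#' @param x A `confusion_counts`.
#' @param ... Unused.
#' @return A ggplot heatmap of the 2x2 confusion matrix.
#' @export
plot_confusion <- function(x, ...) {
  tab <- confusion_table(x)
  tab$truth <- factor(tab$truth, levels = c(0, 1), labels = c("normal", "abnormal"))
  tab$predicted <- factor(tab$predicted, levels = c(0, 1),
                          labels = c("normal", "abnormal"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                    fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey60", high = "firebrick") +
    ggplot2::labs(x = "predicted", y = "truth") +
    ggplot2::theme_minimal()
}
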