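# Binary diagnostic metrics: confusion counts and the four report metrics
# (accuracy, precision, recall, F1), positive class = abnormal (label 1).

#' Confusion counts of binary predictions
#'
#' @param predicted,truth Equal-length binary 0/1 vectors; 1 (abnormal) is
#'   the positive class.
#' @return A `confusion_counts` list with TP, TN, FP, FN; the four counts
#'   partition the records.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` must have equal length.", call. = FALSE)
  }
  predicted <- check_binary(predicted, "predicted")
  truth <- check_binary(truth, "truth")
  structure(list(TP = sum(predicted == 1 & truth == 1),
                 TN = sum(predicted == 0 & truth == 0),
                 FP = sum(predicted == 1 & truth == 0),
                 FN = sum(predicted == 0 & truth == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

#' The four report metrics from confusion counts
#'
#' accuracy = (TP+TN)/n (the "subset accuracy" of a binary task is plain
#' accuracy), precision = TP/(TP+FP), recall = TP/(TP+FN),
#' f1 = 2*precision*recall/(precision+recall). A zero denominator yields
#' `NA` (undefined), never a silent 0.
#'
#' @param x A `confusion_counts`, or a binary vector of predictions (with
#'   `truth` supplied).
#' @param truth Binary truth vector when `x` is a prediction vector.
#' @return One-row tibble: accuracy, precision, recall, f1, n.
#' @export
classification_metrics <- function(x, truth = NULL) {
  if (!inherits(x, "confusion_counts")) x <- confusion_counts(x, truth)
  n <- x$TP + x$TN + x$FP + x$FN
  if (n == 0L) stop("no records to evaluate.", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(x$TP, x$TP + x$FP)
  recall <- safe_div(x$TP, x$TP + x$FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(accuracy = (x$TP + x$TN) / n, precision = precision,
                 recall = recall, f1 = f1, n = n)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * p * r / (p + r)`; `NA` when both are zero or either is
#' undefined.
#'
#' @param precision,recall Values in \[0, 1\].
#' @return The F1 score.
#' @export
f1_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | precision + recall == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}

#' Per-model metric report
#'
#' Computes the four metrics for each model in a long table of predictions —
#' the layout of the published model-comparison tables.
#'
#' @param predictions Tibble with columns `model`, `predicted_label`,
#'   `true_label`.
#' @return Tibble with one row per model: accuracy, precision, recall, f1, n.
#' @export
metric_report <- function(predictions) {
  need <- c("model", "predicted_label", "true_label")
  if (!all(need %in% names(predictions))) {
    stop(sprintf("`predictions` must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  predictions |>
    dplyr::group_by(.data$model) |>
    dplyr::reframe(classification_metrics(.data$predicted_label, .data$true_label)) |>
    dplyr::ungroup()
}

#' Format a metric report as a Markdown table
#'
#' Accuracy is printed as a percentage with 2 decimals; precision, recall
#' and F1 with 3 decimals, matching conventional reporting.
#'
#' @param report Output of [metric_report()] (or any tibble with `model`,
#'   `accuracy`, `precision`, `recall`, `f1`).
#' @return Character vector of Markdown lines.
#' @export
format_metric_report <- function(report) {
  fmt3 <- function(v) ifelse(is.na(v), "-", sprintf("%.3f", v))
  c("| Model | Accuracy | Precision | Recall | F1 Score |",
    "|---|---|---|---|---|",
    sprintf("| %s | %.2f%% | %s | %s | %s |",
            report$model, 100 * report$accuracy, fmt3(report$precision),
            fmt3(report$recall), fmt3(report$f1)))
}

#' Confusion matrix as a tidy tibble
#'
#' @param x A `confusion_counts`.
#' @return Tibble with `truth`, `predicted`, `n` (four rows), convenient for
#'   CSV export or a heatmap.
#' @export
confusion_table <- function(x) {
  stopifnot(inherits(x, "confusion_counts"))
  tibble::tibble(truth = c(1L, 0L, 0L, 1L),
                 predicted = c(1L, 0L, 1L, 0L),
                 n = c(x$TP, x$TN, x$FP, x$FN))
}
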