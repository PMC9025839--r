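# Diagnostic module: a single sigmoid unit over the concatenated retained
# features, trained with Adam at learning rate 1e-4 (the rest of the
# pipeline trains at 1e-3), BCE + L2, plateau decay and early stopping.

#' Train the fused diagnostic head
#'
#' @param x_train,y_train Training feature matrix (records x features) and
#'   binary labels.
#' @param x_val,y_val Validation data (drives plateau decay, early stopping
#'   and best-epoch selection).
#' @param config A [train_config()]; the diagnostic module defaults to
#'   learning rate 1e-4.
#' @param threshold Decision threshold on the predicted probability.
#' @return A `diagnosis_head`: trained single-unit network, `log` tibble,
#'   `best_val_accuracy`, feature names and threshold.
#' @export
train_head <- function(x_train, y_train, x_val = NULL, y_val = NULL,
                       config = train_config(lr = 1e-4), threshold = 0.5) {
  stopifnot(is.matrix(x_train))
  check_scalar_number(threshold, "threshold", 1e-12, 1 - 1e-12)
  if (any(!is.finite(x_train))) stop("features contain non-finite values.", call. = FALSE)
  fit <- train_network(list(dense_layer(1, "sigmoid")), ncol(x_train),
                       x_train, y_train, x_val, y_val, config)
  structure(list(net = fit$net, log = fit$log,
                 best_val_accuracy = fit$best_val_accuracy,
                 epochs_run = fit$epochs_run,
                 features = colnames(x_train), threshold = threshold),
            class = "diagnosis_head")
}

#' @export
print.diagnosis_head <- function(x, ...) {
  cat(sprintf("<diagnosis_head> %d features, threshold %.2f, best validation accuracy %s\n",
              length(x$net$layers[[1]]$W), x$threshold,
              ifelse(is.na(x$best_val_accuracy), "NA",
                     sprintf("%.3f", x$best_val_accuracy))))
  invisible(x)
}

#' Coefficients of a trained diagnosis head
#'
#' @param object A `diagnosis_head`.
#' @param ... Unused.
#' @return Named vector: `(bias)` followed by one weight per feature.
#' @export
coef.diagnosis_head <- function(object, ...) {
  w <- as.vector(object$net$layers[[1]]$W)
  names(w) <- object$features %||% sprintf("x%d", seq_along(w))
  c("(bias)" = object$net$layers[[1]]$b, w)
}

#' Predict diagnoses from features
#'
#' `probability = sigmoid(features %*% w + b)`; `predicted_label` is 1
#' (abnormal) iff the probability is at or above the threshold. Raising the
#' threshold can only turn 1-predictions into 0s, never the reverse.
#'
#' @param object A trained `diagnosis_head`.
#' @param newdata Feature matrix with the same columns the head was trained
#'   on.
#' @param threshold Decision threshold (defaults to the head's).
#' @param ... Unused.
#' @return Tibble with `probability` and `predicted_label`.
#' @export
predict.diagnosis_head <- function(object, newdata, threshold = object$threshold,
                                   ...) {
  stopifnot(is.matrix(newdata))
  w <- object$net$layers[[1]]$W
  if (ncol(newdata) != nrow(w)) {
    stop(sprintf("feature width %d does not match head width %d.",
                 ncol(newdata), nrow(w)), call. = FALSE)
  }
  p <- net_predict(object$net, newdata)
  tibble::tibble(probability = p,
                 predicted_label = as.integer(p >= threshold))
}
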