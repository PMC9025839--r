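# Recursive feature elimination driven by weight norms (FW-RFE). The
# per-feature ranking score is the sum of squared connection weights from
# that feature into the classifier's hidden layer; each iteration removes
# the lowest-scoring feature, re-fits the fully connected head on the
# reduced set, and records its validation accuracy. The subset with the best
# recorded accuracy is kept.

#' Weight-norm ranking scores
#'
#' For a (features x hidden units) weight matrix, the score of feature j is
#' `c_j = sum_n w[j, n]^2` over all hidden units. Scores are nonnegative and
#' invariant to hidden-unit ordering.
#'
#' @param weights Numeric matrix, features in rows, hidden units in columns;
#'   row names (feature labels) are carried through.
#' @return Named nonnegative numeric vector of per-feature scores.
#' @export
ranking_scores <- function(weights) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix (features x hidden units).",
         call. = FALSE)
  }
  bad <- which(!apply(is.finite(weights), 1L, all))
  if (length(bad) > 0) {
    lab <- rownames(weights)[bad[1]] %||% as.character(bad[1])
    stop(sprintf("non-finite weight in feature '%s'.", lab), call. = FALSE)
  }
  scores <- rowSums(weights^2)
  names(scores) <- rownames(weights) %||% sprintf("f%04d", seq_len(nrow(weights)))
  scores
}

#' Index of the lowest-ranked feature
#'
#' Returns the position of the minimal ranking score; ties are broken by the
#' lowest feature index, so elimination is deterministic.
#'
#' @param scores Numeric vector of ranking scores.
#' @return Integer index of the feature to eliminate.
#' @export
argmin_feature <- function(scores) {
  if (length(scores) == 0L) stop("ranking scores are empty.", call. = FALSE)
  which.min(scores)
}

#' Fully connected re-fit procedures for FW-RFE
#'
#' `fit_sigmoid_head()` returns the default re-fit: a
#' Dense(hidden, ReLU) -> Dense(1, sigmoid) head trained with Adam on binary
#' cross-entropy + L2 for a fixed epoch budget; its first-layer weights are
#' the ranking input. `fit_least_squares()` returns a deterministic convex
#' stub (ridge least squares on the 0/1 labels, one "hidden unit" per
#' feature coefficient) used for exact, enumerable elimination traces.
#'
#' Both return a function `f(x, y, seed)` yielding a list with `weights`
#' (features x hidden matrix, feature row names) and `predict` (a function
#' of a feature matrix returning probabilities).
#'
#' @param hidden Hidden width of the re-fit head (default 10).
#' @param epochs Fixed epoch budget per re-fit (default 30).
#' @param lr,l2,batch_size Optimizer settings, as [train_config()].
#' @param ridge Ridge penalty of the least-squares stub.
#' @return A re-fit function.
#' @export
fit_sigmoid_head <- function(hidden = 10, epochs = 30, lr = 0.001, l2 = 0.001,
                             batch_size = 64) {
  force(hidden); force(epochs); force(lr); force(l2); force(batch_size)
  function(x, y, seed) {
    cfg <- train_config(lr = lr, l2 = l2, batch_size = batch_size,
                        max_epochs = epochs, seed = seed)
    fit <- train_network(
      list(dense_layer(hidden, "relu"), dense_layer(1, "sigmoid")),
      ncol(x), x, y, config = cfg)
    W <- fit$net$layers[[1]]$W
    rownames(W) <- colnames(x)
    list(weights = W,
         predict = function(newx) net_predict(fit$net, newx))
  }
}

#' @rdname fit_sigmoid_head
#' @export
fit_least_squares <- function(ridge = 1e-6) {
  force(ridge)
  function(x, y, seed = NULL) {
    X1 <- cbind(1, x)
    A <- crossprod(X1) + diag(ridge, ncol(X1))
    beta <- solve(A, crossprod(X1, as.numeric(y)))
    W <- matrix(beta[-1], ncol = 1)
    rownames(W) <- colnames(x)
    list(weights = W,
         predict = function(newx) as.vector(cbind(1, newx) %*% beta))
  }
}

#' Run weight-norm recursive feature elimination
#'
#' Starting from the full feature set: fit the fully connected head once,
#' then repeat until `min_features` remain — rank features by
#' [ranking_scores()] of the current fit's first-layer weights, remove the
#' [argmin_feature()] from the training and validation matrices, re-fit on
#' the reduced set, and record its validation accuracy (proportion correct
#' at threshold 0.5). Each re-fit starts from a fresh initialization with a
#' seed derived from (`seed`, step), so iterations are not warm-started and
#' the whole trace is reproducible.
#'
#' @param x_train,y_train Training feature matrix (records x features, with
#'   column names) and binary labels.
#' @param x_val,y_val Validation feature matrix (same columns) and labels.
#' @param fit Re-fit procedure, e.g. [fit_sigmoid_head()] (default) or
#'   [fit_least_squares()].
#' @param min_features Stop when this many features remain (default 1; a
#'   0-feature classifier is undefined).
#' @param seed Integer seed.
#' @param extractor Optional extractor name carried into the results.
#' @return An `fw_rfe_result`: `trace` tibble (step, removed, n_remaining,
#'   val_accuracy), the original `features`, and `selection` — the best
#'   subset per [select_best()].
#' @export
run_fw_rfe <- function(x_train, y_train, x_val, y_val,
                       fit = fit_sigmoid_head(), min_features = 1, seed = 1,
                       extractor = attr(x_train, "extractor") %||% "features") {
  force(extractor)
  y_train <- check_binary(y_train, "y_train")
  y_val <- check_binary(y_val, "y_val")
  if (is.null(colnames(x_train))) {
    colnames(x_train) <- sprintf("f%04d", seq_len(ncol(x_train)))
  }
  if (is.null(colnames(x_val))) colnames(x_val) <- colnames(x_train)
  if (!identical(colnames(x_train), colnames(x_val))) {
    stop("training and validation feature matrices must share columns.",
         call. = FALSE)
  }
  n_features <- ncol(x_train)
  if (n_features < 2L) stop("at least 2 features are required.", call. = FALSE)
  check_scalar_number(min_features, "min_features", 1, n_features - 1)

  features <- colnames(x_train)
  current <- fit(x_train, y_train, derive_seed(seed, 0L))
  steps <- vector("list", n_features - min_features)
  removed_order <- character(n_features - min_features)
  for (k in seq_len(n_features - min_features)) {
    scores <- ranking_scores(current$weights)
    h <- argmin_feature(scores)
    removed_order[k] <- colnames(x_train)[h]
    x_train <- x_train[, -h, drop = FALSE]
    x_val <- x_val[, -h, drop = FALSE]
    current <- fit(x_train, y_train, derive_seed(seed, k))
    acc <- mean((current$predict(x_val) >= 0.5) == (y_val == 1))
    steps[[k]] <- tibble::tibble(step = k, removed = removed_order[k],
                                 n_remaining = ncol(x_train),
                                 val_accuracy = acc)
  }
  trace <- dplyr::bind_rows(steps)
  res <- structure(list(trace = trace, features = features,
                        extractor = extractor, seed = as.integer(seed)),
                   class = "fw_rfe_result")
  res$selection <- select_best(res)
  res
}

#' Select the best-accuracy feature subset from an elimination trace
#'
#' Returns the feature set left after the step with the highest recorded
#' validation accuracy; among ties, the latest step (fewest features) wins,
#' favouring parsimony.
#'
#' @param x An `fw_rfe_result` from [run_fw_rfe()].
#' @return An `fw_rfe_selection`: `extractor`, retained `features`, their
#'   `indices` in the original matrix, `val_accuracy`, `n_removed`.
#' @export
select_best <- function(x) {
  stopifnot(inherits(x, "fw_rfe_result"))
  trace <- x$trace
  if (nrow(trace) == 0L) stop("elimination trace is empty.", call. = FALSE)
  best <- max(which(trace$val_accuracy == max(trace$val_accuracy)))
  retained <- setdiff(x$features, trace$removed[seq_len(best)])
  structure(list(extractor = x$extractor, features = retained,
                 indices = match(retained, x$features),
                 val_accuracy = trace$val_accuracy[best],
                 n_removed = best),
            class = "fw_rfe_selection")
}

#' @export
print.fw_rfe_result <- function(x, ...) {
  cat(sprintf(
    "<fw_rfe_result> %s: %d features -> %d retained (val accuracy %.3f after %d removals)\n",
    x$extractor, length(x$features), length(x$selection$features),
    x$selection$val_accuracy, x$selection$n_removed))
  invisible(x)
}

#' @export
print.fw_rfe_selection <- function(x, ...) {
  cat(sprintf("<fw_rfe_selection> %s: %d features retained, val accuracy %.3f\n",
              x$extractor, length(x$features), x$val_accuracy))
  invisible(x)
}

#' Concatenate the retained features of several extractors
#'
#' Subsets each feature matrix to its selection and binds the columns in the
#' order given (A -> B -> C). Column names become
#' `<extractor>.<feature>` and the attribute `provenance` maps every output
#' column back to its extractor and original feature.
#'
#' @param selections List of `fw_rfe_selection` objects.
#' @param matrices List of feature matrices (same order, equal row counts).
#' @return A records x (sum of retained sizes) matrix with a `provenance`
#'   tibble attribute.
#' @export
concatenate_selected <- function(selections, matrices) {
  if (length(selections) != length(matrices) || length(selections) == 0L) {
    stop("`selections` and `matrices` must be non-empty lists of equal length.",
         call. = FALSE)
  }
  n_rows <- unique(vapply(matrices, nrow, integer(1)))
  if (length(n_rows) != 1L) {
    stop("feature matrices must have identical row counts.", call. = FALSE)
  }
  parts <- vector("list", length(selections))
  prov <- vector("list", length(selections))
  for (i in seq_along(selections)) {
    sel <- selections[[i]]
    stopifnot(inherits(sel, "fw_rfe_selection"))
    if (length(sel$features) == 0L) {
      stop(sprintf("selection for '%s' is empty; at least one feature per extractor is required.",
                   sel$extractor), call. = FALSE)
    }
    m <- matrices[[i]]
    if (is.null(colnames(m))) colnames(m) <- sprintf("f%04d", seq_len(ncol(m)))
    missing_f <- setdiff(sel$features, colnames(m))
    if (length(missing_f) > 0) {
      stop(sprintf("matrix %d lacks selected features: %s", i,
                   paste(utils::head(missing_f, 5), collapse = ", ")), call. = FALSE)
    }
    sub <- m[, sel$features, drop = FALSE]
    colnames(sub) <- paste(sel$extractor, sel$features, sep = ".")
    parts[[i]] <- sub
    prov[[i]] <- tibble::tibble(column = colnames(sub),
                                extractor = sel$extractor,
                                feature = sel$features)
  }
  out <- do.call(cbind, parts)
  attr(out, "provenance") <- dplyr::bind_rows(prov)
  out
}
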