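# End-to-end orchestration: train the three extractors independently, prune
# each extractor's features with FW-RFE, concatenate the retained features
# and train the fused diagnostic head; evaluate everything on the test split.

#' Run the full CNN + FW-RFE diagnosis pipeline
#'
#' Given a dataset with a `split` column (see [stratified_split()] or
#' [build_cohort()]), this trains each extractor independently on the train
#' split (early stopping against the validation split), extracts each
#' extractor's flattened final-pooling features, prunes them per extractor
#' with [run_fw_rfe()], concatenates the retained features in extractor
#' order, trains the fused sigmoid head, and evaluates the fused model and
#' each single-CNN baseline on the test split. All randomness derives from
#' `seed`, so reruns reproduce identical traces, feature sets and
#' predictions.
#'
#' @param dataset An `ecg_dataset` (already preprocessed: filtered and, for
#'   the reduced architectures, decimated).
#' @param records Tibble with `record_id`, `label`, `split`; defaults to a
#'   60/20/20 stratified split of the dataset's records.
#' @param specs Named list of [extractor_spec()]s; defaults to
#'   [reduced_extractor_specs()] at the dataset's record length.
#' @param extractor_config [train_config()] for extractor pre-training
#'   (lr 1e-3).
#' @param head_config [train_config()] for the diagnostic head (lr 1e-4).
#' @param rfe_fit Re-fit procedure for FW-RFE (default [fit_sigmoid_head()]).
#' @param min_features Minimum features per extractor kept in the trace.
#' @param seed Integer seed fanned out to per-stage substreams.
#' @return An `fwrfe_fit` with the extractors, FW-RFE results, fused head,
#'   test predictions and the per-model metric report.
#' @export
fwrfe_pipeline <- function(dataset,
                           records = NULL,
                           specs = NULL,
                           extractor_config = NULL,
                           head_config = NULL,
                           rfe_fit = fit_sigmoid_head(),
                           min_features = 1,
                           seed = 1) {
  stopifnot(inherits(dataset, "ecg_dataset"))
  if (is.null(records)) {
    records <- stratified_split(dataset$records, seed = derive_seed(seed, 901L))
  }
  stopifnot(all(c("record_id", "label", "split") %in% names(records)))
  len <- ncol(dataset$signals[[1]])
  if (is.null(specs)) specs <- reduced_extractor_specs(input_length = len)
  if (is.null(extractor_config)) {
    extractor_config <- train_config(lr = 0.001, max_epochs = 40, seed = seed)
  }
  if (is.null(head_config)) {
    head_config <- train_config(lr = 1e-4, max_epochs = 200, seed = derive_seed(seed, 800L))
  }

  ids <- split(records$record_id, records$split)
  labs <- split(records$label, records$split)
  x <- lapply(ids, function(v) as_input_array(dataset, v))

  extractors <- vector("list", length(specs))
  names(extractors) <- names(specs)
  for (i in seq_along(specs)) {
    cfg <- extractor_config
    cfg$seed <- derive_seed(seed, 100L + i)
    extractors[[i]] <- train_extractor(specs[[i]], x$train, labs$train,
                                       x$validation, labs$validation, cfg)
  }

  feats <- lapply(extractors, function(e) {
    lapply(x, function(xx) extract_features(e, xx))
  })

  rfe <- vector("list", length(extractors))
  names(rfe) <- names(extractors)
  for (i in seq_along(extractors)) {
    rfe[[i]] <- run_fw_rfe(feats[[i]]$train, labs$train,
                           feats[[i]]$validation, labs$validation,
                           fit = rfe_fit, min_features = min_features,
                           seed = derive_seed(seed, 200L + i),
                           extractor = extractors[[i]]$name)
  }
  selections <- lapply(rfe, `[[`, "selection")

  fused <- lapply(c(train = "train", validation = "validation", test = "test"),
                  function(s) {
    concatenate_selected(selections, lapply(feats, function(f) f[[s]]))
  })
  head_fit <- train_head(fused$train, labs$train, fused$validation,
                         labs$validation, head_config)

  test_pred <- predict(head_fit, fused$test)
  predictions <- tibble::tibble(
    model = "fused",
    record_id = ids$test,
    probability = test_pred$probability,
    predicted_label = test_pred$predicted_label,
    true_label = as.integer(labs$test)
  )
  for (i in seq_along(extractors)) {
    p <- net_predict(extractors[[i]]$net, x$test)
    predictions <- dplyr::bind_rows(predictions, tibble::tibble(
      model = extractors[[i]]$name,
      record_id = ids$test,
      probability = p,
      predicted_label = as.integer(p >= 0.5),
      true_label = as.integer(labs$test)
    ))
  }

  structure(list(extractors = extractors, rfe = rfe, selections = selections,
                 head = head_fit, records = records,
                 predictions = predictions,
                 metrics = metric_report(predictions),
                 seed = as.integer(seed)),
            class = "fwrfe_fit")
}

#' @export
print.fwrfe_fit <- function(x, ...) {
  cat("<fwrfe_fit>\n")
  for (e in x$extractors) {
    sel <- x$rfe[[which(vapply(x$extractors, identical, logical(1), e))]]$selection
    cat(sprintf("  %s: %d -> %d features (val accuracy %.3f)\n",
                e$name, e$spec$n_features, length(sel$features), sel$val_accuracy))
  }
  cat(sprintf("  fused head: %d features, best val accuracy %.3f\n",
              length(x$head$features), x$head$best_val_accuracy))
  print(x$metrics)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fwrfe_fit <- function(x, ...) x$metrics

#' @exportS3Method generics::glance
glance.fwrfe_fit <- function(x, ...) {
  fused <- dplyr::filter(x$metrics, .data$model == "fused")
  singles <- dplyr::filter(x$metrics, .data$model != "fused")
  dplyr::mutate(fused,
                best_single_accuracy = max(singles$accuracy),
                fused_val_accuracy = x$head$best_val_accuracy,
                best_single_val_accuracy = max(vapply(
                  x$extractors, `[[`, numeric(1), "best_val_accuracy")),
                n_features_retained = length(x$head$features))
}

#' @exportS3Method generics::tidy
tidy.fw_rfe_result <- function(x, ...) x$trace

#' @exportS3Method generics::glance
glance.fw_rfe_result <- function(x, ...) {
  tibble::tibble(extractor = x$extractor,
                 n_features = length(x$features),
                 n_retained = length(x$selection$features),
                 reduction = 1 - length(x$selection$features) / length(x$features),
                 val_accuracy = x$selection$val_accuracy)
}
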