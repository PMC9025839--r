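# The three independently trained 1-D CNN feature extractors. Each is a
# stack of (valid, stride-1) conv + LeakyReLU blocks followed by max pooling,
# then Flatten -> Dense(10, ReLU) -> Dense(1, sigmoid) for pre-training on
# the binary labels. The "features" of a record are the flattened
# activations after the last pooling layer; the Dense(10) weight matrix over
# those features is what FW-RFE ranks.

#' Specification of a CNN feature extractor
#'
#' @param name Extractor name (e.g. "CNN-A").
#' @param layers Alternating [conv_layer()] / [pool_layer()] blocks; the
#'   pre-training head (flatten, Dense(10, ReLU), Dense(1, sigmoid)) is
#'   appended automatically and must not be included.
#' @param input_shape `c(channels, length)` of the records the extractor
#'   consumes.
#' @param hidden_units Width of the pre-training hidden layer whose weights
#'   feed the FW-RFE ranking (default 10).
#' @return An `extractor_spec` with the analytic feature count `n_features`.
#' @export
extractor_spec <- function(name, layers, input_shape, hidden_units = 10) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(input_shape) != 2L || any(input_shape < 1)) {
    stop_config("input_shape", "must be c(channels, length)")
  }
  check_scalar_number(hidden_units, "hidden_units", 1)
  bad <- vapply(layers, function(l) !l$type %in% c("conv", "maxpool"), logical(1))
  if (any(bad)) {
    stop_config("layers", "must contain only conv/pool layers (the head is added automatically)")
  }
  shapes <- trace_shapes(layers, as.integer(input_shape))
  final <- shapes[[length(shapes)]]
  structure(list(name = name, layers = layers,
                 input_shape = as.integer(input_shape),
                 hidden_units = as.integer(hidden_units),
                 n_features = as.integer(prod(final)),
                 feature_shape = final),
            class = "extractor_spec")
}

#' @export
print.extractor_spec <- function(x, ...) {
  cat(sprintf("<extractor_spec> %s: %d conv/pool layers, input %dx%d -> %d features\n",
              x$name, length(x$layers), x$input_shape[1], x$input_shape[2],
              x$n_features))
  invisible(x)
}

#' Committed extractor architectures
#'
#' `reduced_extractor_specs()` returns the three desk-scale architectures
#' used throughout the package's tests and examples: depths 3/4/5 conv+pool
#' blocks (the ensemble's value comes from depth diversity), first block 16
#' kernels of size 15, sized for decimated 100 Hz inputs on one CPU.
#' `paper_scale_extractor_specs()` returns the full-scale counterparts for
#' 500 Hz, 10 s records, first block 54 kernels of size 15, depths 3/4/5;
#' the deeper blocks are a committed, auditable choice since only the first
#' block and the Dense(10) head are pinned by the published description.
#'
#' @param input_length Samples per lead.
#' @param channels Number of leads (default 12).
#' @return Named list of three [extractor_spec()] objects (`cnn_a`, `cnn_b`,
#'   `cnn_c`).
#' @export
reduced_extractor_specs <- function(input_length = 1000, channels = 12) {
  list(
    cnn_a = extractor_spec("CNN-A", list(
      conv_layer(16, 15), pool_layer(4),
      conv_layer(16, 9), pool_layer(4),
      conv_layer(8, 5), pool_layer(4)
    ), c(channels, input_length)),
    cnn_b = extractor_spec("CNN-B", list(
      conv_layer(16, 15), pool_layer(3),
      conv_layer(16, 9), pool_layer(3),
      conv_layer(12, 7), pool_layer(3),
      conv_layer(8, 5), pool_layer(3)
    ), c(channels, input_length)),
    cnn_c = extractor_spec("CNN-C", list(
      conv_layer(16, 15), pool_layer(2),
      conv_layer(16, 9), pool_layer(2),
      conv_layer(16, 7), pool_layer(2),
      conv_layer(12, 5), pool_layer(2),
      conv_layer(8, 3), pool_layer(2)
    ), c(channels, input_length))
  )
}

#' @rdname reduced_extractor_specs
#' @export
paper_scale_extractor_specs <- function(input_length = 5000, channels = 12) {
  list(
    cnn_a = extractor_spec("CNN-A", list(
      conv_layer(54, 15), pool_layer(2),
      conv_layer(32, 9), pool_layer(2),
      conv_layer(16, 5), pool_layer(2)
    ), c(channels, input_length)),
    cnn_b = extractor_spec("CNN-B", list(
      conv_layer(54, 15), pool_layer(2),
      conv_layer(32, 9), pool_layer(2),
      conv_layer(24, 7), pool_layer(2),
      conv_layer(16, 5), pool_layer(2)
    ), c(channels, input_length)),
    cnn_c = extractor_spec("CNN-C", list(
      conv_layer(54, 15), pool_layer(2),
      conv_layer(32, 9), pool_layer(2),
      conv_layer(24, 7), pool_layer(2),
      conv_layer(16, 5), pool_layer(2),
      conv_layer(16, 3), pool_layer(2)
    ), c(channels, input_length))
  )
}

# Full pre-training layer list: conv/pool stack + flatten + Dense(10, relu)
# + Dense(1, sigmoid).
extractor_layers_with_head <- function(spec) {
  c(spec$layers,
    list(flatten_layer(),
         dense_layer(spec$hidden_units, "relu"),
         dense_layer(1, "sigmoid")))
}

#' Train one CNN feature extractor
#'
#' Trains the conv/pool stack end-to-end with its own sigmoid head on the
#' binary labels (Adam, BCE + L2, plateau decay, early stopping; see
#' [train_config()]) and returns the parameters of the best validation
#' epoch. Extractors are trained independently: each call seeds its own RNG
#' stream and shares no state with other extractors.
#'
#' @param spec An [extractor_spec()].
#' @param x_train,y_train Training array (records, channels, length) and
#'   binary labels.
#' @param x_val,y_val Validation data.
#' @param config A [train_config()]; extractors default to learning rate
#'   1e-3 (the diagnostic head, not the extractors, uses 1e-4).
#' @return An `ecg_extractor`: the trained network, the spec, the training
#'   `log` tibble and `best_val_accuracy`.
#' @export
train_extractor <- function(spec, x_train, y_train, x_val, y_val,
                            config = train_config(lr = 0.001)) {
  stopifnot(inherits(spec, "extractor_spec"))
  d <- dim(x_train)
  if (length(d) != 3L || d[2] != spec$input_shape[1] || d[3] != spec$input_shape[2]) {
    stop(sprintf("input shape (%s) does not match extractor input %dx%d.",
                 paste(d[-1], collapse = "x"),
                 spec$input_shape[1], spec$input_shape[2]), call. = FALSE)
  }
  fit <- train_network(extractor_layers_with_head(spec), spec$input_shape,
                       x_train, y_train, x_val, y_val, config)
  structure(list(name = spec$name, spec = spec, net = fit$net,
                 log = fit$log, best_val_accuracy = fit$best_val_accuracy,
                 epochs_run = fit$epochs_run),
            class = "ecg_extractor")
}

#' @export
print.ecg_extractor <- function(x, ...) {
  cat(sprintf("<ecg_extractor> %s: %d features, best validation accuracy %.3f\n",
              x$name, x$spec$n_features, x$best_val_accuracy))
  invisible(x)
}

# Number of layers forming the feature path (conv/pool stack + flatten).
feature_path_length <- function(extractor) length(extractor$spec$layers) + 1L

#' Extract the flattened final-pooling features of records
#'
#' Runs records through the trained conv/pool stack and flattens the last
#' pooling layer's activations: feature `f<k>` maps to kernel
#' `(k - 1) %% kernels + 1` at time index `(k - 1) %/% kernels + 1` of that
#' layer. Deterministic given fixed parameters.
#'
#' @param extractor A trained `ecg_extractor`.
#' @param x Array (records, channels, length) matching the extractor input.
#' @return A records x `n_features` matrix with feature names as column
#'   names and the extractor name as attribute `extractor`.
#' @export
extract_features <- function(extractor, x) {
  stopifnot(inherits(extractor, "ecg_extractor"))
  d <- dim(x)
  if (length(d) != 3L || d[2] != extractor$spec$input_shape[1] ||
      d[3] != extractor$spec$input_shape[2]) {
    stop(sprintf("record shape (%s) does not match extractor input %dx%d.",
                 paste(d[-1], collapse = "x"),
                 extractor$spec$input_shape[1], extractor$spec$input_shape[2]),
         call. = FALSE)
  }
  sub <- extractor$net
  sub$layers <- sub$layers[seq_len(feature_path_length(extractor))]
  out <- net_forward(sub, x)
  colnames(out) <- sprintf("f%04d", seq_len(ncol(out)))
  attr(out, "extractor") <- extractor$name
  out
}

#' First-hidden-layer weight matrix of a trained extractor head
#'
#' The (features x hidden units) weights connecting the flattened pooling
#' features to the Dense(10) layer — the quantity FW-RFE ranks.
#'
#' @param extractor A trained `ecg_extractor`.
#' @return A `n_features` x `hidden_units` matrix with feature row names.
#' @export
head_weight_matrix <- function(extractor) {
  stopifnot(inherits(extractor, "ecg_extractor"))
  W <- extractor$net$layers[[feature_path_length(extractor) + 1L]]$W
  rownames(W) <- sprintf("f%04d", seq_len(nrow(W)))
  W
}
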