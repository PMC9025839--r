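# Minimal 1-D CNN stack: valid convolution, max pooling, dense layers,
# Adam + binary cross-entropy + L2, plateau learning-rate decay and early
# stopping. Batched inputs are arrays of dim (batch, channels, length);
# flattened inputs are plain (batch x features) matrices. All heavy lifting
# is BLAS matrix multiplication via an im2col expansion.

#' Leaky rectified linear activation
#'
#' @param x Numeric vector/matrix/array.
#' @param slope Negative-side slope, in (0, 1).
#' @return `x` where `x >= 0`, `slope * x` elsewhere.
#' @export
leaky_relu <- function(x, slope = 0.01) {
  if (slope <= 0 || slope >= 1) stop_config("slope", "must be in (0, 1)")
  ifelse(x >= 0, x, slope * x)
}

#' Valid 1-D convolution of a (multi-channel) sequence
#'
#' Computes `y = f(sum_i w_i * x_i + b)` at every valid window position: a
#' plain sliding dot product with no padding, stride 1, so the output length
#' is `input length - kernel_size + 1`.
#'
#' @param x Numeric vector (one channel) or a channels x length matrix.
#' @param weights For a vector input, a numeric vector (one kernel) or a
#'   kernels x kernel_size matrix; for a matrix input, an array of dim
#'   (kernels, channels, kernel_size).
#' @param bias Per-kernel offset, recycled to the number of kernels.
#' @param activation Activation function applied elementwise; default identity.
#' @return A numeric vector if one kernel was given a vector input, otherwise
#'   a kernels x out_length matrix.
#' @export
conv1d_forward <- function(x, weights, bias = 0, activation = identity) {
  vec_in <- is.vector(x) && is.numeric(x)
  if (vec_in) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x)) stop("`x` must be a numeric vector or matrix.", call. = FALSE)
  ch <- nrow(x)
  len <- ncol(x)
  if (is.vector(weights) && is.numeric(weights)) {
    weights <- array(weights, dim = c(1L, 1L, length(weights)))
  } else if (is.matrix(weights)) {
    weights <- array(weights, dim = c(nrow(weights), 1L, ncol(weights)))
  }
  dw <- dim(weights)
  if (length(dw) != 3L || dw[2] != ch) {
    stop("`weights` must have dim (kernels, channels, kernel_size) matching `x`.",
         call. = FALSE)
  }
  k <- dw[1]
  ksize <- dw[3]
  if (ksize > len) {
    stop(sprintf("input length %d is shorter than kernel size %d.", len, ksize),
         call. = FALSE)
  }
  bias <- rep_len(bias, k)
  out_len <- len - ksize + 1L
  X <- array(x, dim = c(1L, ch, len))
  # weight matrix rows ordered (offset within channel, channel blocks)
  W <- matrix(aperm(weights, c(3L, 2L, 1L)), nrow = ch * ksize, ncol = k)
  Z <- im2col(X, ksize) %*% W
  Z <- sweep(Z, 2L, bias, "+")
  out <- activation(t(Z)) # kernels x out_len
  if (vec_in && k == 1L) drop(out) else out
}

#' Max pooling of a (multi-channel) sequence
#'
#' Returns the maximum over each block of `pool_size` consecutive values,
#' blocks advanced by `stride`.
#'
#' @param x Numeric vector or channels x length matrix.
#' @param pool_size Block size (>= 1).
#' @param stride Step between block starts; defaults to `pool_size`.
#' @return Same type as the input, pooled along time.
#' @export
max_pool <- function(x, pool_size, stride = pool_size) {
  vec_in <- is.vector(x) && is.numeric(x)
  if (vec_in) x <- matrix(x, nrow = 1L)
  if (length(x) == 0L) stop("`x` must be non-empty.", call. = FALSE)
  if (pool_size < 1L || stride < 1L) stop_config("pool_size/stride", "must be >= 1")
  len <- ncol(x)
  if (pool_size > len) stop("pool_size exceeds input length.", call. = FALSE)
  starts <- seq.int(1L, len - pool_size + 1L, by = stride)
  out <- vapply(starts, function(s) {
    apply(x[, s:(s + pool_size - 1L), drop = FALSE], 1L, max)
  }, numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x))
  if (vec_in) drop(out) else out
}

# ---- layer constructors -----------------------------------------------------

#' Layer specifications for a small 1-D CNN
#'
#' Building blocks for [extractor_spec()] and the internal trainer:
#' `conv_layer()` is a valid, stride-1 1-D convolution followed by LeakyReLU;
#' `pool_layer()` a max pooling step; `flatten_layer()` unrolls
#' (channels, length) activations into one feature vector; `dense_layer()`
#' a fully connected layer.
#'
#' @param kernels Number of convolution kernels.
#' @param kernel_size Kernel width (samples).
#' @param slope LeakyReLU negative slope.
#' @param pool_size,stride Max-pooling block size and step.
#' @param units Dense layer width.
#' @param activation One of "relu", "sigmoid", "linear".
#' @return A layer description list.
#' @name layers
NULL

#' @rdname layers
#' @export
conv_layer <- function(kernels, kernel_size, slope = 0.01) {
  check_scalar_number(kernels, "kernels", 1)
  check_scalar_number(kernel_size, "kernel_size", 1)
  if (slope <= 0 || slope >= 1) stop_config("slope", "must be in (0, 1)")
  list(type = "conv", kernels = as.integer(kernels),
       kernel_size = as.integer(kernel_size), slope = slope)
}

#' @rdname layers
#' @export
pool_layer <- function(pool_size, stride = pool_size) {
  check_scalar_number(pool_size, "pool_size", 1)
  check_scalar_number(stride, "stride", 1)
  list(type = "maxpool", pool_size = as.integer(pool_size),
       stride = as.integer(stride))
}

#' @rdname layers
#' @export
flatten_layer <- function() list(type = "flatten")

#' @rdname layers
#' @export
dense_layer <- function(units, activation = c("relu", "sigmoid", "linear")) {
  check_scalar_number(units, "units", 1)
  activation <- match.arg(activation)
  list(type = "dense", units = as.integer(units), activation = activation)
}

# Trace shapes through the layer list; input_shape = c(channels, length) or a
# single integer for flat inputs. Returns list of per-layer output shapes.
trace_shapes <- function(layers, input_shape) {
  shape <- input_shape
  out <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    shape <- switch(l$type,
      conv = {
        if (length(shape) != 2L) stop("conv layer needs (channels, length) input.", call. = FALSE)
        if (l$kernel_size > shape[2]) {
          stop(sprintf("layer %d: kernel size %d exceeds input length %d.",
                       i, l$kernel_size, shape[2]), call. = FALSE)
        }
        c(l$kernels, shape[2] - l$kernel_size + 1L)
      },
      maxpool = {
        if (length(shape) != 2L) stop("pool layer needs (channels, length) input.", call. = FALSE)
        if (l$pool_size > shape[2]) {
          stop(sprintf("layer %d: pool size %d exceeds input length %d.",
                       i, l$pool_size, shape[2]), call. = FALSE)
        }
        c(shape[1], length(seq.int(1L, shape[2] - l$pool_size + 1L, by = l$stride)))
      },
      flatten = {
        if (length(shape) != 2L) stop("flatten needs (channels, length) input.", call. = FALSE)
        prod(shape)
      },
      dense = {
        if (length(shape) != 1L) stop("dense layer needs a flat input.", call. = FALSE)
        l$units
      },
      stop(sprintf("unknown layer type '%s'.", l$type), call. = FALSE)
    )
    out[[i]] <- shape
  }
  out
}

# Initialize parameters. Uses the current RNG stream.
init_network <- function(layers, input_shape) {
  shapes <- trace_shapes(layers, input_shape)
  shape <- input_shape
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      fan_in <- shape[1] * l$kernel_size
      l$W <- matrix(stats::rnorm(fan_in * l$kernels, sd = sqrt(2 / fan_in)),
                    nrow = fan_in, ncol = l$kernels)
      l$b <- numeric(l$kernels)
    } else if (l$type == "dense") {
      fan_in <- shape[1]
      if (l$activation == "sigmoid") {
        # sigmoid layers are output units here; starting from zero makes the
        # head a convex logistic fit from p = 0.5 with no sign trap
        l$W <- matrix(0, nrow = fan_in, ncol = l$units)
      } else {
        l$W <- matrix(stats::rnorm(fan_in * l$units, sd = sqrt(2 / fan_in)),
                      nrow = fan_in, ncol = l$units)
      }
      l$b <- numeric(l$units)
    }
    layers[[i]] <- l
    shape <- shapes[[i]]
  }
  structure(list(layers = layers, input_shape = input_shape,
                 output_shape = shapes[[length(shapes)]]),
            class = "fwrfe_net")
}

# im2col: X (batch, channels, len) -> (batch*out_len, channels*kernel_size)
# row r corresponds to (batch index fastest, window position next); column
# block c holds the kernel_size offsets of channel c.
im2col <- function(X, ksize) {
  d <- dim(X)
  b <- d[1]; ch <- d[2]; len <- d[3]
  out_len <- len - ksize + 1L
  tidx <- rep(seq_len(out_len), times = ksize) + rep(seq_len(ksize) - 1L, each = out_len)
  M <- matrix(0, b * out_len, ch * ksize)
  for (c in seq_len(ch)) {
    M[, ((c - 1L) * ksize + 1L):(c * ksize)] <- matrix(X[, c, tidx], b * out_len, ksize)
  }
  M
}

# Forward pass. X: (batch, channels, len) array or (batch x features) matrix.
# Returns list(out = batch x out matrix (or array), caches) when cache = TRUE.
net_forward <- function(net, X, cache = FALSE) {
  caches <- if (cache) vector("list", length(net$layers)) else NULL
  A <- X
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      d <- dim(A); b <- d[1]; len <- d[3]
      out_len <- len - l$kernel_size + 1L
      M <- im2col(A, l$kernel_size)
      Z <- M %*% l$W
      Z <- sweep(Z, 2L, l$b, "+")
      G <- ifelse(Z >= 0, 1, l$slope)       # LeakyReLU gradient factor
      Zact <- Z * G
      if (cache) caches[[i]] <- list(M = M, G = G, in_dim = d)
      A <- aperm(array(Zact, c(b, out_len, l$kernels)), c(1L, 3L, 2L))
    } else if (l$type == "maxpool") {
      d <- dim(A); b <- d[1]; ch <- d[2]; len <- d[3]
      starts <- seq.int(1L, len - l$pool_size + 1L, by = l$stride)
      Y <- array(-Inf, c(b, ch, length(starts)))
      Amax <- array(0L, c(b, ch, length(starts)))
      for (s in seq_len(l$pool_size)) {
        cand <- A[, , starts + s - 1L, drop = FALSE]
        upd <- cand > Y
        Y[upd] <- cand[upd]
        Amax[upd] <- s
      }
      if (cache) caches[[i]] <- list(Amax = Amax, starts = starts, in_dim = d)
      A <- Y
    } else if (l$type == "flatten") {
      d <- dim(A)
      if (cache) caches[[i]] <- list(in_dim = d)
      A <- matrix(A, nrow = d[1])
    } else if (l$type == "dense") {
      Z <- A %*% l$W
      Z <- sweep(Z, 2L, l$b, "+")
      out <- switch(l$activation,
        relu = pmax(Z, 0),
        sigmoid = sigmoid(Z),
        linear = Z
      )
      if (cache) caches[[i]] <- list(A_in = A, Z = Z)
      A <- out
    }
  }
  if (cache) list(out = A, caches = caches) else A
}

# Backward pass from dOut (gradient w.r.t. the network output, same shape as
# the final activation output). For the final sigmoid + BCE case the caller
# passes the gradient w.r.t. the pre-activation z directly and sets
# `final_is_dz = TRUE`. Returns list of grads parallel to layers.
net_backward <- function(net, caches, dOut, final_is_dz = FALSE) {
  n <- length(net$layers)
  grads <- vector("list", n)
  dA <- dOut
  for (i in rev(seq_len(n))) {
    l <- net$layers[[i]]
    cc <- caches[[i]]
    if (l$type == "dense") {
      if (i == n && final_is_dz) {
        dZ <- dA
      } else {
        dZ <- switch(l$activation,
          relu = dA * (cc$Z > 0),
          sigmoid = { p <- sigmoid(cc$Z); dA * p * (1 - p) },
          linear = dA
        )
      }
      grads[[i]] <- list(W = crossprod(cc$A_in, dZ), b = colSums(dZ))
      dA <- dZ %*% t(l$W)
    } else if (l$type == "flatten") {
      dA <- array(dA, cc$in_dim)
    } else if (l$type == "maxpool") {
      d <- cc$in_dim
      dX <- array(0, d)
      for (s in seq_len(l$pool_size)) {
        mask <- (cc$Amax == s)
        if (any(mask)) {
          idx <- cc$starts + s - 1L
          dX[, , idx] <- dX[, , idx] + dA * mask
        }
      }
      dA <- dX
    } else if (l$type == "conv") {
      d <- cc$in_dim; b <- d[1]; ch <- d[2]; len <- d[3]
      ksize <- l$kernel_size
      out_len <- len - ksize + 1L
      dZmat <- matrix(aperm(dA, c(1L, 3L, 2L)), b * out_len, l$kernels) * cc$G
      grads[[i]] <- list(W = crossprod(cc$M, dZmat), b = colSums(dZmat))
      if (i > 1L) {
        dM <- dZmat %*% t(l$W)
        dX <- array(0, d)
        for (c in seq_len(ch)) {
          block <- dM[, ((c - 1L) * ksize + 1L):(c * ksize), drop = FALSE]
          for (k in seq_len(ksize)) {
            seg <- matrix(block[, k], b, out_len)
            dX[, c, k:(k + out_len - 1L)] <- dX[, c, k:(k + out_len - 1L)] + seg
          }
        }
        dA <- dX
      } else {
        dA <- NULL
      }
    }
  }
  grads
}

# Sum of squares of every parameter (weights and biases).
param_sumsq <- function(net) {
  s <- 0
  for (l in net$layers) {
    if (!is.null(l$W)) s <- s + sum(l$W^2) + sum(l$b^2)
  }
  s
}

#' Penalized binary cross-entropy loss
#'
#' Mean binary cross-entropy of predicted probabilities plus an L2 penalty
#' `l2 * sum(parameter^2)` over every weight and bias of the network.
#'
#' @param prob Predicted probabilities in (0, 1).
#' @param y Binary 0/1 labels.
#' @param net Optional network whose parameters enter the penalty.
#' @param l2 Penalty factor (the pipeline default is 0.001).
#' @return A single number.
#' @export
bce_loss <- function(prob, y, net = NULL, l2 = 0) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  if (!is.null(net) && l2 > 0) loss <- loss + l2 * param_sumsq(net)
  loss
}

#' Training configuration for every network in the pipeline
#'
#' Adam with binary cross-entropy and L2 penalty 0.001; the learning rate is
#' multiplied by `plateau_factor` after `plateau_patience` epochs without a
#' validation-accuracy improvement, and training stops early after
#' `early_stop_patience` stagnant epochs. The parameters of the best
#' validation-accuracy epoch are returned.
#'
#' @param lr Initial learning rate. The diagnostic head uses 1e-4 and all
#'   other networks 1e-3 by convention; see [train_head()], [train_extractor()].
#' @param l2 L2 penalty factor on all parameters.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap behind early stopping.
#' @param early_stop_patience Stagnant epochs before stopping.
#' @param plateau_patience Stagnant epochs before a learning-rate decay.
#' @param plateau_factor Multiplicative decay (0.1).
#' @param seed Integer seed controlling initialization and batch order.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.001, l2 = 0.001, batch_size = 64,
                         max_epochs = 200, early_stop_patience = 15,
                         plateau_patience = 5, plateau_factor = 0.1,
                         seed = 1) {
  check_scalar_number(lr, "lr", .Machine$double.xmin)
  check_scalar_number(l2, "l2", 0)
  check_scalar_number(batch_size, "batch_size", 1)
  check_scalar_number(max_epochs, "max_epochs", 1)
  check_scalar_number(early_stop_patience, "early_stop_patience", 1)
  check_scalar_number(plateau_patience, "plateau_patience", 1)
  check_scalar_number(plateau_factor, "plateau_factor", 1e-8, 1)
  structure(list(lr = lr, l2 = l2, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor, seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(net) {
  lapply(net$layers, function(l) {
    if (is.null(l$W)) NULL
    else list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(net, grads, state, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mhatW <- s$mW / (1 - beta1^t); vhatW <- s$vW / (1 - beta2^t)
    mhatb <- s$mb / (1 - beta1^t); vhatb <- s$vb / (1 - beta2^t)
    net$layers[[i]]$W <- net$layers[[i]]$W - lr * mhatW / (sqrt(vhatW) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b - lr * mhatb / (sqrt(vhatb) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}

# Subset a batch from X preserving its layout.
slice_batch <- function(X, idx) {
  if (is.matrix(X)) X[idx, , drop = FALSE] else X[idx, , , drop = FALSE]
}

#' Train a network with Adam, plateau decay and early stopping
#'
#' Core trainer behind [train_extractor()], [train_head()] and the FW-RFE
#' inner re-fits. The final layer must be a single sigmoid unit; the loss is
#' binary cross-entropy plus `l2 * sum(parameter^2)`.
#'
#' @param layers Layer list (see [layers]).
#' @param input_shape `c(channels, length)` for convolutional input, or a
#'   single integer feature count for flat input.
#' @param x_train,y_train Training inputs (array/matrix) and binary labels.
#' @param x_val,y_val Optional validation data; when omitted, training runs
#'   for `max_epochs` epochs with no early stopping and the final parameters
#'   are returned.
#' @param config A [train_config()].
#' @return An object of class `fwrfe_trained`: the best-validation network,
#'   a per-epoch `log` tibble (epoch, train_loss, val_accuracy, lr), the best
#'   validation accuracy, and the number of epochs run.
#' @export
train_network <- function(layers, input_shape, x_train, y_train,
                          x_val = NULL, y_val = NULL,
                          config = train_config()) {
  y_train <- check_binary(y_train, "y_train")
  has_val <- !is.null(x_val)
  if (has_val) y_val <- check_binary(y_val, "y_val")
  n <- if (is.matrix(x_train)) nrow(x_train) else dim(x_train)[1]
  if (n < 1L) stop("training split is empty.", call. = FALSE)

  with_seed(config$seed, {
    net <- init_network(layers, input_shape)
    state <- adam_init(net)
    lr <- config$lr
    t_adam <- 0L
    best_acc <- -Inf
    best_net <- net
    since_improve <- 0L
    since_plateau <- 0L
    log_rows <- list()

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq.int(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- slice_batch(x_train, idx)
        yb <- y_train[idx]
        fw <- net_forward(net, Xb, cache = TRUE)
        p <- as.vector(fw$out)
        loss <- bce_loss(p, yb, net, config$l2)
        if (!is.finite(loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d.", epoch),
               call. = FALSE)
        }
        losses <- c(losses, loss)
        dz <- matrix((p - yb) / length(yb), ncol = 1L)
        grads <- net_backward(net, fw$caches, dz, final_is_dz = TRUE)
        if (config$l2 > 0) {
          for (i in seq_along(grads)) {
            if (is.null(grads[[i]])) next
            grads[[i]]$W <- grads[[i]]$W + 2 * config$l2 * net$layers[[i]]$W
            grads[[i]]$b <- grads[[i]]$b + 2 * config$l2 * net$layers[[i]]$b
          }
        }
        t_adam <- t_adam + 1L
        upd <- adam_step(net, grads, state, t_adam, lr)
        net <- upd$net
        state <- upd$state
      }

      val_acc <- NA_real_
      if (has_val) {
        pv <- as.vector(net_forward(net, x_val))
        val_acc <- mean((pv >= 0.5) == (y_val == 1))
        if (val_acc > best_acc) {
          best_acc <- val_acc
          best_net <- net
          since_improve <- 0L
          since_plateau <- 0L
        } else {
          since_improve <- since_improve + 1L
          since_plateau <- since_plateau + 1L
        }
      }
      log_rows[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = mean(losses), val_accuracy = val_acc, lr = lr
      )
      if (has_val) {
        if (since_plateau >= config$plateau_patience) {
          lr <- lr * config$plateau_factor
          since_plateau <- 0L
        }
        if (since_improve >= config$early_stop_patience) break
      }
    }

    if (!has_val) {
      best_net <- net
      best_acc <- NA_real_
    }
    structure(list(net = best_net,
                   log = dplyr::bind_rows(log_rows),
                   best_val_accuracy = best_acc,
                   epochs_run = length(log_rows)),
              class = "fwrfe_trained")
  })
}

#' @export
print.fwrfe_trained <- function(x, ...) {
  cat(sprintf("<fwrfe_trained> %d epochs, best validation accuracy %s\n",
              x$epochs_run,
              ifelse(is.na(x$best_val_accuracy), "NA",
                     sprintf("%.3f", x$best_val_accuracy))))
  invisible(x)
}

# Forward a trained network; returns probabilities as a plain vector for a
# single-unit sigmoid output.
net_predict <- function(net, X) {
  as.vector(net_forward(net, X))
}
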