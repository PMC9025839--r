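test_that("conv1d_forward matches hand convolution and the brute-force oracle", {
  expect_equal(conv1d_forward(c(1, 2, 3), c(1, 1)), c(3, 5))

  # all-zero weights and bias give an all-zero pre-activation output
  x <- matrix(rnorm(3 * 20), 3, 20)
  w0 <- array(0, c(4, 3, 5))
  expect_true(all(conv1d_forward(x, w0) == 0))

  set.seed(42)
  for (i in 1:100) {
    ch <- sample(1:3, 1)
    len <- sample(5:12, 1)
    ksize <- sample(2:min(5, len), 1)
    k <- sample(1:4, 1)
    x <- matrix(rnorm(ch * len), ch, len)
    w <- array(rnorm(k * ch * ksize), c(k, ch, ksize))
    b <- rnorm(k)
    expect_equal(conv1d_forward(x, w, b), oracle_conv1d(x, w, b),
                 tolerance = 1e-12)
  }

  # random single-channel case from a vector, with activation
  set.seed(7)
  v <- rnorm(5)
  kk <- rnorm(2)
  expect_equal(conv1d_forward(v, kk, 0.5, activation = function(z) leaky_relu(z, 0.2)),
               leaky_relu(drop(oracle_conv1d(v, kk, 0.5)), 0.2))

  expect_error(conv1d_forward(c(1, 2), c(1, 1, 1)), "shorter than kernel")
})

test_that("max_pool matches naive sliding-window maxima", {
  expect_equal(max_pool(c(1, 3, 2, 5), 2), c(3, 5))
  expect_equal(max_pool(rep(3.5, 4), 2), c(3.5, 3.5))

  set.seed(43)
  for (i in 1:100) {
    ch <- sample(1:3, 1)
    len <- sample(4:15, 1)
    ps <- sample(2:min(4, len), 1)
    st <- sample(1:3, 1)
    x <- matrix(rnorm(ch * len), ch, len)
    expect_equal(max_pool(x, ps, st), oracle_max_pool(x, ps, st))
  }
  # explicit length-9, pool 3, stride 2 case
  set.seed(44)
  v <- rnorm(9)
  expect_equal(max_pool(v, 3, 2), drop(oracle_max_pool(v, 3, 2)))

  expect_error(max_pool(numeric(0), 2), "non-empty")
  # pooled values stay within the input range
  set.seed(45)
  v <- rnorm(20)
  p <- max_pool(v, 4, 3)
  expect_true(all(p <= max(v) & p >= min(v)))
})

test_that("penalized loss equals BCE plus 0.001 times the parameter sum of squares", {
  # frozen toy model: one dense layer, hand-set parameters
  net <- list(layers = list(list(type = "dense", units = 1L,
                                 activation = "sigmoid",
                                 W = matrix(c(0.5, -1.5), 2, 1), b = 0.25)),
              input_shape = 2L)
  x <- matrix(c(1, 2, -1, 0.5), 2, 2, byrow = TRUE)
  y <- c(1, 0)
  z <- as.vector(x %*% net$layers[[1]]$W + 0.25)
  p <- 1 / (1 + exp(-z))
  hand_bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  hand_pen <- 0.001 * (0.5^2 + (-1.5)^2 + 0.25^2)
  expect_equal(bce_loss(p, y, net, l2 = 0.001), hand_bce + hand_pen)
  expect_equal(bce_loss(p, y), hand_bce)
})

test_that("analytic shape arithmetic matches the committed architectures", {
  specs <- reduced_extractor_specs(input_length = 1000)
  expect_equal(specs$cnn_a$n_features, 104L)
  expect_equal(specs$cnn_b$n_features, 72L)
  expect_equal(specs$cnn_c$n_features, 216L)
  # and against an executed forward pass
  x <- array(rnorm(2 * 12 * 1000), c(2, 12, 1000))
  cfg <- train_config(max_epochs = 1, batch_size = 2, seed = 1)
  ex <- train_extractor(specs$cnn_a, x, c(0, 1), x, c(0, 1), cfg)
  expect_equal(ncol(extract_features(ex, x)), 104L)
})

test_that("plateau schedule decays the learning rate exactly and stops early", {
  # learning rate too small to change anything: validation accuracy is flat
  set.seed(1)
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c(0, 1), 10)
  cfg <- train_config(lr = 1e-9, max_epochs = 50, batch_size = 20,
                      plateau_patience = 5, early_stop_patience = 15, seed = 2)
  fit <- train_network(list(dense_layer(1, "sigmoid")), 2L, x, y, x, y, cfg)
  log <- fit$log
  # epoch 1 always improves on -Inf; decay triggers after epochs 6 and 11
  expect_equal(log$lr[6], 1e-9)
  expect_equal(log$lr[7], 1e-9 * 0.1)
  expect_equal(log$lr[12], 1e-9 * 0.1 * 0.1)
  # after two plateaus the rate is exactly 0.01x the initial rate
  expect_equal(log$lr[12] / log$lr[1], 0.01)
  # early stopping: no improvement after epoch 1, so training stops at 16
  expect_equal(fit$epochs_run, 16)
})

test_that("training stops within patience epochs of the last improvement", {
  set.seed(10)
  x <- matrix(rnorm(60 * 4), 60, 4)
  y <- rbinom(60, 1, 0.5) # pure noise labels
  cfg <- train_config(lr = 0.01, max_epochs = 100, batch_size = 30,
                      early_stop_patience = 15, seed = 3)
  fit <- train_network(list(dense_layer(1, "sigmoid")), 4L, x, y,
                       matrix(rnorm(20 * 4), 20, 4), rbinom(20, 1, 0.5), cfg)
  log <- fit$log
  running_best <- cummax(log$val_accuracy)
  last_improve <- max(which(log$val_accuracy == running_best &
                              !duplicated(running_best)))
  expect_lte(fit$epochs_run, last_improve + 15)
})

test_that("training is deterministic and divergence is reported with the epoch", {
  set.seed(20)
  x <- matrix(rnorm(30 * 3), 30, 3)
  y <- rbinom(30, 1, 0.5)
  cfg <- train_config(lr = 0.01, max_epochs = 5, batch_size = 10, seed = 7)
  f1 <- train_network(list(dense_layer(4, "relu"), dense_layer(1, "sigmoid")),
                      3L, x, y, x, y, cfg)
  f2 <- train_network(list(dense_layer(4, "relu"), dense_layer(1, "sigmoid")),
                      3L, x, y, x, y, cfg)
  expect_identical(f1$net$layers, f2$net$layers)
  expect_identical(f1$log, f2$log)

  xbad <- x; xbad[1, 1] <- NaN
  expect_error(
    train_network(list(dense_layer(1, "sigmoid")), 3L, xbad, y, x, y, cfg),
    "epoch")
})

test_that("gradients agree with numerical differentiation on a tiny CNN", {
  layers <- list(conv_layer(2, 3), pool_layer(2), flatten_layer(),
                 dense_layer(3, "relu"), dense_layer(1, "sigmoid"))
  set.seed(31)
  net <- withr::with_seed(31, fwrfe:::init_network(layers, c(2L, 8L)))
  # give the zero-initialized output unit nonzero weights so gradients
  # propagate into the stack
  net$layers[[5]]$W <- matrix(rnorm(3, sd = 0.5), 3, 1)
  X <- array(rnorm(3 * 2 * 8), c(3, 2, 8))
  y <- c(1, 0, 1)
  loss_at <- function(net) {
    p <- as.vector(fwrfe:::net_forward(net, X))
    fwrfe:::bce_loss(p, y)
  }
  fw <- fwrfe:::net_forward(net, X, cache = TRUE)
  p <- as.vector(fw$out)
  dz <- matrix((p - y) / length(y), ncol = 1)
  grads <- fwrfe:::net_backward(net, fw$caches, dz, final_is_dz = TRUE)
  eps <- 1e-6
  for (li in c(1, 4, 5)) {
    W <- net$layers[[li]]$W
    for (idx in sample(length(W), min(4, length(W)))) {
      nplus <- net; nplus$layers[[li]]$W[idx] <- W[idx] + eps
      nminus <- net; nminus$layers[[li]]$W[idx] <- W[idx] - eps
      num <- (loss_at(nplus) - loss_at(nminus)) / (2 * eps)
      expect_equal(grads[[li]]$W[idx], num, tolerance = 1e-4)
    }
  }
})
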