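# Independent brute-force oracles and fixture builders. These deliberately
# share no code with the package implementation: plain loops and lm/solve.

# position-by-position multi-channel valid convolution
oracle_conv1d <- function(x, weights, bias = 0) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (is.vector(weights)) weights <- array(weights, c(1, 1, length(weights)))
  if (is.matrix(weights)) weights <- array(weights, c(nrow(weights), 1, ncol(weights)))
  k <- dim(weights)[1]; ch <- dim(weights)[2]; ksize <- dim(weights)[3]
  bias <- rep_len(bias, k)
  out_len <- ncol(x) - ksize + 1
  out <- matrix(0, k, out_len)
  for (j in seq_len(k)) {
    for (p in seq_len(out_len)) {
      acc <- 0
      for (c in seq_len(ch)) {
        for (q in seq_len(ksize)) acc <- acc + weights[j, c, q] * x[c, p + q - 1]
      }
      out[j, p] <- acc + bias[j]
    }
  }
  out
}

# sliding-window max with a naive loop
oracle_max_pool <- function(x, pool_size, stride = pool_size) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  starts <- seq(1, ncol(x) - pool_size + 1, by = stride)
  out <- matrix(0, nrow(x), length(starts))
  for (r in seq_len(nrow(x))) {
    for (i in seq_along(starts)) {
      out[r, i] <- max(x[r, starts[i]:(starts[i] + pool_size - 1)])
    }
  }
  out
}

# naive counting loop for confusion counts
oracle_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# Independent ridge least-squares fit used to hand-simulate elimination:
# returns coefficients (no intercept removed) for features of `cols`.
oracle_ls_fit <- function(x, y, ridge = 1e-6) {
  X1 <- cbind(1, x)
  solve(crossprod(X1) + diag(ridge, ncol(X1)), crossprod(X1, y))
}

# Step-by-step hand simulation of weight-norm RFE under the ridge LS re-fit:
# rank by squared coefficient, drop the smallest (first index on ties),
# re-fit, record validation accuracy of the reduced set.
oracle_fw_rfe_ls <- function(x_train, y_train, x_val, y_val, ridge = 1e-6) {
  removed <- character(0)
  acc <- numeric(0)
  beta <- oracle_ls_fit(x_train, y_train, ridge)
  while (ncol(x_train) > 1) {
    scores <- as.vector(beta[-1])^2
    h <- which(scores == min(scores))[1]
    removed <- c(removed, colnames(x_train)[h])
    x_train <- x_train[, -h, drop = FALSE]
    x_val <- x_val[, -h, drop = FALSE]
    beta <- oracle_ls_fit(x_train, y_train, ridge)
    pred <- as.vector(cbind(1, x_val) %*% beta) >= 0.5
    acc <- c(acc, mean(pred == (y_val == 1)))
  }
  list(removed = removed, val_accuracy = acc)
}

# feature matrix with k informative columns (logistic signal) among m
make_planted_features <- function(n, m, k, beta = 2, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * m), n, m)
    colnames(x) <- sprintf("f%04d", seq_len(m))
    z <- x[, seq_len(k), drop = FALSE] %*% rep(beta, k)
    y <- as.integer(stats::runif(n) < stats::plogis(as.vector(z)))
    list(x = x, y = y, planted = colnames(x)[seq_len(k)])
  })
}

# small preprocessed synthetic dataset for training tests: band-passed and
# decimated to 100 Hz
make_small_dataset <- function(n = 60, effect = 0.6, noise = 0.05, seed = 3,
                               duration = 4) {
  cfg <- synthetic_ecg_config(n, duration = duration, abnormal_effect = effect,
                              noise_sd = noise, seed = seed)
  ds <- generate_ecg_dataset(cfg)
  ds <- bandpass_filter(ds)
  decimate_dataset(ds, 5)
}

# statement-level metadata table for cohort tests
make_metadata <- function(n_normal, n_abnormal, records_per_patient = 1,
                          likelihood = 100, seed = 1) {
  withr::with_seed(seed, {
    n <- n_normal + n_abnormal
    classes <- c(rep("NORM", n_normal),
                 sample(c("MI", "STTC", "CD", "HYP"), n_abnormal, replace = TRUE))
    n_pat <- ceiling(n / records_per_patient)
    tibble::tibble(
      record_id = sprintf("R%06d", seq_len(n)),
      patient_id = sprintf("P%05d", rep(seq_len(n_pat), each = records_per_patient)[seq_len(n)]),
      superclass = classes,
      likelihood = likelihood
    )
  })
}
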