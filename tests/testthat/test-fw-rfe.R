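test_that("ranking scores are sums of squared weights over hidden units", {
  expect_equal(unname(ranking_scores(matrix(c(3, 4), 1, 2))), 25)
  expect_equal(unname(ranking_scores(matrix(0, 1, 5))), 0)

  set.seed(50)
  for (i in 1:100) {
    W <- matrix(rnorm(5 * 10), 5, 10,
                dimnames = list(sprintf("f%d", 1:5), NULL))
    brute <- numeric(5)
    for (j in 1:5) for (n in 1:10) brute[j] <- brute[j] + W[j, n]^2
    expect_equal(unname(ranking_scores(W)), brute)
  }

  Wbad <- matrix(c(1, NA, 2, 3), 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_error(ranking_scores(Wbad), "non-finite weight in feature 'b'")
})

test_that("ranking is equivariant under hidden-unit and feature permutations", {
  set.seed(51)
  W <- matrix(rnorm(8 * 10), 8, 10, dimnames = list(sprintf("f%d", 1:8), NULL))
  sc <- ranking_scores(W)
  for (r in 1:20) {
    ph <- sample(10)
    expect_equal(ranking_scores(W[, ph]), sc)
    pf <- sample(8)
    expect_equal(ranking_scores(W[pf, ]), sc[pf])
  }
})

test_that("argmin_feature returns the first minimal score", {
  expect_equal(argmin_feature(c(0.5, 0.1, 0.9)), 2L)
  expect_equal(argmin_feature(c(0.2, 0.2)), 1L)
  set.seed(52)
  for (i in 1:100) {
    v <- sample(round(runif(sample(2:9, 1)), 3), replace = TRUE)
    naive <- which(v == min(v))[1]
    expect_equal(argmin_feature(v), naive)
  }
  expect_error(argmin_feature(numeric(0)), "empty")
})

test_that("a planted label column survives elimination of seeded noise", {
  withr::with_seed(60, {
    y <- rep(c(0, 1), each = 20)
    x <- cbind(f1 = y, f2 = rnorm(40), f3 = rnorm(40))
    yv <- rep(c(0, 1), each = 10)
    xv <- cbind(f1 = yv, f2 = rnorm(20), f3 = rnorm(20))
  })
  res <- run_fw_rfe(x, y, xv, yv, fit = fit_least_squares(), seed = 1)
  expect_setequal(res$trace$removed, c("f2", "f3"))
  expect_true("f1" %in% res$selection$features)
  expect_equal(res$selection$val_accuracy, 1.0)
})

test_that("the elimination trace equals a hand simulation on six features", {
  withr::with_seed(61, {
    n <- 80
    x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, sprintf("f%d", 1:6)))
    z <- 1.5 * x[, 1] - 1.0 * x[, 3] + 0.5 * x[, 5]
    y <- as.integer(z + rnorm(n, sd = 0.5) > 0)
    xv <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, sprintf("f%d", 1:6)))
    yv <- as.integer(1.5 * xv[, 1] - 1.0 * xv[, 3] + 0.5 * xv[, 5] > 0)
  })
  res <- run_fw_rfe(x, y, xv, yv, fit = fit_least_squares(), seed = 3)
  oracle <- oracle_fw_rfe_ls(x, y, xv, yv)
  expect_identical(res$trace$removed, oracle$removed)
  expect_equal(res$trace$val_accuracy, oracle$val_accuracy)
  expect_equal(res$trace$n_remaining, 5:1)
  expect_equal(res$trace$step, 1:5)
})

test_that("redundant duplicate features do not hurt the selected accuracy", {
  withr::with_seed(62, {
    y <- rbinom(60, 1, 0.5)
    inf <- y + rnorm(60, sd = 0.1)
    x <- cbind(f1 = inf, f2 = inf)
    yv <- rbinom(30, 1, 0.5)
    infv <- yv + rnorm(30, sd = 0.1)
    xv <- cbind(f1 = infv, f2 = infv)
  })
  res <- run_fw_rfe(x, y, xv, yv, fit = fit_least_squares(), seed = 4)
  both_acc <- mean((as.vector(cbind(1, xv) %*% oracle_ls_fit(x, y)) >= 0.5) == (yv == 1))
  expect_lte(length(res$selection$features), 2)
  expect_equal(res$selection$val_accuracy, both_acc)
})

test_that("elimination is deterministic for identical inputs and seed", {
  dat <- make_planted_features(120, 12, 3, seed = 8)
  xtr <- dat$x[1:80, ]; ytr <- dat$y[1:80]
  xv <- dat$x[81:120, ]; yv <- dat$y[81:120]
  a <- run_fw_rfe(xtr, ytr, xv, yv, fit = fit_sigmoid_head(epochs = 5), seed = 5)
  b <- run_fw_rfe(xtr, ytr, xv, yv, fit = fit_sigmoid_head(epochs = 5), seed = 5)
  expect_identical(a$trace, b$trace)
  expect_identical(a$selection, b$selection)
})

test_that("select_best picks maximal accuracy, ties resolved to fewer features", {
  fake <- function(acc) {
    tr <- tibble::tibble(step = seq_along(acc),
                         removed = sprintf("f%d", seq_along(acc)),
                         n_remaining = length(acc) + 1 - seq_along(acc),
                         val_accuracy = acc)
    structure(list(trace = tr, features = sprintf("f%d", 1:(length(acc) + 1)),
                   extractor = "toy", seed = 1L),
              class = "fw_rfe_result")
  }
  s1 <- select_best(fake(c(0.80, 0.90, 0.70)))
  expect_equal(s1$n_removed, 2)
  expect_setequal(s1$features, c("f3", "f4"))
  s2 <- select_best(fake(c(0.90, 0.90, 0.70)))
  expect_equal(s2$n_removed, 2)
  s3 <- select_best(fake(c(0.85, 0.85, 0.85)))
  expect_equal(s3$n_removed, 3)
  expect_equal(length(s3$features), 1)
})

test_that("concatenation preserves width, order and provenance", {
  sel <- function(name, feats) {
    structure(list(extractor = name, features = feats,
                   indices = seq_along(feats), val_accuracy = 0.9,
                   n_removed = 0L),
              class = "fw_rfe_selection")
  }
  mk <- function(n_col, n_row = 4) {
    m <- matrix(rnorm(n_row * n_col), n_row, n_col,
                dimnames = list(NULL, sprintf("f%04d", seq_len(n_col))))
    m
  }
  # the published retained sizes: 125 + 89 + 223 concatenate to width 437
  mats <- list(mk(200), mk(150), mk(300))
  sels <- list(sel("CNN-A", sprintf("f%04d", 1:125)),
               sel("CNN-B", sprintf("f%04d", 1:89)),
               sel("CNN-C", sprintf("f%04d", 1:223)))
  out <- concatenate_selected(sels, mats)
  expect_equal(ncol(out), 437)
  prov <- attr(out, "provenance")
  expect_equal(unique(prov$extractor), c("CNN-A", "CNN-B", "CNN-C"))
  # provenance round-trip: every column maps back to its source value
  for (i in c(1, 126, 437)) {
    src <- which(c("CNN-A", "CNN-B", "CNN-C") == prov$extractor[i])
    expect_equal(out[, i], mats[[src]][, prov$feature[i]])
  }

  sels_empty <- sels
  sels_empty[[2]]$features <- character(0)
  expect_error(concatenate_selected(sels_empty, mats), "at least one feature")
  mats_bad <- mats
  mats_bad[[3]] <- mk(300, n_row = 5)
  expect_error(concatenate_selected(sels, mats_bad), "row counts")
})
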