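#' Logistic (sigmoid) function
#'
#' `sigmoid(s) = 1 / (1 + exp(-s))`, the link used by every classification
#' head in the pipeline.
#'
#' @param x Numeric vector or matrix of linear scores.
#' @return Values in (0, 1), same shape as `x`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Probability that a randomly chosen positive scores higher than a randomly
#' chosen negative, with ties counted one half. Used to quantify how well a
#' scalar summary separates the two classes of a generated dataset.
#'
#' @param score Numeric vector of discriminant values.
#' @param label Binary vector (0/1) of the same length; 1 is the positive class.
#' @return A single number in \[0, 1\].
#' @export
rank_auc <- function(score, label) {
  stopifnot(length(score) == length(label))
  label <- as.integer(label)
  if (!all(label %in% c(0L, 1L))) {
    stop("`label` must be binary 0/1.", call. = FALSE)
  }
  n1 <- sum(label == 1L)
  n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present.", call. = FALSE)
  r <- rank(score)
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Deterministic per-unit substream seed, kept below 2^31 - 1 so it is a valid
# R integer seed. Derivation is part of the reproducibility contract: the same
# (seed, i, j) always maps to the same substream.
derive_seed <- function(seed, i, j = 0L) {
  s <- (abs(as.numeric(seed)) %% 1e5) * 20011 + as.numeric(i) * 1117 + as.numeric(j) * 131
  as.integer(s %% 2147483647) + 1L
}

# Run code under a temporary RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(field, "must be a single finite number")
  }
  if (x < lower || x > upper) {
    stop_config(field, sprintf("must be in [%s, %s]", lower, upper))
  }
  invisible(x)
}

check_binary <- function(y, what = "labels") {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop(sprintf("%s must be binary 0/1.", what), call. = FALSE)
  }
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
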