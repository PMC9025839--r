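# Zero-phase band-pass preprocessing. The filter family and corners are not
# fixed by the task; conventional ECG bounds (0.5-40 Hz, 3rd-order
# Butterworth) are the defaults and everything is configurable.

#' Band-pass filter specification
#'
#' @param low_cutoff Lower corner frequency, Hz.
#' @param high_cutoff Upper corner frequency, Hz; must be below the Nyquist
#'   frequency of the signal it is applied to.
#' @param order Filter order (of the underlying low/high prototypes).
#' @param design Filter family; only "butterworth" is implemented.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_cutoff = 0.5, high_cutoff = 40, order = 3,
                        design = "butterworth") {
  check_scalar_number(low_cutoff, "low_cutoff", .Machine$double.xmin)
  check_scalar_number(high_cutoff, "high_cutoff", .Machine$double.xmin)
  if (low_cutoff >= high_cutoff) {
    stop_config("low_cutoff", "must be below high_cutoff")
  }
  check_scalar_number(order, "order", 1)
  design <- match.arg(design, "butterworth")
  structure(list(low_cutoff = low_cutoff, high_cutoff = high_cutoff,
                 order = as.integer(order), design = design),
            class = "filter_spec")
}

#' Zero-phase band-pass filtering of ECG signals
#'
#' Each lead is filtered independently with a Butterworth band-pass applied
#' forward and backward (`signal::filtfilt`), so the output has zero phase
#' shift and the same length as the input.
#'
#' @param x A numeric vector (one lead), a leads x samples matrix, or an
#'   `ecg_dataset` (every record filtered).
#' @param spec A [filter_spec()].
#' @param sampling_rate Sampling frequency in Hz; taken from the dataset when
#'   `x` is an `ecg_dataset`.
#' @return The filtered object, same shape/class as the input.
#' @export
bandpass_filter <- function(x, spec = filter_spec(), sampling_rate = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  if (inherits(x, "ecg_dataset")) {
    fs <- x$sampling_rate
    flt <- make_bandpass(spec, fs)
    x$signals <- lapply(x$signals, filter_matrix, flt = flt)
    return(x)
  }
  if (is.null(sampling_rate)) {
    stop("`sampling_rate` is required for vector/matrix input.", call. = FALSE)
  }
  flt <- make_bandpass(spec, sampling_rate)
  if (is.matrix(x)) filter_matrix(x, flt) else filter_vector(x, flt)
}

make_bandpass <- function(spec, fs) {
  nyq <- fs / 2
  if (spec$high_cutoff >= nyq) {
    stop_config("high_cutoff",
                sprintf("(%g Hz) must be below the Nyquist frequency %g Hz",
                        spec$high_cutoff, nyq))
  }
  signal::butter(spec$order, c(spec$low_cutoff, spec$high_cutoff) / nyq,
                 type = "pass")
}

filter_vector <- function(v, flt) {
  if (any(!is.finite(v))) stop("signal contains non-finite values.", call. = FALSE)
  as.numeric(signal::filtfilt(flt, v))
}

filter_matrix <- function(m, flt) {
  out <- m
  for (i in seq_len(nrow(m))) out[i, ] <- filter_vector(m[i, ], flt)
  out
}

#' Decimate a dataset to a lower sampling rate
#'
#' Keeps every `factor`-th sample of every lead. Intended for use after
#' [bandpass_filter()]: with the default 40 Hz upper corner, decimating
#' 500 Hz signals by a factor of up to 6 is alias-free.
#'
#' @param dataset An `ecg_dataset`.
#' @param factor Positive integer decimation factor.
#' @return The dataset with `sampling_rate` divided by `factor`.
#' @export
decimate_dataset <- function(dataset, factor) {
  stopifnot(inherits(dataset, "ecg_dataset"))
  check_scalar_number(factor, "factor", 1)
  factor <- as.integer(factor)
  keep <- seq.int(1L, ncol(dataset$signals[[1]]), by = factor)
  dataset$signals <- lapply(dataset$signals, function(m) m[, keep, drop = FALSE])
  dataset$sampling_rate <- dataset$sampling_rate / factor
  dataset
}
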