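# Synthetic 12-lead ECG generator. Each record is a quasi-periodic sum of
# per-beat Gaussian components (P, Q, R, S, ST bump, T) placed at beat onsets
# drawn from a heart-rate range, mixed into 12 leads by fixed gains, with
# additive white noise and an optional sub-0.5 Hz baseline-wander sinusoid.
# The abnormal class widens the QRS complex by a factor (1 + abnormal_effect)
# and depresses the ST level proportionally to abnormal_effect. This gives a
# learnable, controllable binary separation; it makes no claim of
# physiological fidelity.

# Fixed per-lead mixing gains for the standard order
# I II III aVR aVL aVF V1..V6 (aVR inverted, as on real ECGs).
LEAD_NAMES <- c("I", "II", "III", "aVR", "aVL", "aVF",
                "V1", "V2", "V3", "V4", "V5", "V6")
LEAD_GAINS <- c(0.6, 1.0, 0.5, -0.8, 0.3, 0.7, -0.4, 0.9, 1.1, 1.0, 0.8, 0.7)

# Baseline beat morphology (amplitudes in mV, times in seconds relative to
# the R peak). The R width `qrs_sd` is drawn per record; Q and S widths and
# the S offset scale with it so the whole QRS complex widens together.
BEAT_TEMPLATE <- list(
  p  = list(amp = 0.12, mu = -0.17, sd = 0.022),
  q  = list(amp = -0.15, mu = -0.028, sd = 0.009),
  r  = list(amp = 1.00, mu = 0.000, sd = NA), # sd = qrs_sd per record
  s  = list(amp = -0.22, mu = 0.030, sd = 0.010),
  st = list(amp = NA, mu = 0.120, sd = 0.040), # amp = st_level per record
  t  = list(amp = 0.30, mu = 0.300, sd = 0.055)
)
QRS_SD_RANGE <- c(0.008, 0.012) # baseline R-wave Gaussian sd, seconds
ST_DEPRESSION_PER_EFFECT <- -0.10 # mV of ST shift per unit abnormal_effect

#' Configuration for the synthetic 12-lead ECG generator
#'
#' @param n_records Number of records to generate.
#' @param sampling_rate Sampling frequency in Hz (default 500).
#' @param duration Record length in seconds (default 10).
#' @param heart_rate_range Interval (bpm) the per-record heart rate is drawn
#'   from.
#' @param abnormal_fraction Proportion of label-1 (abnormal) records in
#'   \[0, 1\]; the label-1 count is `round(abnormal_fraction * n_records)`.
#' @param abnormal_effect Nonnegative scalar: abnormal records have their QRS
#'   width multiplied by `1 + abnormal_effect` and their ST level shifted by
#'   `-0.10 * abnormal_effect` mV. Zero makes the classes indistinguishable.
#' @param noise_sd Standard deviation of the additive white noise (mV). The
#'   baseline-wander amplitude is tied to it (`2 * noise_sd`).
#' @param baseline_wander Add a random sub-0.5 Hz sinusoid per lead, so a
#'   band-pass filter has something to remove.
#' @param seed Integer seed; per-record substreams are derived from
#'   `(seed, record index)` so output is reproducible bit for bit.
#' @return A validated `synthetic_ecg_config` list.
#' @export
synthetic_ecg_config <- function(n_records, sampling_rate = 500, duration = 10,
                                 heart_rate_range = c(60, 100),
                                 abnormal_fraction = 0.5, abnormal_effect = 0.6,
                                 noise_sd = 0.05, baseline_wander = TRUE,
                                 seed = 1) {
  check_scalar_number(n_records, "n_records", 1)
  check_scalar_number(sampling_rate, "sampling_rate", 1)
  check_scalar_number(duration, "duration", .Machine$double.xmin)
  if (!is.numeric(heart_rate_range) || length(heart_rate_range) != 2L ||
      any(!is.finite(heart_rate_range)) || heart_rate_range[1] <= 0 ||
      heart_rate_range[1] > heart_rate_range[2]) {
    stop_config("heart_rate_range", "must be a positive, ordered bpm interval")
  }
  check_scalar_number(abnormal_fraction, "abnormal_fraction", 0, 1)
  check_scalar_number(abnormal_effect, "abnormal_effect", 0)
  check_scalar_number(noise_sd, "noise_sd", 0)
  if (!is.logical(baseline_wander) || length(baseline_wander) != 1L) {
    stop_config("baseline_wander", "must be TRUE or FALSE")
  }
  check_scalar_number(seed, "seed")
  structure(list(n_records = as.integer(n_records),
                 sampling_rate = sampling_rate, duration = duration,
                 heart_rate_range = heart_rate_range,
                 abnormal_fraction = abnormal_fraction,
                 abnormal_effect = abnormal_effect, noise_sd = noise_sd,
                 baseline_wander = baseline_wander, seed = as.integer(seed)),
            class = "synthetic_ecg_config")
}

# Add a Gaussian bump to `base` (length n at rate fs), evaluated only on a
# +-4 sd window for speed.
add_gauss <- function(base, fs, mu, sd, amp) {
  i1 <- max(1L, floor((mu - 4 * sd) * fs) + 1L)
  i2 <- min(length(base), ceiling((mu + 4 * sd) * fs) + 1L)
  if (i1 > i2) return(base)
  idx <- i1:i2
  tt <- (idx - 1) / fs
  base[idx] <- base[idx] + amp * exp(-0.5 * ((tt - mu) / sd)^2)
  base
}

# One 12 x n signal for given per-record parameters. Consumes the current RNG
# stream (beat jitter, noise, wander).
synth_signal <- function(fs, n, heart_rate, qrs_sd, st_level, noise_sd,
                         baseline_wander) {
  duration <- n / fs
  rr <- 60 / heart_rate
  onset <- stats::runif(1, 0.1, 0.1 + rr)
  beats <- seq(onset, duration + 0.4, by = rr)
  beats <- beats + stats::rnorm(length(beats), sd = 0.01 * rr)
  width_factor <- qrs_sd / mean(QRS_SD_RANGE)

  base <- numeric(n)
  for (bt in beats) {
    tpl <- BEAT_TEMPLATE
    base <- add_gauss(base, fs, bt + tpl$p$mu, tpl$p$sd, tpl$p$amp)
    base <- add_gauss(base, fs, bt + tpl$q$mu * width_factor,
                      tpl$q$sd * width_factor, tpl$q$amp)
    base <- add_gauss(base, fs, bt, qrs_sd, tpl$r$amp)
    base <- add_gauss(base, fs, bt + tpl$s$mu * width_factor,
                      tpl$s$sd * width_factor, tpl$s$amp)
    if (st_level != 0) {
      base <- add_gauss(base, fs, bt + tpl$st$mu, tpl$st$sd, st_level)
    }
    base <- add_gauss(base, fs, bt + tpl$t$mu, tpl$t$sd, tpl$t$amp)
  }

  sig <- matrix(0, nrow = 12L, ncol = n,
                dimnames = list(LEAD_NAMES, NULL))
  tvec <- (seq_len(n) - 1) / fs
  for (l in seq_len(12L)) {
    lead <- LEAD_GAINS[l] * base
    if (baseline_wander && noise_sd > 0) {
      freq <- stats::runif(1, 0.15, 0.45)
      phase <- stats::runif(1, 0, 2 * pi)
      lead <- lead + 2 * noise_sd * sin(2 * pi * freq * tvec + phase)
    }
    if (noise_sd > 0) lead <- lead + stats::rnorm(n, sd = noise_sd)
    sig[l, ] <- lead
  }
  sig
}

# Draw per-record morphology parameters from the record's substream.
draw_record_params <- function(config, label) {
  heart_rate <- stats::runif(1, config$heart_rate_range[1], config$heart_rate_range[2])
  qrs_sd <- stats::runif(1, QRS_SD_RANGE[1], QRS_SD_RANGE[2])
  st_level <- 0
  if (label == 1L) {
    qrs_sd <- qrs_sd * (1 + config$abnormal_effect)
    st_level <- ST_DEPRESSION_PER_EFFECT * config$abnormal_effect
  }
  list(heart_rate = heart_rate, qrs_sd = qrs_sd, st_level = st_level)
}

new_ecg_dataset <- function(signals, records, sampling_rate, duration) {
  structure(list(signals = signals, records = records,
                 sampling_rate = sampling_rate, duration = duration),
            class = "ecg_dataset")
}

#' Generate a labeled synthetic 12-lead ECG dataset
#'
#' Emits exactly `n_records` records of 12 leads x
#' `sampling_rate * duration` samples with binary labels (0 = normal,
#' 1 = abnormal). The label-1 count is `round(abnormal_fraction * n_records)`.
#' Identical `config` (including `seed`) reproduces identical signals bit for
#' bit; with `abnormal_effect = 0` the two classes are draw-for-draw identical
#' in distribution.
#'
#' @param config A [synthetic_ecg_config()].
#' @return An `ecg_dataset`: `signals` (list of 12 x n matrices, one per
#'   record), a `records` tibble (record_id, patient_id, label, plus the
#'   ground-truth morphology parameters heart_rate, qrs_width, st_level), and
#'   the sampling rate/duration.
#' @export
generate_ecg_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_ecg_config"))
  n <- config$n_records
  n_samples <- round(config$sampling_rate * config$duration)
  n_abnormal <- round(config$abnormal_fraction * n)
  labels <- integer(n)
  if (n_abnormal > 0) {
    pos <- with_seed(derive_seed(config$seed, 0L), sample.int(n, n_abnormal))
    labels[pos] <- 1L
  }
  signals <- vector("list", n)
  params <- vector("list", n)
  for (i in seq_len(n)) {
    res <- with_seed(derive_seed(config$seed, i), {
      pr <- draw_record_params(config, labels[i])
      sig <- synth_signal(config$sampling_rate, n_samples,
                          pr$heart_rate, pr$qrs_sd, pr$st_level,
                          config$noise_sd, config$baseline_wander)
      list(pr = pr, sig = sig)
    })
    params[[i]] <- res$pr
    signals[[i]] <- res$sig
  }
  records <- tibble::tibble(
    record_id = sprintf("S%05d", seq_len(n)),
    patient_id = sprintf("P%05d", seq_len(n)),
    label = labels,
    heart_rate = vapply(params, `[[`, numeric(1), "heart_rate"),
    qrs_width = vapply(params, `[[`, numeric(1), "qrs_sd"),
    st_level = vapply(params, `[[`, numeric(1), "st_level")
  )
  names(signals) <- records$record_id
  new_ecg_dataset(signals, records, config$sampling_rate, config$duration)
}

#' Generate a patient pool with repeated records per patient
#'
#' Emits `n_records / records_per_patient` patients, each holding
#' `records_per_patient` records that share the patient's identifier, label
#' and morphology parameters but have independent noise and beat jitter.
#' Useful for exercising patient-disjoint (one-record-per-patient) cohort
#' construction.
#'
#' @param config A [synthetic_ecg_config()]; `n_records` must be a multiple
#'   of `records_per_patient`.
#' @param records_per_patient Records per patient (>= 1).
#' @return An `ecg_dataset` (see [generate_ecg_dataset()]).
#' @export
generate_patient_pool <- function(config, records_per_patient) {
  stopifnot(inherits(config, "synthetic_ecg_config"))
  if (!is.numeric(records_per_patient) || length(records_per_patient) != 1L ||
      records_per_patient < 1) {
    stop_config("records_per_patient", "must be a positive integer")
  }
  records_per_patient <- as.integer(records_per_patient)
  if (config$n_records %% records_per_patient != 0L) {
    stop_config("n_records", "must be a multiple of records_per_patient")
  }
  n_patients <- config$n_records %/% records_per_patient
  n_samples <- round(config$sampling_rate * config$duration)
  n_abnormal <- round(config$abnormal_fraction * n_patients)
  labels <- integer(n_patients)
  if (n_abnormal > 0) {
    pos <- with_seed(derive_seed(config$seed, 0L), sample.int(n_patients, n_abnormal))
    labels[pos] <- 1L
  }
  signals <- list()
  rows <- list()
  k <- 0L
  for (p in seq_len(n_patients)) {
    pr <- with_seed(derive_seed(config$seed, p), draw_record_params(config, labels[p]))
    for (r in seq_len(records_per_patient)) {
      k <- k + 1L
      sig <- with_seed(derive_seed(config$seed, p, r), {
        synth_signal(config$sampling_rate, n_samples, pr$heart_rate, pr$qrs_sd,
                     pr$st_level, config$noise_sd, config$baseline_wander)
      })
      signals[[k]] <- sig
      rows[[k]] <- tibble::tibble(
        record_id = sprintf("S%05d", k),
        patient_id = sprintf("P%05d", p),
        label = labels[p],
        heart_rate = pr$heart_rate, qrs_width = pr$qrs_sd, st_level = pr$st_level
      )
    }
  }
  records <- dplyr::bind_rows(rows)
  names(signals) <- records$record_id
  new_ecg_dataset(signals, records, config$sampling_rate, config$duration)
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat(sprintf(
    "<ecg_dataset> %d records (%d abnormal), 12 leads x %d samples at %g Hz\n",
    nrow(x$records), sum(x$records$label), ncol(x$signals[[1]]), x$sampling_rate))
  invisible(x)
}

#' Stack dataset signals into a training array
#'
#' @param dataset An `ecg_dataset`.
#' @param record_ids Records to include, in order (default all).
#' @return An array of dim (records, 12, samples).
#' @export
as_input_array <- function(dataset, record_ids = dataset$records$record_id) {
  stopifnot(inherits(dataset, "ecg_dataset"))
  missing_ids <- setdiff(record_ids, names(dataset$signals))
  if (length(missing_ids) > 0) {
    stop(sprintf("unknown record ids: %s", paste(utils::head(missing_ids, 5), collapse = ", ")),
         call. = FALSE)
  }
  n <- length(record_ids)
  len <- ncol(dataset$signals[[record_ids[1]]])
  X <- array(0, dim = c(n, 12L, len))
  for (i in seq_len(n)) X[i, , ] <- dataset$signals[[record_ids[i]]]
  X
}

#' Stratified train/validation/test assignment for synthetic datasets
#'
#' Splits records by label into train/validation/test with the given
#' proportions (per class, largest-remainder rounding), then shuffles the
#' overall order. Real cohorts built from metadata use [build_cohort()]
#' instead.
#'
#' @param records A tibble with `record_id` and `label` columns.
#' @param prop Named proportions for train/validation/test, summing to 1.
#' @param seed Integer seed.
#' @return `records` with a `split` column, rows shuffled.
#' @export
stratified_split <- function(records,
                             prop = c(train = 0.6, validation = 0.2, test = 0.2),
                             seed = 1) {
  stopifnot(all(c("record_id", "label") %in% names(records)))
  if (abs(sum(prop) - 1) > 1e-8 ||
      !setequal(names(prop), c("train", "validation", "test"))) {
    stop_config("prop", "must be named train/validation/test proportions summing to 1")
  }
  with_seed(seed, {
    parts <- lapply(split(records, records$label), function(df) {
      n <- nrow(df)
      counts <- floor(prop * n)
      rem <- n - sum(counts)
      if (rem > 0) {
        extra <- order(prop * n - counts, decreasing = TRUE)[seq_len(rem)]
        counts[extra] <- counts[extra] + 1
      }
      df <- df[sample.int(n), , drop = FALSE]
      df$split <- rep(c("train", "validation", "test"),
                      times = counts[c("train", "validation", "test")])
      df
    })
    out <- dplyr::bind_rows(parts)
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}
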