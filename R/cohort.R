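# Cohort construction mirroring the two study designs used with PTB-XL:
# DA keeps every record whose diagnostic statement is clinician-confirmed at
# 100% likelihood (several records per patient allowed); DB additionally
# keeps only one record per patient, so the train/validation/test splits are
# patient-disjoint by construction.

ABNORMAL_SUPERCLASSES <- c("MI", "STTC", "CD", "HYP")
NORMAL_SUPERCLASSES <- c("NORM", "NORMAL")

#' Cohort specification (DA / DB paradigms)
#'
#' `split_counts` gives per-class record counts for train/validation/test;
#' each class's pool is subsampled (with `seed`) to the sum of its counts
#' before splitting. `cohort_spec_da()` and `cohort_spec_db()` are the
#' published designs: DA trains on 5198+5198 records, validates on 577+577
#' and tests on 1150 abnormal + 1410 normal (pools 6925/7185); DB uses
#' 5031/559/1000 per class (pools 6590/6590) with one record per patient.
#'
#' @param paradigm "DA" (all confirmed records) or "DB" (one record per
#'   patient).
#' @param split_counts Named list with `abnormal` and `normal`, each a
#'   3-vector of train/validation/test counts.
#' @param confidence_threshold Minimum statement likelihood admitted
#'   (fixed at 100 in the study designs).
#' @param seed Integer seed for subsampling and shuffling.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(paradigm = c("DA", "DB"),
                        split_counts = list(abnormal = c(5198, 577, 1150),
                                            normal = c(5198, 577, 1410)),
                        confidence_threshold = 100, seed = 1) {
  paradigm <- match.arg(paradigm)
  for (cls in c("abnormal", "normal")) {
    v <- split_counts[[cls]]
    if (is.null(v) || length(v) != 3L || any(v < 0) || any(v != round(v))) {
      stop_config("split_counts", sprintf("$%s must be 3 nonnegative counts", cls))
    }
  }
  check_scalar_number(confidence_threshold, "confidence_threshold", 0, 100)
  structure(list(paradigm = paradigm,
                 split_counts = lapply(split_counts[c("abnormal", "normal")],
                                       as.integer),
                 confidence_threshold = confidence_threshold,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
cohort_spec_da <- function(seed = 1) {
  cohort_spec("DA",
              split_counts = list(abnormal = c(5198, 577, 1150),
                                  normal = c(5198, 577, 1410)),
              seed = seed)
}

#' @rdname cohort_spec
#' @export
cohort_spec_db <- function(seed = 1) {
  cohort_spec("DB",
              split_counts = list(abnormal = c(5031, 559, 1000),
                                  normal = c(5031, 559, 1000)),
              seed = seed)
}

#' Collapse statement-level metadata to binary per-record labels
#'
#' Keeps only statements with likelihood at or above the threshold, then
#' labels a record normal (0) when all of its admitted statements are in the
#' Normal superclass and abnormal (1) when all are in MI/STTC/CD/HYP.
#' Records carrying both normal and abnormal admitted statements, or no
#' admitted statement at all, are excluded.
#'
#' @param metadata Tibble with columns `record_id`, `patient_id`,
#'   `superclass`, `likelihood`.
#' @param confidence_threshold Minimum admitted likelihood (default 100).
#' @return Tibble with one row per retained record: `record_id`,
#'   `patient_id`, `label`.
#' @export
label_records <- function(metadata, confidence_threshold = 100) {
  need <- c("record_id", "patient_id", "superclass", "likelihood")
  if (!all(need %in% names(metadata))) {
    stop(sprintf("metadata must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  known <- c(NORMAL_SUPERCLASSES, ABNORMAL_SUPERCLASSES)
  bad <- setdiff(unique(toupper(metadata$superclass)), known)
  if (length(bad) > 0) {
    stop(sprintf("unknown diagnostic superclass: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  metadata |>
    dplyr::filter(.data$likelihood >= confidence_threshold) |>
    dplyr::mutate(abn = toupper(.data$superclass) %in% ABNORMAL_SUPERCLASSES) |>
    dplyr::group_by(.data$record_id, .data$patient_id) |>
    dplyr::summarise(any_abn = any(.data$abn), any_norm = any(!.data$abn),
                     .groups = "drop") |>
    dplyr::filter(xor(.data$any_abn, .data$any_norm)) |>
    dplyr::transmute(.data$record_id, .data$patient_id,
                     label = as.integer(.data$any_abn))
}

#' Build a train/validation/test cohort from record metadata
#'
#' Implements the DA/DB designs: admit only clinician-confirmed records,
#' optionally reduce to one record per patient (DB), subsample each class's
#' pool to the specified total, assign the per-class split counts, and
#' shuffle the assembled table. All randomness is driven by `spec$seed`, so
#' the same metadata and spec always give the same membership.
#'
#' @param metadata Either statement-level metadata (see [label_records()]) or
#'   a per-record tibble with `record_id`, `patient_id`, `label` (0/1).
#' @param spec A [cohort_spec()].
#' @return A `dataset_split` tibble (`record_id`, `patient_id`, `label`,
#'   `split`) with the paradigm and seed as attributes.
#' @export
build_cohort <- function(metadata, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if ("superclass" %in% names(metadata)) {
    metadata <- label_records(metadata, spec$confidence_threshold)
  }
  need <- c("record_id", "patient_id", "label")
  if (!all(need %in% names(metadata))) {
    stop(sprintf("metadata must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  metadata$label <- as.integer(check_binary(metadata$label, "metadata$label"))
  if (anyDuplicated(metadata$record_id)) {
    stop("metadata must have one row per record.", call. = FALSE)
  }

  with_seed(spec$seed, {
    if (spec$paradigm == "DB") {
      # one record per patient, chosen at random within each patient
      metadata <- metadata |>
        dplyr::slice(sample.int(dplyr::n())) |>
        dplyr::distinct(.data$patient_id, .keep_all = TRUE)
    }
    pools <- split(metadata, ifelse(metadata$label == 1L, "abnormal", "normal"))
    shortfall <- character(0)
    for (cls in c("abnormal", "normal")) {
      need_n <- sum(spec$split_counts[[cls]])
      have_n <- if (is.null(pools[[cls]])) 0L else nrow(pools[[cls]])
      if (have_n < need_n) {
        shortfall <- c(shortfall,
                       sprintf("%s: need %d, have %d", cls, need_n, have_n))
      }
    }
    if (length(shortfall) > 0) {
      stop(sprintf("cohort pools too small (%s).", paste(shortfall, collapse = "; ")),
           call. = FALSE)
    }
    assigned <- lapply(c(abnormal = "abnormal", normal = "normal"), function(cls) {
      counts <- spec$split_counts[[cls]]
      pool <- pools[[cls]]
      take <- pool[sample.int(nrow(pool), sum(counts)), , drop = FALSE]
      take$split <- rep(c("train", "validation", "test"), times = counts)
      take
    })
    out <- dplyr::bind_rows(assigned)
    out <- out[sample.int(nrow(out)), c("record_id", "patient_id", "label", "split")]
    structure(tibble::as_tibble(out),
              class = c("dataset_split", class(tibble::tibble())),
              paradigm = spec$paradigm, seed = spec$seed)
  })
}

#' Summarize a cohort split
#'
#' @param split A `dataset_split` from [build_cohort()].
#' @return Tibble of record counts by split and label.
#' @export
split_counts <- function(split) {
  split |>
    dplyr::count(.data$split, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       names_prefix = "label_", values_fill = 0L)
}
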