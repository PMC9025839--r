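test_that("generator emits the configured shape and exact label balance", {
  cfg <- synthetic_ecg_config(10, abnormal_fraction = 0.5, seed = 1)
  ds <- generate_ecg_dataset(cfg)
  expect_equal(nrow(ds$records), 10)
  expect_equal(sum(ds$records$label), 5)
  expect_true(all(vapply(ds$signals, function(s) all(dim(s) == c(12, 5000)), logical(1))))
  expect_true(all(vapply(ds$signals, function(s) all(is.finite(s)), logical(1))))
  expect_true(all(ds$records$label %in% c(0L, 1L)))

  cfg37 <- synthetic_ecg_config(40, abnormal_fraction = 0.37, duration = 1, seed = 2)
  ds37 <- generate_ecg_dataset(cfg37)
  expect_equal(sum(ds37$records$label), round(0.37 * 40))
})

test_that("identical config and seed reproduce signals bit for bit", {
  cfg <- synthetic_ecg_config(6, duration = 2, seed = 11)
  a <- generate_ecg_dataset(cfg)
  b <- generate_ecg_dataset(cfg)
  expect_identical(a$signals, b$signals)
  expect_identical(a$records, b$records)
})

test_that("zero effect makes the label irrelevant to the waveform", {
  base <- synthetic_ecg_config(8, duration = 2, abnormal_effect = 0,
                               noise_sd = 0, seed = 5)
  allnorm <- synthetic_ecg_config(8, duration = 2, abnormal_effect = 0,
                                  noise_sd = 0, abnormal_fraction = 0, seed = 5)
  expect_identical(generate_ecg_dataset(base)$signals,
                   generate_ecg_dataset(allnorm)$signals)
})

test_that("ground-truth QRS width separates classes, monotonically in effect", {
  aucs <- vapply(c(0, 0.3, 0.6), function(ef) {
    cfg <- synthetic_ecg_config(400, duration = 1, abnormal_effect = ef,
                                noise_sd = 0.05, seed = 7)
    ds <- generate_ecg_dataset(cfg)
    rank_auc(ds$records$qrs_width, ds$records$label)
  }, numeric(1))
  expect_true(aucs[3] > 0.9)
  expect_true(all(diff(aucs) >= 0))
  expect_lt(abs(aucs[1] - 0.5), 0.1)
})

test_that("abnormal records have widened QRS by the documented factor", {
  cfg <- synthetic_ecg_config(200, duration = 1, abnormal_effect = 0.6, seed = 4)
  rec <- generate_ecg_dataset(cfg)$records
  expect_true(min(rec$qrs_width[rec$label == 1]) >
                max(rec$qrs_width[rec$label == 0]))
  expect_true(all(rec$st_level[rec$label == 1] < 0))
  expect_true(all(rec$st_level[rec$label == 0] == 0))
})

test_that("invalid generator configuration names the offending field", {
  expect_error(synthetic_ecg_config(10, abnormal_fraction = 1.5), "abnormal_fraction")
  expect_error(synthetic_ecg_config(10, noise_sd = -1), "noise_sd")
  expect_error(synthetic_ecg_config(0), "n_records")
  expect_error(synthetic_ecg_config(10, heart_rate_range = c(100, 60)),
               "heart_rate_range")
})

test_that("patient pools share parameters within patient and are reproducible", {
  cfg <- synthetic_ecg_config(12, duration = 1, seed = 9)
  pool <- generate_patient_pool(cfg, records_per_patient = 3)
  expect_equal(dplyr::n_distinct(pool$records$patient_id), 4)
  expect_true(all(table(pool$records$patient_id) == 3))
  per_pat <- dplyr::summarise(
    dplyr::group_by(pool$records, patient_id),
    hr = dplyr::n_distinct(heart_rate), lb = dplyr::n_distinct(label),
    .groups = "drop")
  expect_true(all(per_pat$hr == 1) && all(per_pat$lb == 1))

  single <- generate_patient_pool(cfg, records_per_patient = 1)
  expect_false(anyDuplicated(single$records$patient_id) > 0)

  again <- generate_patient_pool(cfg, records_per_patient = 3)
  expect_identical(pool$signals, again$signals)
  expect_identical(pool$records, again$records)

  expect_error(generate_patient_pool(cfg, 0), "records_per_patient")
})

test_that("stratified_split respects proportions per class and shuffles", {
  cfg <- synthetic_ecg_config(50, duration = 1, abnormal_fraction = 0.4, seed = 2)
  rec <- generate_ecg_dataset(cfg)$records
  out <- stratified_split(rec, seed = 3)
  expect_setequal(out$record_id, rec$record_id)
  tab <- table(out$split, out$label)
  expect_equal(sum(tab["train", ]), 30)
  expect_equal(sum(tab["validation", ]), 10)
  expect_equal(sum(tab["test", ]), 10)
  expect_identical(stratified_split(rec, seed = 3), out)
})
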