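test_that("WFDB export/load round-trips within quantization tolerance", {
  cfg <- synthetic_ecg_config(2, duration = 2, seed = 21)
  ds <- generate_ecg_dataset(cfg)
  dir <- withr::local_tempdir()
  export_wfdb_dataset(ds, dir)
  for (id in ds$records$record_id) {
    rec <- load_ptbxl_record(dir, id)
    expect_equal(rec$sampling_rate, 500)
    # ADC quantization at gain 1000 bounds the error by half a unit
    expect_lt(max(abs(rec$signal - ds$signals[[id]])), 5.1e-4)
    expect_equal(rec$lead_names,
                 c("I", "II", "III", "aVR", "aVL", "aVF",
                   "V1", "V2", "V3", "V4", "V5", "V6"))
  }
})

test_that("truncated waveforms and wrong sampling rates are format errors", {
  cfg <- synthetic_ecg_config(1, duration = 1, seed = 22)
  ds <- generate_ecg_dataset(cfg)
  dir <- withr::local_tempdir()
  id <- ds$records$record_id[1]
  write_wfdb(ds$signals[[id]], id, dir)

  dat <- file.path(dir, paste0(id, ".dat"))
  full <- readBin(dat, "raw", file.info(dat)$size)
  writeBin(full[seq_len(length(full) - 100)], dat)
  expect_error(load_ptbxl_record(dir, id), "truncated|expected")

  dir2 <- withr::local_tempdir()
  write_wfdb(ds$signals[[id]][, seq(1, 500, by = 5), drop = FALSE], id, dir2,
             sampling_rate = 100)
  expect_error(load_ptbxl_record(dir2, id), "500")

  expect_error(read_wfdb(dir2, "nonexistent"), "not found")
})

test_that("band-pass rejects DC and preserves in-band tones", {
  fs <- 500
  n <- 20 * fs
  # DC: residual after the edge transient is far below 1e-3 of the input
  y <- bandpass_filter(rep(1, n), filter_spec(), sampling_rate = fs)
  ctr <- (n %/% 2 - fs):(n %/% 2 + fs)
  expect_lt(max(abs(y[ctr])), 1e-3)

  # 10 Hz tone in the passband: amplitude preserved within 5%
  t <- (0:(n - 1)) / fs
  tone <- sin(2 * pi * 10 * t)
  yt <- bandpass_filter(tone, filter_spec(), sampling_rate = fs)
  expect_lt(abs(max(abs(yt[ctr])) - 1), 0.05)

  # output length always equals input length
  expect_length(yt, n)
})

test_that("filtering is linear and double filtering attenuates stopbands monotonely", {
  fs <- 500
  set.seed(30)
  x <- rnorm(4000)
  f1 <- bandpass_filter(x, filter_spec(), sampling_rate = fs)
  expect_lt(max(abs(bandpass_filter(3.7 * x, filter_spec(), sampling_rate = fs) -
                      3.7 * f1)), 1e-8)

  # stopband tone: each extra pass attenuates further
  t <- (0:9999) / fs
  tone60 <- sin(2 * pi * 60 * t)
  once <- bandpass_filter(tone60, filter_spec(), sampling_rate = fs)
  twice <- bandpass_filter(once, filter_spec(), sampling_rate = fs)
  ctr <- 4000:6000
  expect_lt(max(abs(once[ctr])), 1)
  expect_lt(max(abs(twice[ctr])), max(abs(once[ctr])))
})

test_that("filter specification is validated against the Nyquist limit", {
  expect_error(filter_spec(low_cutoff = 50, high_cutoff = 10), "low_cutoff")
  expect_error(bandpass_filter(rnorm(100), filter_spec(high_cutoff = 300),
                               sampling_rate = 500), "Nyquist")
})

test_that("statement-level metadata collapses to binary labels per the rules", {
  md <- tibble::tibble(
    record_id = c("r1", "r2", "r3", "r3", "r4", "r5", "r5"),
    patient_id = c("p1", "p2", "p3", "p3", "p4", "p5", "p5"),
    superclass = c("NORM", "MI", "STTC", "CD", "HYP", "NORM", "MI"),
    likelihood = c(100, 100, 100, 100, 80, 100, 100)
  )
  lab <- label_records(md)
  # r4: below confidence threshold -> dropped; r5: mixed normal/abnormal -> excluded
  expect_setequal(lab$record_id, c("r1", "r2", "r3"))
  expect_equal(lab$label[lab$record_id == "r1"], 0L)
  expect_equal(lab$label[lab$record_id == "r2"], 1L)
  expect_equal(lab$label[lab$record_id == "r3"], 1L)
  expect_error(label_records(dplyr::mutate(md, superclass = "XX")), "superclass")
})

test_that("cohort splits are exact, disjoint, deterministic, and report shortfalls", {
  md <- make_metadata(n_normal = 120, n_abnormal = 150, seed = 5)
  spec <- cohort_spec("DA",
                      split_counts = list(abnormal = c(70, 20, 10),
                                          normal = c(80, 20, 20)),
                      seed = 9)
  split <- build_cohort(md, spec)
  tab <- table(split$split, split$label)
  expect_equal(unname(tab["train", "1"]), 70)
  expect_equal(unname(tab["validation", "1"]), 20)
  expect_equal(unname(tab["test", "1"]), 10)
  expect_equal(unname(tab["train", "0"]), 80)
  expect_equal(unname(tab["test", "0"]), 20)
  expect_false(anyDuplicated(split$record_id) > 0)
  expect_identical(build_cohort(md, spec), split)

  spec_big <- cohort_spec("DA",
                          split_counts = list(abnormal = c(200, 20, 10),
                                              normal = c(80, 20, 20)))
  expect_error(build_cohort(md, spec_big), "abnormal: need 230, have 150")
})

test_that("DB paradigm is patient-disjoint even with adversarial metadata", {
  # patients hold several records, some spanning both label classes
  md <- make_metadata(n_normal = 150, n_abnormal = 150, seed = 6)
  md$patient_id <- sprintf("P%05d", rep(seq_len(60), length.out = nrow(md)))
  spec <- cohort_spec("DB",
                      split_counts = list(abnormal = c(15, 5, 5),
                                          normal = c(15, 5, 5)),
                      seed = 2)
  split <- build_cohort(md, spec)
  expect_false(anyDuplicated(split$patient_id) > 0)
  counts <- table(split$split)
  expect_equal(as.integer(counts[c("train", "validation", "test")]),
               c(30L, 10L, 10L))
})
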