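# Minimal reader/writer for the open WFDB waveform format, covering the
# subset the pipeline needs: one segment, signal format 16 (interleaved
# little-endian 16-bit integers), a plain-text .hea header. Enough to export
# synthetic records for interoperability and to load 500 Hz 12-lead records
# stored the same way.

#' Write a 12-lead record in WFDB format
#'
#' Emits `<record_id>.hea` (text header) and `<record_id>.dat` (format 16,
#' interleaved int16, little-endian) in `dir`. Amplitudes are quantized with
#' the given ADC gain, so a round-trip is exact to within `1/gain`.
#'
#' @param signal Leads x samples numeric matrix (millivolts).
#' @param record_id Record name (file stem).
#' @param dir Output directory (created if missing).
#' @param sampling_rate Sampling frequency written to the header.
#' @param gain ADC units per millivolt (default 1000).
#' @param lead_names Signal descriptions; defaults to the standard 12-lead
#'   names when the matrix has 12 rows.
#' @return Invisibly, the path of the header file.
#' @export
write_wfdb <- function(signal, record_id, dir, sampling_rate = 500,
                       gain = 1000, lead_names = NULL) {
  stopifnot(is.matrix(signal), is.numeric(signal))
  if (any(!is.finite(signal))) stop("signal contains non-finite values.", call. = FALSE)
  n_sig <- nrow(signal)
  n_samp <- ncol(signal)
  if (is.null(lead_names)) {
    lead_names <- if (n_sig == 12L) LEAD_NAMES else sprintf("CH%d", seq_len(n_sig))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  adc <- round(signal * gain)
  adc <- pmin(pmax(adc, -32768), 32767)
  first_sample <- as.integer(adc[, 1])
  header <- c(
    sprintf("%s %d %g %d", record_id, n_sig, sampling_rate, n_samp),
    sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s",
            record_id, gain, first_sample, lead_names)
  )
  writeLines(header, file.path(dir, paste0(record_id, ".hea")))
  con <- file(file.path(dir, paste0(record_id, ".dat")), "wb")
  on.exit(close(con))
  writeBin(as.integer(adc), con, size = 2L, endian = "little")
  invisible(file.path(dir, paste0(record_id, ".hea")))
}

#' Read a WFDB record (format 16)
#'
#' @param dir Directory holding `<record_id>.hea` and `<record_id>.dat`.
#' @param record_id Record name (file stem).
#' @return A list: `signal` (leads x samples matrix, millivolts),
#'   `sampling_rate`, `lead_names`, `record_id`.
#' @export
read_wfdb <- function(dir, record_id) {
  hea <- file.path(dir, paste0(record_id, ".hea"))
  if (!file.exists(hea)) {
    stop(sprintf("header file not found: %s", hea), call. = FALSE)
  }
  lines <- readLines(hea)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4L) stop("malformed WFDB header record line.", call. = FALSE)
  n_sig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  n_samp <- as.integer(top[4])
  if (length(lines) < 1L + n_sig) {
    stop("WFDB header lists fewer signal lines than signals.", call. = FALSE)
  }
  gains <- numeric(n_sig)
  lead_names <- character(n_sig)
  dat_file <- NULL
  for (i in seq_len(n_sig)) {
    f <- strsplit(trimws(lines[1L + i]), "\\s+")[[1]]
    if (length(f) < 3L) stop("malformed WFDB signal line.", call. = FALSE)
    if (f[2] != "16") {
      stop(sprintf("unsupported WFDB signal format '%s' (only 16).", f[2]),
           call. = FALSE)
    }
    dat_file <- dat_file %||% f[1]
    g <- sub("\\(.*$", "", sub("/.*$", "", f[3]))
    gains[i] <- as.numeric(g)
    if (gains[i] == 0 || is.na(gains[i])) gains[i] <- 200 # WFDB default gain
    lead_names[i] <- if (length(f) >= 9L) f[length(f)] else sprintf("CH%d", i)
  }
  dat <- file.path(dir, dat_file)
  if (!file.exists(dat)) stop(sprintf("waveform file not found: %s", dat), call. = FALSE)
  expected_bytes <- 2 * n_sig * n_samp
  if (file.info(dat)$size != expected_bytes) {
    stop(sprintf(
      "format error: %s holds %d bytes, expected %d (truncated or corrupt).",
      dat, file.info(dat)$size, expected_bytes), call. = FALSE)
  }
  con <- file(dat, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, integer(), n = n_sig * n_samp, size = 2L,
                      signed = TRUE, endian = "little")
  adc <- matrix(raw_vals, nrow = n_sig)
  signal <- adc / gains
  rownames(signal) <- lead_names
  list(signal = signal, sampling_rate = fs, lead_names = lead_names,
       record_id = record_id)
}

#' Load one 500 Hz 12-lead record from a WFDB directory
#'
#' Thin validation wrapper around [read_wfdb()] for PTB-XL-style storage:
#' checks the sampling rate and lead count and returns the record ready for
#' [bandpass_filter()].
#'
#' @param dir Directory holding the record files.
#' @param record_id Record name.
#' @param expected_rate Required sampling frequency (default 500 Hz).
#' @return A list with `signal` (12 x samples, millivolts, lead order as
#'   stored in the header), `sampling_rate`, `lead_names`, `record_id`.
#' @export
load_ptbxl_record <- function(dir, record_id, expected_rate = 500) {
  rec <- read_wfdb(dir, record_id)
  if (!isTRUE(all.equal(rec$sampling_rate, expected_rate))) {
    stop(sprintf(
      "format error: record '%s' is sampled at %g Hz, expected %g Hz.",
      record_id, rec$sampling_rate, expected_rate), call. = FALSE)
  }
  if (nrow(rec$signal) != 12L) {
    stop(sprintf("format error: record '%s' has %d signals, expected 12.",
                 record_id, nrow(rec$signal)), call. = FALSE)
  }
  rec
}

#' Export an `ecg_dataset` to WFDB files plus a metadata CSV
#'
#' @param dataset An `ecg_dataset`.
#' @param dir Output directory.
#' @return Invisibly, the metadata CSV path.
#' @export
export_wfdb_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ecg_dataset"))
  for (id in dataset$records$record_id) {
    write_wfdb(dataset$signals[[id]], id, dir,
               sampling_rate = dataset$sampling_rate)
  }
  meta_path <- file.path(dir, "records.csv")
  utils::write.csv(dataset$records, meta_path, row.names = FALSE)
  invisible(meta_path)
}
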