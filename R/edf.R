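# Minimal EDF (16-bit European Data Format) I/O. One data record per second;
# each channel is scaled linearly from its physical range onto the full
# 16-bit digital range, so the round-trip error is bounded by one quantum
# (physical range / 65535).

.edf_field <- function(x, width) {
  s <- substr(format(x, width = width), 1, width)
  formatC(s, width = width, flag = "-")
}

.edf_num <- function(x, width) {
  s <- formatC(signif(x, 7), format = "g", width = 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Writes standard 16-bit EDF with one data record per second. The sampling
#' rate must be a whole number of samples per second; trailing samples that
#' do not fill a complete record are dropped.
#'
#' @param rec An [eeg_recording()] (samples in microvolts).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (fs != round(fs)) abort("EDF export needs an integer sampling rate")
  ns <- nrow(rec$samples)
  n_rec <- floor(ncol(rec$samples) / fs)
  if (n_rec < 1) abort("recording shorter than one EDF data record (1 s)")

  phys_min <- apply(rec$samples, 1, min)
  phys_max <- apply(rec$samples, 1, max)
  flat <- phys_max - phys_min < 1e-9
  phys_max[flat] <- phys_min[flat] + 1 # avoid zero physical range
  # pad the range so ascii truncation of the limits can never clip the data
  pad <- (phys_max - phys_min) * 0.01
  phys_min <- phys_min - pad
  phys_max <- phys_max + pad
  dig_min <- -32768
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_field("0", 8),
    .edf_field(paste("subject", rec$subject_id), 80),
    .edf_field(paste("condition", rec$condition), 80),
    .edf_field("01.01.00", 8), .edf_field("00.00.00", 8),
    .edf_field(as.character(256 * (1 + ns)), 8),
    .edf_field("", 44),
    .edf_field(as.character(n_rec), 8),
    .edf_field("1", 8),
    .edf_field(as.character(ns), 4)
  )
  sig_hdr <- paste0(
    paste(vapply(rec$channel_labels, .edf_field, "", width = 16), collapse = ""),
    paste(rep(.edf_field("AgAgCl electrode", 80), ns), collapse = ""),
    paste(rep(.edf_field("uV", 8), ns), collapse = ""),
    paste(vapply(phys_min, .edf_num, "", width = 8), collapse = ""),
    paste(vapply(phys_max, .edf_num, "", width = 8), collapse = ""),
    paste(rep(.edf_field(as.character(dig_min), 8), ns), collapse = ""),
    paste(rep(.edf_field(as.character(dig_max), 8), ns), collapse = ""),
    paste(rep(.edf_field("", 80), ns), collapse = ""),
    paste(rep(.edf_field(as.character(fs), 8), ns), collapse = ""),
    paste(rep(.edf_field("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)

  # physical min written with limited ascii precision: reread the values we
  # actually wrote, so quantisation is consistent between writer and reader
  pm <- as.numeric(vapply(phys_min, .edf_num, "", width = 8))
  px <- as.numeric(vapply(phys_max, .edf_num, "", width = 8))
  gain <- (px - pm) / (dig_max - dig_min)

  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    block <- rec$samples[, cols, drop = FALSE]
    dig <- round((block - pm) / gain + dig_min)
    dig <- pmin(pmax(dig, dig_min), dig_max)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF file path.
#' @param subject_id,condition Metadata for the returned recording; defaults
#'   are recovered from the EDF header fields written by [write_edf()] when
#'   present.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, subject_id = NULL, condition = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8) # version
  patient <- trimws(rd(80))
  recinfo <- trimws(rd(80))
  rd(16) # date + time
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))

  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns) # transducer
  rd(8 * ns) # physical dimension
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) trimws(rd(8)), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) trimws(rd(8)), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) trimws(rd(8)), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) trimws(rd(8)), ""))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) trimws(rd(8)), ""))
  rd(32 * ns)

  if (length(unique(spr)) != 1) abort("mixed per-channel sampling rates unsupported")
  fs <- spr[1] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)

  x <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2, endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns) # samples x channels
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    x[, cols] <- t(sweep(sweep(block, 2, dig_min), 2, gain, "*") +
      matrix(phys_min, nrow = spr[1], ncol = ns, byrow = TRUE))
  }

  if (is.null(subject_id)) {
    subject_id <- if (startsWith(patient, "subject ")) {
      sub("^subject ", "", patient)
    } else {
      patient
    }
  }
  if (is.null(condition)) {
    condition <- if (grepl("EO", recinfo)) "EO" else "EC"
  }
  eeg_recording(x, fs, labels, subject_id = subject_id, condition = condition)
}
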