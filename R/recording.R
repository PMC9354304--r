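#' Construct an EEG recording object
#'
#' A lightweight container for one subject/condition block of multichannel
#' EEG: a channels-by-time matrix of samples in microvolts plus the metadata
#' the pipeline needs (sampling rate, 10-5 channel labels, condition,
#' referencing state).
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector, one unique label per row of `samples`.
#' @param subject_id Subject identifier.
#' @param condition `"EC"` (eyes closed) or `"EO"` (eyes open).
#' @param bad_channels Labels of channels flagged bad (subset of `channel_labels`).
#' @param reference `"raw"` or `"average"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate, channel_labels,
                          subject_id = "s01", condition = c("EC", "EO"),
                          bad_channels = character(), reference = "raw") {
  condition <- match.arg(condition)
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) abort("samples must be a numeric matrix")
  if (length(channel_labels) != nrow(samples)) {
    abort("channel_labels length must equal the number of sample rows")
  }
  if (anyDuplicated(channel_labels)) abort("channel labels must be unique")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    abort("sampling_rate must be positive")
  }
  if (!all(bad_channels %in% channel_labels)) {
    abort("bad_channels must be a subset of channel_labels")
  }
  rownames(samples) <- channel_labels
  structure(
    list(
      subject_id = subject_id,
      condition = condition,
      sampling_rate = sampling_rate,
      channel_labels = channel_labels,
      samples = samples,
      bad_channels = bad_channels,
      reference = reference
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s, %s | %d channels x %.1f s @ %g Hz | ref: %s\n",
    x$subject_id, x$condition, nrow(x$samples),
    ncol(x$samples) / x$sampling_rate, x$sampling_rate, x$reference
  ))
  if (length(x$bad_channels)) {
    cat("  bad channels:", paste(x$bad_channels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  ncol(rec$samples) / rec$sampling_rate
}

#' Drop channels from a recording
#'
#' Used e.g. to delete the recording reference channel (Fz in the default
#' pipeline configuration) before re-referencing.
#'
#' @param rec An `eeg_recording`.
#' @param labels Channels to remove; labels not present are ignored.
#' @export
drop_channels <- function(rec, labels) {
  stopifnot(inherits(rec, "eeg_recording"))
  keep <- !(toupper(rec$channel_labels) %in% toupper(labels))
  if (all(keep)) return(rec)
  if (!any(keep)) abort("cannot drop all channels")
  eeg_recording(
    rec$samples[keep, , drop = FALSE], rec$sampling_rate,
    rec$channel_labels[keep], rec$subject_id, rec$condition,
    intersect(rec$bad_channels, rec$channel_labels[keep]), rec$reference
  )
}
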