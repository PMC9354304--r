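#' Subtract the baseline (mean) from every channel
#'
#' @param rec An [eeg_recording()].
#' @return The recording with every channel mean-zero over the full record.
#' @export
subtract_baseline <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$samples) == 0) abort("empty recording")
  rec$samples <- rec$samples - rowMeans(rec$samples)
  rec
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the pipeline's phase-invariant band pass (default 0.3-54 Hz,
#' 2nd-order Butterworth) to every channel. The filter is realized as an
#' order-`order` high-pass at `low` cascaded with an order-`order` low-pass
#' at `high`, each run forward and backward (`filtfilt`), giving zero phase
#' and an effective roll-off of twice the design order. The channel mean is
#' removed before filtering; a 0.3 Hz high-pass suppresses it in any case and
#' removing it first avoids long edge transients.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz.
#' @param order Butterworth design order for each cascade section.
#' @return Filtered recording.
#' @export
bandpass_filter <- function(rec, low = 0.3, high = 54, order = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (high >= nyq) abort("high cutoff must be below the Nyquist frequency")
  if (low <= 0 || low >= high) abort("require 0 < low < high")
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  rec$samples <- t(apply(rec$samples, 1, function(ch) {
    ch <- ch - mean(ch)
    out <- signal::filtfilt(lp, signal::filtfilt(hp, ch))
    out - mean(out) # residual DC is numerical; the passband excludes it
  }))
  rownames(rec$samples) <- rec$channel_labels
  rec
}

# Legendre polynomials P_1..P_n evaluated at x (vector); rows = order
.legendre_upto <- function(n, x) {
  out <- matrix(0, nrow = n, ncol = length(x))
  p_prev <- rep(1, length(x)) # P_0
  p_cur <- x # P_1
  out[1, ] <- p_cur
  if (n > 1) {
    for (k in 1:(n - 1)) {
      p_next <- ((2 * k + 1) * x * p_cur - k * p_prev) / (k + 1)
      out[k + 1, ] <- p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  out
}

# spherical-spline kernel g(cos angle), Perrin-style, order m, n_terms terms
.spline_g <- function(cosang, m = 4, n_terms = 7) {
  cosang <- pmin(pmax(cosang, -1), 1)
  P <- .legendre_upto(n_terms, cosang)
  n <- seq_len(n_terms)
  coef <- (2 * n + 1) / (n * (n + 1))^m
  as.vector(crossprod(coef, P)) / (4 * pi)
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces each channel listed in `bad_channels` with a spherical-spline
#' estimate from the good channels (spline order `m`, truncated Legendre
#' series, ridge regularization on the fitting system). Good channels are
#' untouched and the bad-channel list is cleared.
#'
#' @param rec An [eeg_recording()] with `bad_channels` set.
#' @param montage Montage covering all channels of `rec`.
#' @param m Spline order.
#' @param n_terms Number of Legendre terms in the kernel series.
#' @param reg Regularization added to the fitting system diagonal.
#' @return Recording with bad channels reconstructed.
#' @export
interpolate_bad_channels <- function(rec, montage, m = 4, n_terms = 7,
                                     reg = 1e-5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(rec$bad_channels) == 0) return(rec)
  good <- setdiff(rec$channel_labels, rec$bad_channels)
  if (length(good) < 4) abort("need at least 4 good channels for spline interpolation")
  pos <- montage_positions(montage, rec$channel_labels)
  gi <- match(good, rec$channel_labels)
  bi <- match(rec$bad_channels, rec$channel_labels)

  cos_gg <- tcrossprod(pos[gi, , drop = FALSE])
  G <- matrix(.spline_g(cos_gg, m, n_terms), nrow = length(gi))
  A <- rbind(
    cbind(G + reg * diag(length(gi)), 1),
    c(rep(1, length(gi)), 0)
  )
  # solve for all time points at once: coefficients (n_good+1) x n_time,
  # last row is the constant term; final equation enforces sum(c) = 0
  coefs <- solve(A, rbind(rec$samples[gi, , drop = FALSE], 0))
  cos_bg <- pos[bi, , drop = FALSE] %*% t(pos[gi, , drop = FALSE])
  Gb <- matrix(.spline_g(cos_bg, m, n_terms), nrow = length(bi))
  est <- Gb %*% coefs[seq_along(gi), , drop = FALSE] +
    matrix(coefs[length(gi) + 1, ],
      nrow = length(bi), ncol = ncol(rec$samples), byrow = TRUE
    )
  rec$samples[bi, ] <- est
  rec$bad_channels <- character()
  rec
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the channel mean is zero at every time sample. Idempotent; preserves all
#' pairwise channel differences exactly.
#'
#' @param rec An [eeg_recording()] with at least 2 channels.
#' @return Average-referenced recording (`reference = "average"`).
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$samples) < 2) abort("average reference needs >= 2 channels")
  rec$samples <- sweep(rec$samples, 2, colMeans(rec$samples))
  rec$reference <- "average"
  rec
}

#' Segment a recording into overlapping analysis windows
#'
#' Cuts the recording into `window_s`-second windows advancing by `hop_s`
#' (defaults: 2-s windows with 1-s overlap, i.e. consecutive windows share
#' 50% of their samples). Windows that would run past the end of the
#' recording are dropped, so every window has exactly
#' `window_s * sampling_rate` samples.
#'
#' @param rec An [eeg_recording()] of duration >= `window_s`.
#' @param window_s,hop_s Window length and hop in seconds.
#' @return A `qeeg_segments` object: array `data` of dimension
#'   (samples, channels, windows) plus metadata.
#' @export
segment_windows <- function(rec, window_s = 2, hop_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  nsamp <- round(window_s * rec$sampling_rate)
  hop <- round(hop_s * rec$sampling_rate)
  n <- ncol(rec$samples)
  if (n < nsamp) abort("recording shorter than one analysis window")
  onsets <- seq(1, n - nsamp + 1, by = hop)
  dat <- array(0, dim = c(nsamp, nrow(rec$samples), length(onsets)))
  for (w in seq_along(onsets)) {
    dat[, , w] <- t(rec$samples[, onsets[w]:(onsets[w] + nsamp - 1), drop = FALSE])
  }
  structure(
    list(
      data = dat,
      sampling_rate = rec$sampling_rate,
      channel_labels = rec$channel_labels,
      window_s = window_s, hop_s = hop_s,
      onsets_s = (onsets - 1) / rec$sampling_rate,
      subject_id = rec$subject_id, condition = rec$condition
    ),
    class = "qeeg_segments"
  )
}

#' @export
print.qeeg_segments <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<qeeg_segments> %d windows of %g s (%d samples) x %d channels @ %g Hz\n",
    d[3], x$window_s, d[1], d[2], x$sampling_rate
  ))
  invisible(x)
}

#' Minimum-duration inclusion rule
#'
#' The inclusion criterion requires at least `minimum` seconds of usable
#' resting-state EEG. Under the default `"combined"` rule the EC and EO
#' durations are summed; under `"each"` both conditions must individually
#' reach the minimum.
#'
#' @param clean_duration_ec,clean_duration_eo Usable durations in seconds.
#' @param minimum Threshold in seconds.
#' @param rule `"combined"` (sum of conditions) or `"each"`.
#' @return Logical.
#' @export
passes_duration_rule <- function(clean_duration_ec, clean_duration_eo,
                                 minimum = 20, rule = c("combined", "each")) {
  rule <- match.arg(rule)
  if (clean_duration_ec < 0 || clean_duration_eo < 0) abort("durations must be >= 0")
  if (rule == "combined") {
    (clean_duration_ec + clean_duration_eo) >= minimum
  } else {
    clean_duration_ec >= minimum && clean_duration_eo >= minimum
  }
}

#' Standard preprocessing chain
#'
#' Baseline subtraction, zero-phase band-pass, optional reference-channel
#' deletion, bad-channel spherical-spline interpolation, and common-average
#' re-referencing, in that order.
#'
#' @param rec An [eeg_recording()].
#' @param montage Montage for interpolation.
#' @param low,high Band-pass edges, Hz.
#' @param drop_reference Label of a recording-reference channel to delete
#'   (default `"Fz"`; set `NULL` to keep all channels).
#' @return Preprocessed recording.
#' @export
preprocess_recording <- function(rec, montage, low = 0.3, high = 54,
                                 drop_reference = "Fz") {
  rec <- subtract_baseline(rec)
  rec <- bandpass_filter(rec, low = low, high = high)
  if (!is.null(drop_reference) &&
    any(toupper(drop_reference) %in% toupper(rec$channel_labels)) &&
    nrow(rec$samples) > length(drop_reference)) {
    rec <- drop_channels(rec, drop_reference)
  }
  if (length(rec$bad_channels)) {
    rec <- interpolate_bad_channels(rec, montage)
  }
  average_reference(rec)
}
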