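#' Canonical frequency band definitions
#'
#' The five analysis bands: delta 0.5-4, theta 4-5.5, high theta 5.5-8,
#' alpha 8-13 and beta 13-30 Hz. Band intervals are half-open `[low, high)`
#' except beta, which closes at 30 Hz so the five bands tile the 0.5-30 Hz
#' relative-power denominator exactly.
#'
#' @return Tibble with columns `name`, `low`, `high`.
#' @export
qeeg_bands <- function() {
  tibble::tibble(
    name = c("delta", "theta", "high_theta", "alpha", "beta"),
    low = c(0.5, 4, 5.5, 8, 13),
    high = c(4, 5.5, 8, 13, 30)
  )
}

#' Per-window power spectral densities (Welch scheme)
#'
#' Computes a Hamming-tapered periodogram for every 2-s analysis window,
#' zero-padded to `nfft` points and normalized as a one-sided power spectral
#' density in microvolts squared per Hz. At the nominal 1024 Hz sampling rate
#' with `nfft = 2^13` the frequency grid has 0.125 Hz spacing. Because the
#' segmentation already advances 2048-sample windows by 50%, the mean of
#' these per-window spectra is exactly a Welch estimate with Hamming taper
#' and 50% segment overlap ([welch_mean_spectrum()]).
#'
#' @param seg A `qeeg_segments` object from [segment_windows()].
#' @param nfft FFT length (default `2^13 = 8192`).
#' @return A `qeeg_spectra` object: `frequencies` (Hz) and `psd` array of
#'   dimension (frequency, channel, window).
#' @export
compute_spectra <- function(seg, nfft = 8192) {
  stopifnot(inherits(seg, "qeeg_segments"))
  d <- dim(seg$data)
  nsamp <- d[1]
  if (nsamp > nfft) abort("window longer than nfft")
  fs <- seg$sampling_rate
  w <- signal::hamming(nsamp)
  U <- sum(w^2)

  # taper all windows/channels at once, zero-pad, one multi-column FFT
  flat <- matrix(seg$data, nrow = nsamp) * w
  padded <- rbind(flat, matrix(0, nrow = nfft - nsamp, ncol = ncol(flat)))
  spec <- stats::mvfft(padded)
  n_keep <- nfft / 2 + 1
  p <- abs(spec[seq_len(n_keep), , drop = FALSE])^2 / (fs * U)
  p[2:(n_keep - 1), ] <- 2 * p[2:(n_keep - 1), ] # one-sided, keep DC/Nyquist
  psd <- array(p, dim = c(n_keep, d[2], d[3]))

  structure(
    list(
      frequencies = (seq_len(n_keep) - 1) * fs / nfft,
      psd = psd,
      channel_labels = seg$channel_labels,
      sampling_rate = fs, nfft = nfft, taper = "hamming",
      subject_id = seg$subject_id, condition = seg$condition
    ),
    class = "qeeg_spectra"
  )
}

#' @export
print.qeeg_spectra <- function(x, ...) {
  d <- dim(x$psd)
  cat(sprintf(
    "<qeeg_spectra> %d frequency bins (spacing %g Hz) x %d channels x %d windows\n",
    d[1], x$frequencies[2] - x$frequencies[1], d[2], d[3]
  ))
  invisible(x)
}

#' Welch mean spectrum across windows
#'
#' @param spectra A `qeeg_spectra` object.
#' @return Matrix frequency x channel of window-averaged PSD.
#' @export
welch_mean_spectrum <- function(spectra) {
  stopifnot(inherits(spectra, "qeeg_spectra"))
  m <- rowMeans(spectra$psd, dims = 2) # mean over windows
  colnames(m) <- spectra$channel_labels
  m
}

# frequency-bin mask for [low, high), optionally closing at high
.band_mask <- function(freqs, low, high, closed_high = FALSE) {
  if (closed_high) freqs >= low & freqs <= high else freqs >= low & freqs < high
}

#' Relative band power per channel
#'
#' Integrates the Welch mean spectrum over each band (rectangle rule on the
#' PSD grid) and divides by the integrated power over the full 0.5-30 Hz
#' analysis range, so the five canonical band fractions sum to 1 per channel.
#'
#' @param spectra A `qeeg_spectra` object.
#' @param bands Band table as from [qeeg_bands()].
#' @param total_range Denominator range in Hz.
#' @return Tibble: `channel`, one column per band, fractions in \[0, 1\].
#' @export
relative_band_power <- function(spectra, bands = qeeg_bands(),
                                total_range = c(0.5, 30)) {
  stopifnot(inherits(spectra, "qeeg_spectra"))
  if (any(bands$high <= bands$low)) abort("empty band definition")
  mean_spec <- welch_mean_spectrum(spectra)
  freqs <- spectra$frequencies
  total <- colSums(mean_spec[.band_mask(freqs, total_range[1], total_range[2],
    closed_high = TRUE
  ), , drop = FALSE])
  upper <- max(bands$high)
  fr <- purrr::map(seq_len(nrow(bands)), function(i) {
    mask <- .band_mask(freqs, bands$low[i], bands$high[i],
      closed_high = bands$high[i] >= upper
    )
    unname(colSums(mean_spec[mask, , drop = FALSE]) / total)
  })
  names(fr) <- bands$name
  tibble::as_tibble(c(list(channel = spectra$channel_labels), fr))
}

#' Dominant frequency and its variance per channel
#'
#' For every analysis window the dominant frequency is the frequency bin of
#' highest power within the search band (ties broken toward the lower bin).
#' DF is the mean of the per-window values and DFV their sample (n-1)
#' standard deviation; DFV is `NA` when fewer than two windows are present.
#'
#' @param spectra A `qeeg_spectra` object.
#' @param search_band Two-element numeric, Hz (default 4-15).
#' @return Tibble: `channel`, `DF`, `DFV` (both in Hz).
#' @export
dominant_frequency_stats <- function(spectra, search_band = c(4, 15)) {
  stopifnot(inherits(spectra, "qeeg_spectra"))
  freqs <- spectra$frequencies
  mask <- freqs >= search_band[1] & freqs <= search_band[2]
  band_freqs <- freqs[mask]
  d <- dim(spectra$psd)
  sub <- spectra$psd[mask, , , drop = FALSE]
  flat <- matrix(sub, nrow = sum(mask)) # (channel, window) in columns
  peak <- max.col(t(flat), ties.method = "first") # first max = lowest bin
  peak_f <- matrix(band_freqs[peak], nrow = d[2])
  tibble::tibble(
    channel = spectra$channel_labels,
    DF = rowMeans(peak_f),
    DFV = if (d[3] >= 2) apply(peak_f, 1, sd) else NA_real_
  )
}

#' Aggregate per-channel values over cortical regions
#'
#' Unweighted mean of channel values within each region (F/C/T/P/O) defined
#' by the montage.
#'
#' @param values Named numeric vector (names = channel labels) or a tibble
#'   with a `channel` column and numeric columns.
#' @param montage Montage covering all channels.
#' @return Tibble: `region` plus the aggregated numeric columns.
#' @export
region_aggregate <- function(values, montage) {
  if (is.numeric(values)) {
    values <- tibble::tibble(channel = names(values), value = unname(values))
  }
  regions <- montage_regions(montage, values$channel)
  present <- unique(regions)
  missing_regions <- setdiff(c("F", "C", "T", "P", "O"), present)
  if (length(missing_regions)) {
    abort(paste(
      "regions with zero channels:",
      paste(missing_regions, collapse = ", ")
    ))
  }
  values$region <- unname(regions)
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::select(values, -"channel"), .data$region),
    dplyr::across(dplyr::everything(), mean),
    .groups = "drop"
  )
  dplyr::arrange(out, match(.data$region, c("F", "C", "T", "P", "O")))
}

#' Theta-alpha ratio
#'
#' Ratio of a theta-range band's relative power to alpha relative power.
#' The default numerator is the high-theta band (5.5-8 Hz); `"theta"`
#' (4-5.5 Hz) and `"theta_broad"` (their sum, 4-8 Hz) are available.
#'
#' @param theta,high_theta,alpha Relative powers (vectors recycle).
#' @param numerator Which numerator convention to use.
#' @return Numeric ratio; errors if any alpha power is zero.
#' @export
theta_alpha_ratio <- function(theta, high_theta, alpha,
                              numerator = c("high_theta", "theta", "theta_broad")) {
  numerator <- match.arg(numerator)
  if (any(alpha <= 0)) abort("alpha relative power must be positive")
  num <- switch(numerator,
    high_theta = high_theta,
    theta = theta,
    theta_broad = theta + high_theta
  )
  num / alpha
}

#' Eyes-closed / eyes-open dominant-frequency-variance ratio
#'
#' The reactivity biomarker: DFV in the eyes-closed condition divided by DFV
#' in the eyes-open condition. Returns `NA` (flagged missing) when the EO
#' DFV is zero or missing.
#'
#' @param dfv_ec,dfv_eo DFV values in Hz.
#' @return Unitless ratio.
#' @export
dfv_ec_eo_ratio <- function(dfv_ec, dfv_eo) {
  out <- dfv_ec / dfv_eo
  out[!is.finite(out)] <- NA_real_
  out
}
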