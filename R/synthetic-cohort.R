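#' Spectral parameter set for one diagnostic group
#'
#' Describes the generative model for one group's synthetic EEG: a 1/f^chi
#' background plus a single region-weighted oscillatory peak whose centre
#' frequency is redrawn once per non-overlapping 2-s epoch from
#' `Normal(df_mean, df_jitter_sd)` (per condition). Eye opening attenuates
#' the oscillation by `eo_amplitude_factor` and switches to the EO mean and
#' jitter.
#'
#' @param group_label One of `"HC"`, `"AD"`, `"DLB"`, `"PDD"`.
#' @param df_mean_ec,df_mean_eo Oscillatory peak centre frequency, Hz, within 4-15.
#' @param df_jitter_sd_ec,df_jitter_sd_eo SD of the per-epoch peak-frequency
#'   draws, Hz.
#' @param osc_amplitude_by_region Named numeric vector (F, C, T, P, O), peak
#'   envelope in microvolts; conventionally largest occipitally/parietally.
#' @param eo_amplitude_factor Multiplicative attenuation of the oscillation in
#'   the eyes-open condition.
#' @param background_exponent Exponent chi of the 1/f^chi background.
#' @param background_sd Background standard deviation per channel, microvolts.
#' @param subject_df_sd SD of a per-subject offset added to both conditions'
#'   peak centre frequency, Hz. Models stable inter-individual differences in
#'   the dominant rhythm.
#' @return A `group_spectral_params` list.
#' @export
group_spectral_params <- function(group_label,
                                  df_mean_ec, df_mean_eo,
                                  df_jitter_sd_ec, df_jitter_sd_eo,
                                  osc_amplitude_by_region =
                                    c(F = 8, C = 8, T = 7, P = 15, O = 20),
                                  eo_amplitude_factor = 0.5,
                                  background_exponent = 1,
                                  background_sd = 6,
                                  subject_df_sd = 0.4) {
  p <- structure(
    list(
      group_label = group_label,
      df_mean_ec = df_mean_ec, df_mean_eo = df_mean_eo,
      df_jitter_sd_ec = df_jitter_sd_ec, df_jitter_sd_eo = df_jitter_sd_eo,
      osc_amplitude_by_region = osc_amplitude_by_region,
      eo_amplitude_factor = eo_amplitude_factor,
      background_exponent = background_exponent,
      background_sd = background_sd,
      subject_df_sd = subject_df_sd
    ),
    class = "group_spectral_params"
  )
  validate_group_params(p)
}

#' @rdname group_spectral_params
#' @param params Object to validate.
#' @export
validate_group_params <- function(params) {
  if (!params$group_label %in% c("HC", "AD", "DLB", "PDD")) {
    abort("group_label must be one of HC, AD, DLB, PDD")
  }
  sds <- c(
    params$df_jitter_sd_ec, params$df_jitter_sd_eo,
    params$background_sd, params$subject_df_sd
  )
  if (any(sds < 0)) abort("standard deviations must be >= 0")
  if (any(params$osc_amplitude_by_region < 0)) abort("amplitudes must be >= 0")
  if (params$eo_amplitude_factor < 0) abort("eo_amplitude_factor must be >= 0")
  dfm <- c(params$df_mean_ec, params$df_mean_eo)
  if (any(dfm < 4 | dfm > 15)) abort("df means must lie within [4, 15] Hz")
  regs <- names(params$osc_amplitude_by_region)
  if (!all(c("F", "C", "T", "P", "O") %in% regs)) {
    abort("osc_amplitude_by_region must name all of F, C, T, P, O")
  }
  params
}

#' Default group parameter sets
#'
#' Package-default generative parameters for the four cohorts. These are
#' design defaults chosen to embody the qualitative contrasts reported for
#' clinical cohorts -- dementia groups have their dominant frequency slowed
#' into the high-theta range, healthy controls show a larger per-epoch
#' dominant-frequency jitter with eyes open than closed (so their EC/EO DFV
#' ratio falls below 1) while dementia groups jitter equally in both
#' conditions -- and are not measurements of any cohort.
#'
#' @return Named list of four [group_spectral_params()] objects
#'   (`HC`, `AD`, `DLB`, `PDD`).
#' @export
default_group_params <- function() {
  list(
    HC = group_spectral_params(
      "HC",
      df_mean_ec = 9.5, df_mean_eo = 9.5,
      df_jitter_sd_ec = 0.3, df_jitter_sd_eo = 1.0,
      eo_amplitude_factor = 0.4
    ),
    AD = group_spectral_params(
      "AD",
      df_mean_ec = 7.5, df_mean_eo = 7.5,
      df_jitter_sd_ec = 0.6, df_jitter_sd_eo = 0.6,
      eo_amplitude_factor = 0.8
    ),
    DLB = group_spectral_params(
      "DLB",
      df_mean_ec = 6.8, df_mean_eo = 6.8,
      df_jitter_sd_ec = 0.7, df_jitter_sd_eo = 0.7,
      eo_amplitude_factor = 0.8
    ),
    PDD = group_spectral_params(
      "PDD",
      df_mean_ec = 7.0, df_mean_eo = 7.0,
      df_jitter_sd_ec = 0.7, df_jitter_sd_eo = 0.7,
      eo_amplitude_factor = 0.8
    )
  )
}

# 1/f^chi background: spectrally shaped white noise rescaled to target sd;
# generates n_channels independent traces (columns) in one multi-column FFT
.background_1f <- function(n, exponent, sd_target, n_channels = 1) {
  if (sd_target <= 0) return(matrix(0, n, n_channels))
  w <- matrix(rnorm(n * n_channels), n, n_channels)
  if (exponent != 0) {
    spec <- stats::mvfft(w)
    k <- seq_len(n) - 1
    freq_idx <- pmin(k, n - k) # symmetric frequency index, DC at 0
    shape <- c(0, freq_idx[-1]^(-exponent / 2))
    w <- Re(stats::mvfft(spec * shape, inverse = TRUE)) / n
  }
  w <- sweep(w, 2, colMeans(w))
  sweep(w, 2, apply(w, 2, stats::sd) / sd_target, "/")
}

#' Synthesize one synthetic EEG recording
#'
#' Generates `1/f^chi` background noise (independent per channel) plus a
#' shared oscillation whose instantaneous frequency is redrawn from
#' `Normal(df_mean, df_jitter_sd)` once per non-overlapping 2-s epoch, with
#' phase kept continuous across epoch boundaries. The oscillation amplitude
#' is the region weight of each channel, multiplied by `eo_amplitude_factor`
#' in the eyes-open condition.
#'
#' @param params A [group_spectral_params()] object.
#' @param condition `"EC"` or `"EO"`.
#' @param montage Montage tibble covering all of `channel_labels`.
#' @param sampling_rate Hz.
#' @param duration_s Seconds; must be positive.
#' @param channel_labels Channels to synthesize; default all montage labels.
#' @param subject_id Identifier stored on the recording.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is used.
#' @param subject_df_offset Per-subject dominant-frequency offset in Hz
#'   (normally drawn by [make_cohort()]).
#' @return An [eeg_recording()] in microvolts.
#' @export
synthesize_recording <- function(params, condition, montage,
                                 sampling_rate = 1024, duration_s = 150,
                                 channel_labels = montage$label,
                                 subject_id = "sim", seed = NULL,
                                 subject_df_offset = 0) {
  if (!condition %in% c("EC", "EO")) abort("condition must be 'EC' or 'EO'")
  if (duration_s <= 0) abort("duration_s must be positive")
  if (!is.null(seed)) set.seed(seed)
  validate_group_params(params)

  regions <- montage_regions(montage, channel_labels)
  n <- round(duration_s * sampling_rate)
  epoch_len <- 2 * sampling_rate
  n_epochs <- ceiling(n / epoch_len)

  if (condition == "EC") {
    f_mean <- params$df_mean_ec + subject_df_offset
    f_sd <- params$df_jitter_sd_ec
    amp_scale <- 1
  } else {
    f_mean <- params$df_mean_eo + subject_df_offset
    f_sd <- params$df_jitter_sd_eo
    amp_scale <- params$eo_amplitude_factor
  }
  freqs <- rnorm(n_epochs, f_mean, f_sd)
  freqs <- pmin(pmax(freqs, 0.5), sampling_rate / 2 - 1)

  # phase-continuous oscillator with piecewise-constant frequency
  inst_freq <- rep(freqs, each = epoch_len)[seq_len(n)]
  phase <- 2 * pi * cumsum(inst_freq) / sampling_rate
  osc <- sin(phase)

  amps <- params$osc_amplitude_by_region[regions] * amp_scale
  bg <- .background_1f(
    n, params$background_exponent, params$background_sd,
    length(channel_labels)
  )
  x <- tcrossprod(amps, osc) + t(bg)
  eeg_recording(x, sampling_rate, channel_labels,
    subject_id = subject_id, condition = condition
  )
}

#' Cohort specification for the synthetic generator
#'
#' @param group_sizes Named integer vector, subjects per group, e.g.
#'   `c(HC = 15, AD = 12, DLB = 21, PDD = 17)`.
#' @param sampling_rate Hz; must exceed twice the 54 Hz analysis band edge.
#' @param duration_s Recording length per condition, seconds (>= 20, matching
#'   the minimum-duration inclusion rule).
#' @param channel_labels Electrodes to simulate.
#' @param params Named list of [group_spectral_params()], one per group.
#' @param montage Montage covering `channel_labels`.
#' @param seed Integer master seed; identical spec + seed gives a
#'   bit-identical cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(group_sizes = c(HC = 15, AD = 12, DLB = 21, PDD = 17),
                        sampling_rate = 1024, duration_s = 150,
                        montage = default_montage("full"),
                        channel_labels = montage$label,
                        params = default_group_params(),
                        seed = 1L) {
  if (length(group_sizes) == 0 || sum(group_sizes) == 0) abort("empty cohort")
  if (is.null(names(group_sizes)) ||
    !all(names(group_sizes) %in% c("HC", "AD", "DLB", "PDD"))) {
    abort("group_sizes must be named with HC/AD/DLB/PDD")
  }
  if (duration_s < 20) abort("duration_s must be >= 20 s")
  if (sampling_rate <= 2 * 54) abort("sampling_rate must exceed 108 Hz")
  if (!all(names(group_sizes) %in% names(params))) {
    abort("params must cover every group in group_sizes")
  }
  montage_regions(montage, channel_labels) # errors if labels uncovered
  structure(
    list(
      group_sizes = group_sizes, sampling_rate = sampling_rate,
      duration_s = duration_s, channel_labels = channel_labels,
      params = params, montage = montage, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a seeded synthetic cohort
#'
#' One eyes-closed and one eyes-open recording per subject. Per-subject
#' substreams are derived from the master seed, so cohorts are reproducible
#' and subjects mutually independent.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `subject_id`, `group`, and list-columns
#'   `ec`, `eo` holding [eeg_recording()] objects.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$group_sizes), times = spec$group_sizes)
  n_subj <- length(groups)
  set.seed(spec$seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1, 2 * n_subj), ncol = 2)
  df_offsets <- vapply(groups, function(g) {
    rnorm(1, 0, spec$params[[g]]$subject_df_sd)
  }, numeric(1))

  ids <- sprintf("sub-%03d", seq_len(n_subj))
  recs <- purrr::map(seq_len(n_subj), function(i) {
    p <- spec$params[[groups[i]]]
    ec <- synthesize_recording(p, "EC", spec$montage,
      spec$sampling_rate, spec$duration_s, spec$channel_labels,
      subject_id = ids[i], seed = sub_seeds[i, 1],
      subject_df_offset = df_offsets[i]
    )
    eo <- synthesize_recording(p, "EO", spec$montage,
      spec$sampling_rate, spec$duration_s, spec$channel_labels,
      subject_id = ids[i], seed = sub_seeds[i, 2],
      subject_df_offset = df_offsets[i]
    )
    list(ec = ec, eo = eo)
  })
  tibble::tibble(
    subject_id = ids,
    group = groups,
    ec = purrr::map(recs, "ec"),
    eo = purrr::map(recs, "eo")
  )
}

#' Write a cohort to EDF files plus a subjects table
#'
#' One EDF file per subject per condition plus a `subjects.tsv` manifest
#' (`subject_id`, `group`, `ec_path`, `eo_path`) readable by
#' [read_subjects_table()].
#'
#' @param cohort Tibble from [make_cohort()].
#' @param dir Output directory, created if needed.
#' @return Path to the subjects table, invisibly.
#' @export
write_cohort_edf <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::pmap(cohort, function(subject_id, group, ec, eo) {
    ec_path <- file.path(dir, paste0(subject_id, "_EC.edf"))
    eo_path <- file.path(dir, paste0(subject_id, "_EO.edf"))
    write_edf(ec, ec_path)
    write_edf(eo, eo_path)
    list(ec_path = ec_path, eo_path = eo_path)
  })
  tab <- tibble::tibble(
    subject_id = cohort$subject_id,
    group = cohort$group,
    ec_path = purrr::map_chr(paths, "ec_path"),
    eo_path = purrr::map_chr(paths, "eo_path")
  )
  out <- file.path(dir, "subjects.tsv")
  readr::write_tsv(tab, out, progress = FALSE)
  invisible(out)
}
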