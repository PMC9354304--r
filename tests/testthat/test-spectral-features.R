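# hand-built spectra object with specified per-window peak frequencies
make_fake_spectra <- function(peaks_by_window, channels = "O1", df = 0.125) {
  freqs <- seq(0, 512, by = df)
  psd <- array(0.001, dim = c(length(freqs), length(channels), length(peaks_by_window)))
  for (w in seq_along(peaks_by_window)) {
    i <- which.min(abs(freqs - peaks_by_window[w]))
    psd[i, , w] <- 1
  }
  structure(
    list(
      frequencies = freqs, psd = psd, channel_labels = channels,
      sampling_rate = 1024, nfft = 8192, taper = "hamming",
      subject_id = "fake", condition = "EC"
    ),
    class = "qeeg_spectra"
  )
}

test_that("the spectral grid has 0.125 Hz spacing and peaks land on it", {
  rec <- make_sine_recording(10, duration_s = 6)
  sp <- compute_spectra(segment_windows(rec))
  expect_equal(unique(round(diff(sp$frequencies), 10)), 0.125)
  # argmax of every window's periodogram sits at exactly 10 Hz
  for (w in seq_len(dim(sp$psd)[3])) {
    expect_equal(sp$frequencies[which.max(sp$psd[, 1, w])], 10)
  }
  expect_true(all(sp$psd >= 0))
})

test_that("the window-mean spectrum equals a single-call Welch oracle", {
  set.seed(99)
  x <- rnorm(30 * 1024) # 30 s of white noise -> 29 overlapping windows
  rec <- eeg_recording(matrix(x, 1), 1024, "O1")
  mine <- welch_mean_spectrum(compute_spectra(segment_windows(rec)))[, 1]
  oracle <- welch_psd_oracle(x, 1024)
  expect_lt(max(abs(mine - oracle)) / max(oracle), 1e-6)
})

test_that("total integrated PSD matches time-domain variance (Parseval)", {
  set.seed(5)
  rec <- eeg_recording(matrix(rnorm(4 * 1024), 1), 1024, "O1")
  sp <- compute_spectra(segment_windows(rec))
  df <- sp$frequencies[2] - sp$frequencies[1]
  for (w in seq_len(dim(sp$psd)[3])) {
    seg_var <- var(rec$samples[1, (1024 * (w - 1) + 1):(1024 * (w - 1) + 2048)])
    expect_equal(sum(sp$psd[, 1, w]) * df, seg_var, tolerance = 0.02)
  }
})

test_that("relative band powers integrate, tile and normalize correctly", {
  rec <- make_sine_recording(10, duration_s = 6)
  bp <- relative_band_power(compute_spectra(segment_windows(rec)))
  expect_gt(bp$alpha[1], 0.99)
  expect_lt(bp$delta[1] + bp$theta[1] + bp$high_theta[1] + bp$beta[1], 0.01)
  expect_equal(rowSums(as.matrix(bp[-1])), rep(1, nrow(bp)), tolerance = 1e-9)

  # equal-amplitude 3 Hz + 20 Hz mixture splits power evenly delta/beta
  mix <- make_sine_recording(c(3, 20), amps = c(1, 1), duration_s = 20)
  bp2 <- relative_band_power(compute_spectra(segment_windows(mix)))
  expect_equal(bp2$delta[1], 0.5, tolerance = 0.02)
  expect_equal(bp2$beta[1], 0.5, tolerance = 0.02)
  expect_error(
    relative_band_power(
      compute_spectra(segment_windows(mix)),
      bands = tibble::tibble(name = "bad", low = 5, high = 5)
    ),
    "empty band"
  )
})

test_that("dominant frequency statistics follow the search-band and SD conventions", {
  rec <- make_sine_recording(10, duration_s = 8)
  d <- dominant_frequency_stats(compute_spectra(segment_windows(rec)))
  expect_equal(d$DF, rep(10, 2))
  expect_equal(d$DFV, rep(0, 2))

  # strong 20 Hz + weak 5 Hz: search restricted to 4-15 Hz finds 5 Hz
  mix <- make_sine_recording(c(20, 5), amps = c(3, 0.5), duration_s = 8)
  d2 <- dominant_frequency_stats(compute_spectra(segment_windows(mix)))
  expect_equal(d2$DF, rep(5, 2))

  # alternating 8/10 Hz windows: DF is the mean, DFV the sample SD
  alt <- make_fake_spectra(rep(c(8, 10), 5))
  d3 <- dominant_frequency_stats(alt)
  expect_equal(d3$DF, 9)
  expect_equal(d3$DFV, sd(rep(c(8, 10), 5)))

  # a single window leaves the SD undefined
  one <- make_fake_spectra(10)
  expect_true(is.na(dominant_frequency_stats(one)$DFV))

  # scale invariance of DF/DFV and relative power
  sp <- compute_spectra(segment_windows(rec))
  sp_scaled <- sp
  sp_scaled$psd <- sp$psd * 7^2
  expect_equal(dominant_frequency_stats(sp_scaled), d)
  expect_equal(
    relative_band_power(sp_scaled),
    relative_band_power(sp),
    tolerance = 1e-12
  )
})

test_that("region aggregation is an unweighted mean, invariant to channel order", {
  m <- default_montage("reduced")
  v <- setNames(rep(0, 10), m$label)
  v[c("O1", "O2")] <- c(9, 11)
  agg <- region_aggregate(v, m)
  expect_equal(agg$value[agg$region == "O"], 10)
  expect_equal(agg$value[agg$region == "F"], 0)

  vc <- setNames(rep(4.2, 10), m$label)
  expect_equal(region_aggregate(vc, m)$value, rep(4.2, 5))

  perm <- sample(length(v))
  expect_equal(region_aggregate(v[perm], m), region_aggregate(v, m))

  expect_error(region_aggregate(v[c("O1", "C3")], m), "zero channels")
})

test_that("theta-alpha ratio honours the numerator convention", {
  expect_equal(theta_alpha_ratio(theta = 0.1, high_theta = 0.2, alpha = 0.4), 0.5)
  expect_equal(theta_alpha_ratio(0.1, 0, 0.4), 0)
  expect_equal(theta_alpha_ratio(0.1, 0.2, 0.4, numerator = "theta"), 0.25)
  expect_equal(theta_alpha_ratio(0.1, 0.2, 0.4, numerator = "theta_broad"), 0.75)
  expect_error(theta_alpha_ratio(0.1, 0.2, 0), "positive")

  # a slowed oscillator (7 Hz) has higher occipital TAR than a 10 Hz one
  m <- default_montage("reduced")
  slow <- group_spectral_params("AD", 7, 7, 0.2, 0.2, subject_df_sd = 0)
  fast <- group_spectral_params("HC", 10, 10, 0.2, 0.2, subject_df_sd = 0)
  f_slow <- recording_features(
    synthesize_recording(slow, "EC", m, duration_s = 10, seed = 2),
    m,
    preprocess = FALSE
  )
  f_fast <- recording_features(
    synthesize_recording(fast, "EC", m, duration_s = 10, seed = 2),
    m,
    preprocess = FALSE
  )
  expect_gt(
    f_slow$TAR[f_slow$region == "O"],
    f_fast$TAR[f_fast$region == "O"]
  )
})

test_that("the EC/EO DFV ratio handles equal, fractional and degenerate inputs", {
  expect_equal(dfv_ec_eo_ratio(0.5, 1.0), 0.5)
  expect_equal(dfv_ec_eo_ratio(0.8, 0.8), 1.0)
  expect_true(is.na(dfv_ec_eo_ratio(0.5, 0)))
  expect_true(is.na(dfv_ec_eo_ratio(0.5, NA)))
})

test_that("the feature table has the documented shape and handles missing data", {
  m <- default_montage("reduced")
  p <- default_group_params()
  spec <- cohort_spec(
    group_sizes = c(HC = 1, AD = 1), duration_s = 20,
    montage = m, seed = 4
  )
  co <- make_cohort(spec)
  f <- build_feature_table(co, m, preprocess = FALSE)
  # 2 conditions x 5 regions x 8 features + 5 ratio columns
  expect_equal(length(feature_columns(f)), 2 * 5 * 8 + 5)
  expect_equal(nrow(f), 2)
  # five relative powers sum to 1 for each subject/condition/region
  for (cond in c("EC", "EO")) {
    for (reg in c("F", "C", "T", "P", "O")) {
      cols <- paste(cond, reg, c("delta", "theta", "high_theta", "alpha", "beta"),
        sep = "_"
      )
      expect_equal(rowSums(f[cols]), rep(1, 2), tolerance = 1e-9)
    }
  }
  # DF lies in the 4-15 Hz search band, DFV is nonnegative
  expect_true(all(f$EC_O_DF >= 4 & f$EC_O_DF <= 15))
  expect_true(all(f$EC_O_DFV >= 0))

  # subject lacking EO keeps EC columns but loses ratio columns
  co_miss <- co
  co_miss$eo[2] <- list(NULL)
  f2 <- build_feature_table(co_miss, m, preprocess = FALSE)
  expect_true(is.na(f2$P_DFV_ECEO_ratio[2]))
  expect_false(is.na(f2$EC_P_DFV[2]))

  # a clinical column joins as exactly one extra numeric column
  clin <- tibble::tibble(subject_id = co$subject_id, camcog_memory = c(24, 11))
  f3 <- build_feature_table(co, m, clinical = clin, preprocess = FALSE)
  expect_equal(ncol(f3), ncol(f) + 1)
  expect_true(is.numeric(f3$camcog_memory))

  dup <- co
  dup$subject_id <- c("a", "a")
  expect_error(build_feature_table(dup, m), "duplicate")
})

test_that("feature tables round-trip through TSV", {
  f <- make_separated_features(n_per_group = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(f, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back[names(f)]), as.data.frame(f))
})
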