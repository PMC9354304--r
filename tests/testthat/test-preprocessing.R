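test_that("baseline subtraction zeroes channel means and is idempotent", {
  rec <- make_sine_recording(10, offset = 5, duration_s = 3)
  out <- subtract_baseline(rec)
  expect_equal(rowMeans(out$samples), c(O1 = 0, O2 = 0), tolerance = 1e-12)

  const <- eeg_recording(matrix(5, 2, 100), 100, c("O1", "O2"))
  expect_equal(max(abs(subtract_baseline(const)$samples)), 0)

  again <- subtract_baseline(out)
  expect_equal(again$samples, out$samples)

  # sine + offset: offset removed, oscillation preserved
  mid <- 1024:(2 * 1024)
  pure <- make_sine_recording(10, duration_s = 3)
  expect_equal(out$samples[1, mid], pure$samples[1, mid], tolerance = 1e-9)
})

test_that("band-pass filter matches the designed digital response", {
  fs <- 1024
  rec <- make_sine_recording(10, fs = fs, duration_s = 10)
  out <- bandpass_filter(rec)
  mid <- (4 * fs):(6 * fs)
  # forward-backward filtering squares the magnitude response of the design;
  # evaluate the designed transfer function directly at frequency f
  h <- function(filt, f) {
    z <- exp(-1i * 2 * pi * f / fs)
    k <- seq_along(filt$b) - 1
    abs(sum(filt$b * z^k) / sum(filt$a * z^k))^2
  }
  hp <- signal::butter(2, 0.3 / (fs / 2), "high")
  lp <- signal::butter(2, 54 / (fs / 2), "low")
  expected_gain <- h(hp, 10) * h(lp, 10)
  expect_equal(max(abs(out$samples[1, mid])), expected_gain, tolerance = 0.02)
  expect_gt(expected_gain, 0.98) # passband: within 2% of unity

  # zero phase: cross-correlation with the input peaks at lag 0
  cc <- stats::ccf(out$samples[1, mid], rec$samples[1, mid],
    lag.max = 30, plot = FALSE
  )
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # DC is rejected almost completely
  dc <- eeg_recording(matrix(5, 2, 10 * fs), fs, c("O1", "O2"))
  dc_out <- bandpass_filter(dc)
  expect_lt(mean(dc_out$samples[1, ]^2) / 25, 1e-4)

  # stop band: 100 Hz attenuated by the designed squared response
  hi <- make_sine_recording(100, fs = fs, duration_s = 10)
  hi_out <- bandpass_filter(hi)
  expect_equal(
    max(abs(hi_out$samples[1, mid])),
    h(hp, 100) * h(lp, 100),
    tolerance = 0.15
  )
  expect_lt(max(abs(hi_out$samples[1, mid])), 0.12)

  expect_error(bandpass_filter(rec, high = 600), "Nyquist")
})

test_that("filtering and baseline subtraction commute", {
  rec <- make_sine_recording(c(5, 11), amps = c(1, 2),
    offset = 2, noise_sd = 0.5, duration_s = 6, seed = 3
  )
  a <- bandpass_filter(subtract_baseline(rec))
  b <- subtract_baseline(bandpass_filter(rec))
  expect_equal(a$samples, b$samples, tolerance = 1e-6)
})

test_that("spherical-spline interpolation reconstructs held-out channels", {
  m <- default_montage("full")
  labels <- m$label
  n_t <- 50
  t_sig <- sin(2 * pi * 8 * seq_len(n_t) / 256)

  # spatially constant field reproduced essentially exactly
  x <- matrix(rep(t_sig, each = length(labels)), nrow = length(labels))
  rec <- eeg_recording(x, 256, labels, bad_channels = "Cz")
  out <- interpolate_bad_channels(rec, m)
  i <- match("Cz", labels)
  expect_equal(out$samples[i, ], t_sig, tolerance = 1e-6)
  expect_length(out$bad_channels, 0)

  # no bad channels: untouched
  rec2 <- eeg_recording(x, 256, labels)
  expect_identical(interpolate_bad_channels(rec2, m)$samples, rec2$samples)

  # field linear in sensor position: held-out channel recovered within 5%
  pos <- qeegdx:::montage_positions(m, labels)
  field <- 10 + 4 * pos[, 1] + 3 * pos[, 2] + 2 * pos[, 3]
  xl <- field %*% t(rep(1, n_t))
  for (held_out in c("Pz", "C3", "PO4")) {
    recl <- eeg_recording(xl, 256, labels, bad_channels = held_out)
    outl <- interpolate_bad_channels(recl, m)
    j <- match(held_out, labels)
    rel_err <- abs(outl$samples[j, 1] - field[j]) / abs(field[j])
    expect_lt(rel_err, 0.05)
  }

  few <- eeg_recording(xl[1:4, ], 256, labels[1:4], bad_channels = labels[1])
  expect_error(interpolate_bad_channels(few, m), "at least 4")
})

test_that("average referencing zeroes the cross-channel mean and keeps differences", {
  x <- rbind(c(1, 4), c(3, 8))
  rec <- eeg_recording(x, 10, c("C3", "C4"))
  out <- average_reference(rec)
  expect_equal(out$samples[, 1], c(C3 = -1, C4 = 1))
  expect_equal(colMeans(out$samples), c(0, 0), tolerance = 1e-12)
  expect_equal(out$reference, "average")

  # idempotent
  expect_equal(average_reference(out)$samples, out$samples)

  # common signal removed exactly; pairwise differences preserved
  rec2 <- make_sine_recording(c(7), duration_s = 2)
  rec2$samples[1, ] <- rec2$samples[1, ] + 3
  common <- sin(2 * pi * 3 * seq_len(ncol(rec2$samples)) / 1024)
  rec3 <- rec2
  rec3$samples <- sweep(rec3$samples, 2, -common)
  out2 <- average_reference(rec2)
  out3 <- average_reference(rec3)
  expect_equal(out2$samples, out3$samples, tolerance = 1e-12)
  expect_equal(
    rec2$samples[1, ] - rec2$samples[2, ],
    out2$samples[1, ] - out2$samples[2, ],
    tolerance = 1e-12
  )
})

test_that("segmentation yields the expected window count and layout", {
  rec <- make_sine_recording(10, duration_s = 150, labels = "O1")
  seg <- segment_windows(rec)
  expect_equal(dim(seg$data), c(2048, 1, 149)) # floor(150 - 2) + 1

  # consecutive windows share exactly half their samples
  expect_equal(seg$data[1025:2048, 1, 1], seg$data[1:1024, 1, 2])
  # onsets tile [0, duration - 2] at 1-s steps
  expect_equal(seg$onsets_s, 0:148)

  one <- segment_windows(make_sine_recording(10, duration_s = 2, labels = "O1"))
  expect_equal(dim(one$data)[3], 1)
  expect_error(
    segment_windows(make_sine_recording(10, duration_s = 1.5, labels = "O1")),
    "shorter"
  )
})

test_that("the minimum-duration inclusion rule follows the configured reading", {
  expect_true(passes_duration_rule(25, 25))
  expect_false(passes_duration_rule(10, 9))
  expect_true(passes_duration_rule(20, 0)) # combined-sum reading
  expect_false(passes_duration_rule(20, 0, rule = "each"))
  expect_true(passes_duration_rule(20, 21, rule = "each"))
  expect_error(passes_duration_rule(-1, 5), ">= 0")
})
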