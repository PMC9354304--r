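# Fixture builders and independent oracles used across the suite.

# multichannel recording holding a sum of sinusoids (+ optional offset/noise)
make_sine_recording <- function(freqs, amps = rep(1, length(freqs)),
                                fs = 1024, duration_s = 6,
                                labels = c("O1", "O2"), offset = 0,
                                noise_sd = 0, condition = "EC", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  ch <- Reduce(`+`, Map(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  x <- matrix(rep(ch, length(labels)), nrow = length(labels), byrow = TRUE)
  x <- x + offset
  if (noise_sd > 0) x <- x + matrix(rnorm(length(x), 0, noise_sd), nrow = nrow(x))
  eeg_recording(x, fs, labels, condition = condition)
}

# single-call Welch PSD oracle: explicit segment loop over the raw signal,
# Hamming taper, 50% overlap, zero-padding to nfft; one-sided density
welch_psd_oracle <- function(x, fs, nseg = 2048, nfft = 8192) {
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1))
  U <- sum(w^2)
  hop <- nseg / 2
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  acc <- numeric(nfft / 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * w
    X <- fft(c(seg, rep(0, nfft - nseg)))
    p <- abs(X[1:(nfft / 2 + 1)])^2 / (fs * U)
    p[2:(nfft / 2)] <- 2 * p[2:(nfft / 2)]
    acc <- acc + p
  }
  acc / length(starts)
}

# one-way ANOVA F by explicit sums of squares
anova_f_oracle <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  lv <- unique(groups)
  ss_between <- sum(vapply(lv, function(g) {
    n_g <- sum(groups == g)
    n_g * (mean(values[groups == g]) - grand)^2
  }, numeric(1)))
  ss_within <- sum(vapply(lv, function(g) {
    sum((values[groups == g] - mean(values[groups == g]))^2)
  }, numeric(1)))
  df1 <- length(lv) - 1
  df2 <- length(values) - length(lv)
  (ss_between / df1) / (ss_within / df2)
}

# AUC by brute force over all positive-negative pairs, ties counted 1/2
auc_bruteforce <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) {
    tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  }
  tot / (length(sp) * length(sn))
}

# closed-form NCA objective (no regularization shortcuts), direct loops
nca_objective_oracle <- function(x, y, w, lambda = 0) {
  n <- nrow(x)
  obj <- 0
  for (i in seq_len(n)) {
    d <- vapply(seq_len(n), function(j) sum(w^2 * (x[i, ] - x[j, ])^2), 0)
    e <- exp(-(d - min(d[-i])))
    e[i] <- 0
    p <- e / sum(e)
    obj <- obj + sum(p[y == y[i]]) # p[i] is 0, so self is excluded
  }
  obj - lambda * sum(w^2)
}

# small feature table with well-separated gaussian groups, for classifier tests
make_separated_features <- function(n_per_group = 12, gap = 6, seed = 1,
                                    groups = c("HC", "AD", "DLB", "PDD")) {
  set.seed(seed)
  k <- length(groups)
  centers <- diag(gap, k, 3 + k)[, seq_len(3 + k - 1), drop = FALSE]
  rows <- purrr::map_dfr(seq_len(k), function(g) {
    x <- matrix(rnorm(n_per_group * ncol(centers)), n_per_group) +
      matrix(centers[g, ], n_per_group, ncol(centers), byrow = TRUE) + 3
    d <- tibble::as_tibble(as.data.frame(x))
    names(d) <- paste0("feat_", seq_len(ncol(d)))
    dplyr::bind_cols(tibble::tibble(group = groups[g]), d)
  })
  rows$subject_id <- sprintf("s%02d", seq_len(nrow(rows)))
  rows
}
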