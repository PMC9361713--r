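test_that("region RMS medians reproduce hand-computable cases", {
  fs <- 100
  n <- 1000
  mask <- contamination_mask(rep(c(FALSE, TRUE), each = 500), fs)
  # constant signal
  expect_equal(region_rms_median(rep(-2, n), mask, "noise", fs = fs), 2)
  expect_equal(region_rms_median(rep(-2, n), mask, "emg", fs = fs), 2)
  # unit sinusoid much longer than the window
  t <- seq_len(n) / fs
  expect_equal(region_rms_median(sin(2 * pi * 10 * t), mask, "noise",
                                 fs = fs),
               1 / sqrt(2), tolerance = 0.01)
  # piecewise windows with RMS {1, 2, 9} -> median 2
  x <- c(rep(1, 100), rep(2, 100), rep(9, 100))
  m3 <- contamination_mask(rep(FALSE, 300), fs)
  expect_equal(region_rms_median(x, m3, "noise", fs = fs), 2)
  # degenerate region
  expect_error(region_rms_median(rep(1, 50), contamination_mask(rep(FALSE, 50),
                                                                fs),
                                 "emg", fs = fs),
               "shorter than one")
})

test_that("GL/GH obey the identity and pure-gain scale laws", {
  rec <- small_recording(seed = 61, duration_s = 30)
  mx <- rec$mixed
  tf_id <- time_features(mx, mx, rec$mask)
  expect_equal(tf_id$GL, 0)
  expect_equal(tf_id$GH, 0)
  tf_half <- time_features(mx, time_series(mx$samples / 2, 1000), rec$mask)
  expect_equal(tf_half$GL, 20 * log10(0.5), tolerance = 1e-8)
  expect_equal(tf_half$GH, 20 * log10(0.5), tolerance = 1e-8)
  # the four features recompute exactly from the stored medians
  md <- tf_id$medians
  expect_equal(tf_id$GXin, 20 * log10(md[["Xin1"]] / md[["Xin0"]]))
  # scale equivariance: gain g shifts GL and GH by 20 log10 g
  g <- 3.7
  tf_g <- time_features(mx, time_series(g * mx$samples, 1000), rec$mask)
  expect_equal(tf_g$GL, 20 * log10(g), tolerance = 1e-8)
  expect_equal(tf_g$GH, 20 * log10(g), tolerance = 1e-8)
})

test_that("GXin reflects a constructed in/out amplitude contrast", {
  fs <- 100
  flags <- rep(c(FALSE, TRUE), each = 500)
  x <- ifelse(flags, 10, 1) * sin(2 * pi * 7 * seq_len(1000) / fs)
  tf <- time_features(time_series(x, fs), time_series(x, fs),
                      contamination_mask(flags, fs))
  expect_equal(tf$GXin, 20, tolerance = 0.05)
  expect_equal(tf$GXout, 20, tolerance = 0.05)
})

test_that("feature curves have the k-grid geometry and monotone GL", {
  rec <- small_recording(seed = 62, duration_s = 40)
  fc <- feature_curve(rec$mixed, "SSA", rec$mask)
  expect_length(fc$k, 20)
  expect_length(fc$GL, 20)
  expect_length(fc$GH, 20)
  expect_equal(fc$k, seq(0.1, 2, by = 0.1))
  expect_true(all(diff(fc$GL) <= 1e-9))
  expect_error(feature_curve(rec$mixed, "SSA", rec$mask,
                             k_grid = c(1, 0.5)),
               "strictly increasing")
})

test_that("uncontaminated signals give nearly coincident GL and GH curves", {
  rec <- small_recording(seed = 63, duration_s = 40)
  # 'contaminated' channel without any EMG: the mask still labels regions
  fc <- feature_curve(rec$eeg, "SSA", rec$mask)
  expect_lt(normalized_distance(fc), 0.12)
  # the truly contaminated channel sits far away
  fc2 <- feature_curve(rec$mixed, "SSA", rec$mask)
  expect_gt(normalized_distance(fc2), 3 * normalized_distance(fc))
})

test_that("normalized distance is a bounded symmetric dissimilarity", {
  expect_equal(normalized_distance(c(3, 0), c(0, 4)), 5 / 7)
  u <- c(1, -2, 3)
  expect_equal(normalized_distance(u, u), 0)
  expect_equal(normalized_distance(u, -u), 1)
  expect_equal(normalized_distance(numeric(3), numeric(3)), 0)
  set.seed(64)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(normalized_distance(a, b), normalized_distance(b, a))
  expect_lte(normalized_distance(a, b), 1)
  expect_error(normalized_distance(1:3, 1:4), "lengths differ")
})

test_that("Yule-Walker spectrum is flat for white noise, peaked for a tone", {
  set.seed(65)
  sp <- ar_spectrum(rnorm(50000), order = 10, df = 0.1, fs = 200)
  expect_true(all(sp$pxx >= 0))
  expect_lt(stats::sd(sp$pxx) / mean(sp$pxx), 0.3)
  # Parseval: grid integral approximates the variance
  x <- rnorm(50000)
  sp2 <- ar_spectrum(x, order = 10, df = 0.01, fs = 200)
  expect_equal(sum(sp2$pxx) * 0.01, stats::var(x), tolerance = 0.1)
  # 10 Hz tone in weak noise: AR(10) peak within 0.5 Hz
  t <- seq_len(20000) / 200
  tone <- sin(2 * pi * 10 * t) + rnorm(20000, sd = 0.1)
  sp3 <- ar_spectrum(tone, order = 10, df = 0.01, fs = 200)
  expect_lt(abs(sp3$f[which.max(sp3$pxx)] - 10), 0.5)
  expect_error(ar_spectrum(rep(1, 1000), fs = 200), "constant")
})

test_that("median frequency matches the cumulative-sum oracle", {
  set.seed(66)
  for (i in 1:20) {
    f <- seq(0, 50, by = 0.5)
    pxx <- stats::runif(length(f))
    got <- median_frequency(list(f = f, pxx = pxx))
    tot <- sum(pxx)
    acc <- 0
    j <- 0
    repeat {
      j <- j + 1
      acc <- acc + pxx[j]
      if (acc >= tot / 2) break
    }
    expect_identical(got$fmed, f[j])
    expect_identical(got$p_at_fmed, pxx[j])
  }
  # all mass at one grid point
  p1 <- numeric(101); p1[31] <- 2
  got <- median_frequency(list(f = 0:100, pxx = p1))
  expect_equal(got$fmed, 30)
  # symmetric two-peak spectrum: fmed between the peaks
  p2 <- numeric(101); p2[c(11, 21)] <- 1
  got2 <- median_frequency(list(f = 0:100, pxx = p2))
  expect_gte(got2$fmed, 10)
  expect_lte(got2$fmed, 20)
  expect_error(median_frequency(list(f = 0:3, pxx = numeric(4))),
               "no positive mass")
})

test_that("band features respect the band partition", {
  set.seed(67)
  fs <- 200
  t <- seq_len(20000) / fs
  tone <- sin(2 * pi * 10 * t) + rnorm(20000, sd = 0.05)
  bf <- band_features(tone, df = 0.05, fs = fs)
  alpha <- bf[bf$band == "Alpha", ]
  expect_gte(alpha$fmed, 7)
  expect_lt(alpha$fmed, 13)
  # alpha-limited noise: delta band at least 20 dB weaker
  nz <- rnorm(20000)
  f <- (seq_len(20000) - 1) / 20000 * fs
  fp <- pmin(f, fs - f)
  X <- stats::fft(nz)
  X[!(fp >= 7 & fp < 13)] <- 0
  alpha_noise <- Re(stats::fft(X, inverse = TRUE)) / 20000
  bf2 <- band_features(alpha_noise, df = 0.05, fs = fs)
  p_alpha <- bf2[bf2$band == "Alpha", "power"]
  p_delta <- bf2[bf2$band == "Delta", "power"]
  expect_gt(10 * log10(p_alpha / p_delta), 20)
  # every per-band fmed lies inside its band edges
  edges <- list(Delta = c(0.5, 4), Theta = c(4, 7), Alpha = c(7, 13),
                Beta = c(13, 30), Gamma = c(30, 70))
  for (b in names(edges)) {
    fm <- bf2[bf2$band == b, "fmed"]
    if (!is.na(fm)) {
      expect_gte(fm, edges[[b]][1])
      expect_lte(fm, edges[[b]][2])
    }
  }
  expect_error(band_features(rnorm(1000), fs = 100), "too low")
})

test_that("SSA reference + RLS recovers heavily contaminated EEG", {
  # decomposition-derived (not oracle) EEG reference at -10 dB in-burst SNR:
  # contamination is attenuated (GH < 0) while clean regions stay within 3 dB
  rec <- small_recording(seed = 68, duration_s = 110)
  mx <- rec$mixed
  emg_ref <- make_emg_reference(mx, "SSA", rec$mask, k = 1.5)
  eeg_ref <- make_eeg_reference(mx, emg_ref)
  cl <- clean_eeg(mx, eeg_ref, filter_config("RLS", reference_kind = "EEG_ref"))
  tf <- time_features(mx, cl, rec$mask)
  expect_lt(tf$GH, 0)
  expect_lte(abs(tf$GL), 3)
})
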