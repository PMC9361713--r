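test_that("soft thresholding matches the elementwise shrinkage formula", {
  expect_identical(soft_threshold(c(2, -2, 0.3), 0.5), c(1.5, -1.5, 0))
  set.seed(31)
  v <- rnorm(10000, sd = 2)
  t0 <- 0.7
  oracle <- ifelse(abs(v) - t0 < 0, 0, sign(v) * (abs(v) - t0))
  expect_identical(soft_threshold(v, t0), oracle)
  # t = 0 is the identity; contraction holds for any t
  expect_identical(soft_threshold(v, 0), v)
  for (tt in c(0.1, 1, 5)) {
    out <- soft_threshold(v, tt)
    expect_true(all(abs(out) <= abs(v)))
    expect_true(all(out * v >= 0))   # sign preserved or zeroed
  }
  expect_error(soft_threshold(v, -1), "nonnegative")
})

test_that("thresholds are k times the noise-region SD of each component", {
  set.seed(32)
  n <- 2000
  comps <- list(rnorm(n), 2 * rnorm(n), numeric(n))
  cs <- component_set(comps, method = "SSA", fs = 100)
  mask <- contamination_mask(seq_len(n) > 1000, fs = 100)  # low = first half
  tv <- estimate_thresholds(cs, mask, k = 1.5)
  lo <- seq_len(1000)
  expect_equal(tv$t,
               1.5 * vapply(comps, function(c) stats::sd(c[lo]), numeric(1)))
  # linearity in k, zero at k = 0, zero for a silent component
  tv0 <- estimate_thresholds(cs, mask, k = 0)
  expect_true(all(tv0$t == 0))
  tv2 <- estimate_thresholds(cs, mask, k = 3)
  expect_equal(tv2$t, 2 * tv$t)
  expect_equal(tv$t[3], 0)
  expect_error(estimate_thresholds(cs, contamination_mask(rep(TRUE, n), 100)),
               "noise")
})

test_that("reference construction shrinks noise regions, preserves bursts", {
  rec <- small_recording(seed = 33, duration_s = 60)
  mx <- rec$mixed
  ref <- make_emg_reference(mx, "SSA", rec$mask, k = 1.5)
  hi <- rec$mask$flags
  ratio <- function(v) sqrt(mean(v[hi]^2)) / sqrt(mean(v[!hi]^2))
  # reference concentrates energy in bursts more than the raw mixture does
  expect_gt(ratio(ref$samples), ratio(mx$samples))
  # k = 0 with the complete SSA set returns the input
  ref0 <- make_emg_reference(mx, "SSA", rec$mask, k = 0)
  expect_lt(rel_err(ref0$samples, mx$samples), 1e-8)
  # absurdly large k shrinks everything to zero
  refbig <- make_emg_reference(mx, "SSA", rec$mask, k = 1e6)
  expect_true(all(refbig$samples == 0))
})

test_that("raising k never raises the reference noise-region amplitude", {
  rec <- small_recording(seed = 34, duration_s = 40)
  cs <- ssa(rec$mixed$samples, fs = 1000)
  lo <- !rec$mask$flags
  rms <- sapply(c(0.5, 1, 1.5, 2), function(k) {
    r <- make_emg_reference(rec$mixed$samples, cs, rec$mask, k = k, fs = 1000)
    sqrt(mean(r$samples[lo]^2))
  })
  expect_true(all(diff(rms) <= 1e-12))
})

test_that("EMG and EEG references always sum back to the contaminated signal", {
  rec <- small_recording(seed = 35, duration_s = 30)
  ref <- make_emg_reference(rec$mixed, "Wavelet", rec$mask, k = 1.5)
  eeg_ref <- make_eeg_reference(rec$mixed, ref)
  expect_equal(eeg_ref$samples + ref$samples, rec$mixed$samples)
  expect_equal(make_eeg_reference(rec$mixed,
                                  time_series(numeric(length(rec$mixed)),
                                              1000))$samples,
               rec$mixed$samples)
  expect_true(all(make_eeg_reference(rec$mixed, rec$mixed)$samples == 0))
  expect_error(make_eeg_reference(rec$mixed, rec$mixed$samples[1:10],
                                  fs = 1000),
               "lengths differ")
})

test_that("EMD-PCA reference skips the soft-thresholding stage", {
  rec <- small_recording(seed = 36, duration_s = 30)
  ref <- make_emg_reference(rec$mixed, "EMD_PCA", rec$mask, k = 1.5)
  expect_null(attr(ref, "thresholds"))
  # same k, different k: identical reference (no k-dependence at all)
  ref2 <- make_emg_reference(rec$mixed, "EMD_PCA", rec$mask, k = 0.1)
  expect_identical(ref$samples, ref2$samples)
  # thresholded methods do depend on k
  r1 <- make_emg_reference(rec$mixed, "SSA", rec$mask, k = 0.5)
  r2 <- make_emg_reference(rec$mixed, "SSA", rec$mask, k = 1.5)
  expect_false(identical(r1$samples, r2$samples))
  expect_false(is.null(attr(r1, "thresholds")))
})
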