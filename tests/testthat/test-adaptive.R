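test_that("output plus error equals desired for every method", {
  set.seed(41)
  d <- rnorm(3000)
  r <- rnorm(3000)
  for (m in c("LMS", "NLMS", "RLS", "Wiener")) {
    fr <- adaptive_filter(d, r, filter_config(m), fs = 100)
    expect_equal(fr$output$samples + fr$error$samples, d, tolerance = 1e-12)
  }
})

test_that("zero reference passes the desired signal through", {
  set.seed(42)
  d <- rnorm(500)
  z <- numeric(500)
  for (m in c("LMS", "NLMS", "RLS")) {
    fr <- adaptive_filter(d, z, filter_config(m), fs = 100)
    expect_true(all(fr$output$samples == 0))
    expect_equal(fr$error$samples, d)
    expect_equal(clean_eeg(d, z, filter_config(m, reference_kind = "EMG_ref"),
                           fs = 100)$samples, d)
  }
  # Wiener normal equations are singular for an all-zero reference
  expect_error(adaptive_filter(d, z, filter_config("Wiener"), fs = 100),
               "singular")
})

test_that("Wiener identifies a known FIR system from clean data", {
  set.seed(43)
  n <- 200000
  r <- rnorm(n)
  h <- c(0.5, -0.3, 0.2)
  d <- as.numeric(stats::filter(r, h, method = "convolution", sides = 1))
  d[1] <- h[1] * r[1]
  d[2] <- h[1] * r[2] + h[2] * r[1]
  fr <- adaptive_filter(d, r, filter_config("Wiener", order = 10), fs = 1000)
  expect_lt(max(abs(fr$weights[1:3] - h)), 1e-6)
  expect_lt(max(abs(fr$weights[4:10])), 1e-5)
  expect_lt(mean(fr$error$samples^2), 1e-10 * mean(d^2))
})

test_that("Wiener solution beats randomized FIR competitors of equal order", {
  set.seed(44)
  n <- 5000
  r <- rnorm(n)
  d <- as.numeric(stats::filter(r, c(0.4, 0.1, -0.2), sides = 1))
  d[1:2] <- 0
  d <- d + rnorm(n, sd = 0.3)
  ord <- 6
  fr <- adaptive_filter(d, r, filter_config("Wiener", order = ord), fs = 100)
  wiener_mse <- mean(fr$error$samples^2)
  for (i in 1:20) {
    w <- fr$weights + rnorm(ord, sd = 0.05)
    y <- as.numeric(stats::filter(r, w, sides = 1))
    y[seq_len(ord - 1)] <- 0
    expect_gte(mean((d - y)^2, na.rm = TRUE), wiener_mse - 1e-12)
  }
})

test_that("recursive filters are deterministic and cancel a filtered artifact", {
  rec <- small_recording(seed = 45, duration_s = 60)
  mx <- rec$mixed
  src <- time_series(rec$emg_gain * rec$emg$samples, 1000)
  hi <- rec$mask$flags
  for (m in c("RLS", "NLMS", "LMS")) {
    cfg <- filter_config(m, reference_kind = "EMG_ref")
    fr1 <- adaptive_filter(mx, src, cfg)
    fr2 <- adaptive_filter(mx, src, cfg)
    expect_identical(fr1$error$samples, fr2$error$samples)
  }
  # in-burst power of the cancellation error drops below the raw mixture's
  # for the exactly-tracking filters (NLMS needs longer records before its
  # onset transients average out; its median-based gains are covered by the
  # end-to-end cancellation checks)
  for (m in c("RLS", "LMS")) {
    fr <- adaptive_filter(mx, src, filter_config(m, reference_kind = "EMG_ref"))
    expect_lt(mean(fr$error$samples[hi]^2), mean(mx$samples[hi]^2))
  }
})

test_that("cleaned-signal selection follows the reference kind", {
  set.seed(46)
  d <- rnorm(2000)
  r <- rnorm(2000)
  fr_emg <- adaptive_filter(d, r, filter_config("RLS",
                                                reference_kind = "EMG_ref"),
                            fs = 100)
  expect_identical(fr_emg$cleaned$samples, fr_emg$error$samples)
  fr_eeg <- adaptive_filter(d, r, filter_config("RLS",
                                                reference_kind = "EEG_ref"),
                            fs = 100)
  expect_identical(fr_eeg$cleaned$samples, fr_eeg$output$samples)
  # EEG-like reference equal to the desired signal, Wiener order 1:
  # unit-gain solution reproduces the input
  fr <- adaptive_filter(d, d, filter_config("Wiener", order = 1,
                                            reference_kind = "EEG_ref"),
                        fs = 100)
  expect_equal(fr$cleaned$samples, d, tolerance = 1e-10)
})

test_that("argument validation rejects bad inputs", {
  expect_error(adaptive_filter(rnorm(5), rnorm(4), filter_config(), fs = 10),
               "lengths differ")
  expect_error(adaptive_filter(rnorm(5), rnorm(5),
                               filter_config("RLS", order = 10), fs = 10),
               "shorter than the filter order")
  expect_error(filter_config("RLS", rls_forgetting = 1.5))
})
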