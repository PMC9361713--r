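# Shared fixture builders. Desk-scale sampling rates keep the suite fast;
# the generator's protocol structure (event counts, durations, gaps) is
# identical at any rate.

# one-participant recording cropped to `duration_s`, remixed on the crop so
# the in-burst SNR is exact over the cropped mask
small_recording <- function(seed, fs = 1000, duration_s = 110,
                            snr_db = -10) {
  p <- synth_params(fs = fs, seed = seed, snr_db = snr_db)
  rec <- synthesize_recording(1, p, duration_s = duration_s)
  rec$mixed <- mix(rec$eeg, rec$emg, rec$mask, snr_db)
  rec$emg_gain <- attr(rec$mixed, "emg_gain")
  rec
}

# mean/min intersection-over-union of detected vs true burst intervals
interval_iou <- function(detected, truth) {
  di <- mask_intervals(detected)
  ti <- mask_intervals(truth)
  iou <- vapply(seq_len(nrow(ti)), function(i) {
    a0 <- ti$start_sample[i]; a1 <- ti$end_sample[i]
    best <- 0
    for (j in seq_len(nrow(di))) {
      b0 <- di$start_sample[j]; b1 <- di$end_sample[j]
      inter <- max(0L, min(a1, b1) - max(a0, b0))
      union <- (a1 - a0) + (b1 - b0) - inter
      best <- max(best, inter / union)
    }
    best
  }, numeric(1))
  list(n_detected = nrow(di), n_true = nrow(ti),
       mean_iou = mean(iou), min_iou = min(iou))
}

# variance of x restricted to a frequency band (periodogram mass)
band_power <- function(x, fs, low, high) {
  n <- length(x)
  X <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  sum(X[f >= low & f <= high]) / n
}

rel_err <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))
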