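#' Moving-RMS energy envelope
#'
#' Centered moving root-mean-square of the signal with a rectangular window,
#' the energy estimator driving burst detection. Edges use the partial
#' window (shrinking support), so the output length equals the input length.
#'
#' @param x A [time_series()] or numeric vector.
#' @param window_ms Window length in milliseconds (default 100).
#' @param fs Sampling rate when `x` is a bare vector.
#' @return A nonnegative [time_series()].
#' @export
energy_envelope <- function(x, window_ms = 100, fs = NULL) {
  s <- as_signal(x, fs)
  n <- length(s$samples)
  w <- max(1L, round(window_ms / 1000 * s$fs))
  if (w > n) stop("window longer than signal", call. = FALSE)
  # centered running mean of x^2 via cumulative sums, partial at the edges
  cs <- cumsum(c(0, s$samples^2))
  half <- w %/% 2L
  i <- seq_len(n)
  a <- pmax(i - half, 1L)
  b <- pmin(i - half + w - 1L, n)
  env <- sqrt((cs[b + 1L] - cs[a]) / (b - a + 1L))
  time_series(env, s$fs)
}

#' Detect EMG bursts and build the contamination mask
#'
#' Automatic burst detection: the input is detrended (linear + non-linear),
#' decomposed by EMD, each component is soft-thresholded with thresholds
#' estimated from a known noise-only window, the shrunk components are
#' summed, and the moving-RMS energy envelope of the result is binarized at
#' `mean + c_sd * SD` of the envelope over the noise window. Morphological
#' cleanup then drops high runs shorter than `min_duration_ms` and merges
#' high runs separated by gaps shorter than `merge_gap_ms`.
#'
#' Because the moving-RMS window smears any above-threshold instant to
#' roughly the window length, `min_duration_ms` must comfortably exceed
#' `envelope_window_ms`; the default (250 ms) is 2.5 times the envelope
#' window while staying at half the shortest burst the contraction protocol
#' produces (500 ms).
#'
#' Preferably run on a simultaneously recorded EMG channel; the same
#' procedure works directly on EMG-corrupted EEG.
#'
#' @param x A [time_series()] or numeric vector.
#' @param noise_window `c(start_s, end_s)`: an interval known to contain
#'   only baseline activity (>= 0.1 s).
#' @param k Soft-threshold multiplier (default 1.5).
#' @param envelope_window_ms Moving-RMS window (default 100 ms).
#' @param c_sd Binarization constant: threshold = noise mean + `c_sd` * noise
#'   SD of the envelope (default 3).
#' @param min_duration_ms Shortest retained burst (default 250 ms).
#' @param merge_gap_ms Longest gap merged between bursts (default 200 ms).
#' @param detrend_window_ms Non-linear detrend window (default 20 ms).
#' @param max_imf IMF cap for the EMD stage (default 10).
#' @param fs Sampling rate when `x` is a bare vector.
#' @return An [contamination_mask()] with attribute `envelope` (the
#'   post-filtering energy envelope) and `threshold`.
#' @export
detect_emg_bursts <- function(x, noise_window, k = 1.5,
                              envelope_window_ms = 100, c_sd = 3,
                              min_duration_ms = 250, merge_gap_ms = 200,
                              detrend_window_ms = 20, max_imf = 10,
                              fs = NULL) {
  s <- as_signal(x, fs)
  n <- length(s$samples)
  if (length(noise_window) != 2L || diff(noise_window) < 0.1)
    stop("'noise_window' must be an interval of at least 0.1 s",
         call. = FALSE)
  a <- max(1L, floor(noise_window[1] * s$fs) + 1L)
  b <- min(n, ceiling(noise_window[2] * s$fs))
  if (b <= a) stop("'noise_window' lies outside the record", call. = FALSE)

  y <- remove_linear_trend(s$samples, fs = s$fs)
  y <- remove_nonlinear_trend(y, window_ms = detrend_window_ms)
  cs <- emd(y, max_imf = max_imf)

  # thresholds from the noise window only
  nm <- rep(TRUE, n)
  nm[a:b] <- FALSE           # mask-low == the declared noise window
  noise_mask <- contamination_mask(nm, s$fs)
  tv <- estimate_thresholds(cs, noise_mask, k = k)
  comps <- all_components(cs)
  filt <- numeric(n)
  for (m in seq_along(comps))
    filt <- filt + soft_threshold(comps[[m]], tv$t[m])

  env <- energy_envelope(filt, window_ms = envelope_window_ms, fs = s$fs)
  ref <- env$samples[a:b]
  thr <- mean(ref) + c_sd * stats::sd(ref)
  flags <- env$samples > thr

  flags <- drop_short_runs(flags, round(min_duration_ms / 1000 * s$fs))
  flags <- merge_short_gaps(flags, round(merge_gap_ms / 1000 * s$fs))

  out <- contamination_mask(flags, s$fs)
  attr(out, "envelope") <- env
  attr(out, "threshold") <- thr
  out
}

# set low runs shorter than max_gap (strictly interior) high
merge_short_gaps <- function(flags, max_gap) {
  if (!any(flags) || max_gap < 1L) return(flags)
  r <- rle(flags)
  nr <- length(r$values)
  for (i in seq_len(nr)) {
    if (!r$values[i] && i > 1L && i < nr && r$lengths[i] < max_gap)
      r$values[i] <- TRUE
  }
  inverse.rle(r)
}

# drop high runs shorter than min_len
drop_short_runs <- function(flags, min_len) {
  if (!any(flags) || min_len < 1L) return(flags)
  r <- rle(flags)
  r$values[r$values & r$lengths < min_len] <- FALSE
  inverse.rle(r)
}
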