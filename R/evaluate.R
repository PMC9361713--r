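#' Median windowed RMS over a masked region
#'
#' Concatenates the samples of the selected region (noise = mask-low, emg =
#' mask-high) in time order, tiles them with non-overlapping windows of
#' `window_s` seconds (default 1 s, i.e. `fs` samples), computes the RMS of
#' each full window, and returns the median of the window RMS values. A
#' trailing partial window is discarded.
#'
#' @param x A [time_series()] or numeric vector.
#' @param mask An [contamination_mask()] of the same length.
#' @param region `"noise"` (mask-low) or `"emg"` (mask-high).
#' @param window_s Window length in seconds (default 1).
#' @param fs Sampling rate when `x` is a bare vector.
#' @return Scalar: median windowed RMS in microvolts.
#' @export
region_rms_median <- function(x, mask, region = c("noise", "emg"),
                              window_s = 1, fs = NULL) {
  s <- as_signal(x, fs)
  region <- match.arg(region)
  stopifnot(inherits(mask, "emg_mask"))
  if (length(mask) != length(s$samples))
    stop("mask length differs from signal length", call. = FALSE)
  sel <- if (region == "emg") mask$flags else !mask$flags
  v <- s$samples[sel]
  w <- round(window_s * s$fs)
  nwin <- floor(length(v) / w)
  if (nwin < 1L)
    stop("region '", region, "' is shorter than one ", window_s,
         " s window", call. = FALSE)
  v <- v[seq_len(nwin * w)]
  rms <- sqrt(colMeans(matrix(v^2, nrow = w)))
  stats::median(rms)
}

#' Time-domain filtering features GL, GH, GXin, GXout
#'
#' Windowed-RMS gain features comparing an unfiltered signal `xin` and a
#' filtered signal `xout` over the noise-only and EMG-contaminated regions
#' of a contamination mask. With `Xin0'`, `Xin1'`, `Xout0'`, `Xout1'` the
#' median windowed RMS of the input/output in the noise (0) and EMG (1)
#' regions:
#' \deqn{GL = 20 \log_{10}(Xout_0'/Xin_0'), \quad
#'       GH = 20 \log_{10}(Xout_1'/Xin_1')}
#' \deqn{GXin = 20 \log_{10}(Xin_1'/Xin_0'), \quad
#'       GXout = 20 \log_{10}(Xout_1'/Xout_0')}
#' GL measures how much the filter alters clean-EEG regions (ideally 0 dB),
#' GH how much it attenuates contaminated regions (negative is attenuation),
#' GXin/GXout the in/out contamination contrast before/after filtering.
#'
#' @param xin,xout [time_series()] objects (or numeric with `fs`) of equal
#'   length: signal before and after filtering.
#' @param mask An [contamination_mask()].
#' @param window_s RMS window in seconds (default 1).
#' @param fs Sampling rate when inputs are bare vectors.
#' @return Object of class `time_features`: list with `GL`, `GH`, `GXin`,
#'   `GXout` (dB), `window_s`, and `medians` (the four region medians).
#' @export
time_features <- function(xin, xout, mask, window_s = 1, fs = NULL) {
  a <- as_signal(xin, fs)
  b <- as_signal(xout, fs)
  if (length(a$samples) != length(b$samples))
    stop("'xin' and 'xout' lengths differ", call. = FALSE)
  xin0 <- region_rms_median(a$samples, mask, "noise", window_s, fs = a$fs)
  xin1 <- region_rms_median(a$samples, mask, "emg", window_s, fs = a$fs)
  xout0 <- region_rms_median(b$samples, mask, "noise", window_s, fs = b$fs)
  xout1 <- region_rms_median(b$samples, mask, "emg", window_s, fs = b$fs)
  structure(list(GL = 20 * log10(xout0 / xin0),
                 GH = 20 * log10(xout1 / xin1),
                 GXin = 20 * log10(xin1 / xin0),
                 GXout = 20 * log10(xout1 / xout0),
                 window_s = window_s,
                 medians = c(Xin0 = xin0, Xin1 = xin1,
                             Xout0 = xout0, Xout1 = xout1)),
            class = "time_features")
}

#' @export
print.time_features <- function(x, ...) {
  cat(sprintf("<time_features> GL %.2f dB, GH %.2f dB, GXin %.2f dB, GXout %.2f dB\n",
              x$GL, x$GH, x$GXin, x$GXout))
  invisible(x)
}

#' GL/GH curves over the soft-threshold multiplier k
#'
#' Sweeps the soft-threshold multiplier over `k_grid` (default 0.1 to 2.0 in
#' steps of 0.1). For each k the EMG reference is rebuilt from the same
#' decomposition and GL/GH are computed with the raw signal as input and the
#' reference as output. The decomposition is computed once and reused
#' across the sweep.
#'
#' @param x A [time_series()] or numeric vector (contaminated signal).
#' @param method Decomposition method (see [decompose()]), or a ready
#'   [component_set()].
#' @param mask An [contamination_mask()].
#' @param k_grid Strictly increasing multipliers (default
#'   `seq(0.1, 2, by = 0.1)`).
#' @param window_s RMS window in seconds (default 1).
#' @param ... Extra arguments for [decompose()].
#' @param fs Sampling rate when `x` is a bare vector.
#' @return Object of class `feature_curve`: list with `k`, `GL`, `GH`.
#' @export
feature_curve <- function(x, method, mask, k_grid = seq(0.1, 2, by = 0.1),
                          window_s = 1, ..., fs = NULL) {
  s <- as_signal(x, fs)
  if (is.unsorted(k_grid, strictly = TRUE))
    stop("'k_grid' must be strictly increasing", call. = FALSE)
  cs <- if (inherits(method, "component_set")) method else
    decompose(s$samples, method, ..., fs = s$fs)
  GL <- GH <- numeric(length(k_grid))
  for (i in seq_along(k_grid)) {
    ref <- make_emg_reference(s$samples, cs, mask, k = k_grid[i], fs = s$fs)
    tf <- time_features(s$samples, ref$samples, mask, window_s, fs = s$fs)
    GL[i] <- tf$GL
    GH[i] <- tf$GH
  }
  structure(list(k = k_grid, GL = GL, GH = GH, method = cs$method),
            class = "feature_curve")
}

#' @export
print.feature_curve <- function(x, ...) {
  cat(sprintf("<feature_curve> %s, k in [%g, %g] (%d points)\n",
              x$method, min(x$k), max(x$k), length(x$k)))
  cat(sprintf("  GL: %.2f .. %.2f dB; GH: %.2f .. %.2f dB\n",
              x$GL[1], x$GL[length(x$GL)], x$GH[1], x$GH[length(x$GH)]))
  invisible(x)
}

#' Normalized Euclidean distance between feature vectors
#'
#' `d(u, v) = ||u - v|| / (||u|| + ||v||)`: 0 iff the vectors coincide, at
#' most 1 (attained for anti-parallel vectors), symmetric. Applied to the
#' GL and GH curves of a k-sweep it quantifies EMG contamination: the
#' farther apart the curves, the stronger the contamination.
#'
#' @param u,v Equal-length numeric vectors, or two [feature_curve()] objects
#'   (then the distance between their GL and GH curves is returned).
#' @return Scalar in `[0, 1]`; two zero vectors give 0.
#' @examples
#' normalized_distance(c(3, 0), c(0, 4))  # 5/7
#' @export
normalized_distance <- function(u, v = NULL) {
  if (inherits(u, "feature_curve") && is.null(v)) {
    v <- u$GH
    u <- u$GL
  }
  u <- as.numeric(u)
  v <- as.numeric(v)
  if (length(u) != length(v)) stop("lengths differ", call. = FALSE)
  den <- sqrt(sum(u^2)) + sqrt(sum(v^2))
  if (den == 0) return(0)
  sqrt(sum((u - v)^2)) / den
}

#' Yule-Walker autoregressive spectrum
#'
#' Fits an AR model of the given order by the Yule-Walker method
#' (autocorrelation + Levinson-Durbin) and evaluates the one-sided power
#' spectral density on the grid `f = 0, df, 2*df, ..., fs/2`:
#' \deqn{pxx(f) = s \cdot \sigma^2 / (f_s |A(e^{-2\pi i f/f_s})|^2)}
#' with `s = 2` except at DC and Nyquist, so that the grid sum times `df`
#' approximates the signal variance.
#'
#' @param x A [time_series()] or numeric vector.
#' @param order AR model order (default 10).
#' @param df Grid step in Hz (default 0.01; use a coarser grid for long
#'   records if only the median frequency is needed).
#' @param fs Sampling rate when `x` is a bare vector.
#' @return Object of class `ar_spectrum`: list with `f`, `pxx`, `order`,
#'   `ar` (coefficients), `sigma2`, `fs`.
#' @export
ar_spectrum <- function(x, order = 10, df = 0.01, fs = NULL) {
  s <- as_signal(x, fs)
  n <- length(s$samples)
  if (n <= 2L * order)
    stop("signal too short for AR order ", order, call. = FALSE)
  if (stats::sd(s$samples) == 0)
    stop("constant signal: autocorrelation is singular", call. = FALSE)
  fit <- stats::ar.yw(s$samples, aic = FALSE, order.max = order,
                      demean = TRUE)
  a <- fit$ar
  sigma2 <- fit$var.pred
  f <- seq(0, s$fs / 2, by = df)
  # |A|^2 on the grid via the transfer polynomial 1 - sum a_k z^-k
  z <- exp(-2i * pi * outer(f / s$fs, seq_along(a)))
  A <- 1 - as.vector(z %*% a)
  scale <- rep(2, length(f))
  scale[f == 0 | f == s$fs / 2] <- 1
  pxx <- scale * sigma2 / (s$fs * Mod(A)^2)
  structure(list(f = f, pxx = pxx, order = order, ar = a, sigma2 = sigma2,
                 fs = s$fs),
            class = "ar_spectrum")
}

#' @export
print.ar_spectrum <- function(x, ...) {
  cat(sprintf("<ar_spectrum> AR(%d), %d grid points up to %g Hz; peak at %.3f Hz\n",
              x$order, length(x$f), max(x$f), x$f[which.max(x$pxx)]))
  invisible(x)
}

#' Median frequency of a power spectrum
#'
#' Smallest grid frequency at which the cumulative spectral mass reaches
#' half of the total, together with the PSD value there.
#'
#' @param sf An [ar_spectrum()] object, or a list with elements `f` and
#'   `pxx`.
#' @return List with `fmed` (Hz) and `p_at_fmed`.
#' @export
median_frequency <- function(sf) {
  f <- sf$f
  pxx <- sf$pxx
  if (length(f) != length(pxx)) stop("f/pxx length mismatch", call. = FALSE)
  tot <- sum(pxx)
  if (!is.finite(tot) || tot <= 0)
    stop("spectrum has no positive mass", call. = FALSE)
  i <- which(cumsum(pxx) >= tot / 2)[1]
  list(fmed = f[i], p_at_fmed = pxx[i])
}

#' Per-band spectral features
#'
#' Splits the signal into the five canonical EEG rhythm bands — Delta
#' (0.5-4 Hz), Theta (4-7), Alpha (7-13), Beta (13-30), Gamma (30-70) —
#' with a zero-phase brick-wall band-pass, then computes the Yule-Walker
#' spectrum and median frequency for the full signal and for each band.
#'
#' @param x A [time_series()] or numeric vector (`fs/2` must exceed 70 Hz).
#' @param order AR order (default 10).
#' @param df Spectral grid step in Hz (default 0.01).
#' @param fs Sampling rate when `x` is a bare vector.
#' @return Data frame with one row per band (plus `full`): columns `band`,
#'   `fmed`, `p_at_fmed`, `power` (band variance).
#' @export
band_features <- function(x, order = 10, df = 0.01, fs = NULL) {
  s <- as_signal(x, fs)
  if (s$fs / 2 <= 70)
    stop("sampling rate too low: need fs/2 > 70 Hz for the gamma band",
         call. = FALSE)
  bands <- eeg_bands()
  rows <- vector("list", length(bands) + 1L)
  sp <- ar_spectrum(s$samples, order, df, fs = s$fs)
  mf <- median_frequency(sp)
  rows[[1]] <- data.frame(band = "full", fmed = mf$fmed,
                          p_at_fmed = mf$p_at_fmed,
                          power = stats::var(s$samples))
  for (i in seq_along(bands)) {
    y <- fft_bandpass(s$samples, s$fs, bands[[i]][1], bands[[i]][2])
    row <- tryCatch({
      spb <- ar_spectrum(y, order, df, fs = s$fs)
      mfb <- median_frequency(spb)
      data.frame(band = names(bands)[i], fmed = mfb$fmed,
                 p_at_fmed = mfb$p_at_fmed, power = stats::var(y))
    }, error = function(e) {
      data.frame(band = names(bands)[i], fmed = NA_real_,
                 p_at_fmed = NA_real_, power = stats::var(y))
    })
    rows[[i + 1L]] <- row
  }
  do.call(rbind, rows)
}
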