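#' Remove the linear trend from a signal
#'
#' Fits a least-squares straight line to the samples as a function of time
#' and subtracts it, so the output has zero mean and zero least-squares
#' slope. Electrode-impedance drift and slow cable/skin motion show up as
#' such trends.
#'
#' @param x A [time_series()] or numeric vector.
#' @param fs Sampling rate, required when `x` is a bare vector.
#' @return A [time_series()] of the same length.
#' @export
remove_linear_trend <- function(x, fs = NULL) {
  s <- as_signal(x, fs)
  n <- length(s$samples)
  if (n < 2L) stop("need at least 2 samples to fit a line", call. = FALSE)
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), s$samples)
  time_series(unname(fit$residuals), s$fs)
}

#' Estimate the non-linear trend of a signal
#'
#' Tiles the record with non-overlapping rectangular windows (default 20 ms:
#' 100 samples at 5 kHz), takes the median of each window, and interpolates
#' the (window-center, median) points back to every sample with a monotone
#' piecewise cubic Hermite polynomial (pchip). A trailing partial window is
#' treated as its own window; the first/last medians are held constant
#' beyond the outermost window centers.
#'
#' @param x A [time_series()] or numeric vector.
#' @param window_ms Window length in milliseconds (default 20).
#' @param fs Sampling rate, required when `x` is a bare vector.
#' @return A [time_series()]: the trend, same length as the input.
#' @export
estimate_nonlinear_trend <- function(x, window_ms = 20, fs = NULL) {
  s <- as_signal(x, fs)
  n <- length(s$samples)
  w <- max(1L, round(window_ms / 1000 * s$fs))
  if (w > n)
    stop("window (", w, " samples) longer than signal (", n, ")",
         call. = FALSE)
  starts <- seq.int(1L, n, by = w)
  ends <- pmin(starts + w - 1L, n)
  med <- vapply(seq_along(starts),
                function(i) stats::median(s$samples[starts[i]:ends[i]]),
                numeric(1))
  centers <- (starts + ends) / 2
  if (length(med) == 1L) return(time_series(rep(med, n), s$fs))
  # constant extension to the record edges avoids end extrapolation
  xi <- c(1, centers, n)
  yi <- c(med[1], med, med[length(med)])
  keep <- !duplicated(xi)
  trend <- pracma::pchip(xi[keep], yi[keep], seq_len(n))
  time_series(trend, s$fs)
}

#' Remove the non-linear trend from a signal
#'
#' Subtracts [estimate_nonlinear_trend()] from the signal.
#'
#' @inheritParams estimate_nonlinear_trend
#' @return A [time_series()] of the same length.
#' @export
remove_nonlinear_trend <- function(x, window_ms = 20, fs = NULL) {
  s <- as_signal(x, fs)
  tr <- estimate_nonlinear_trend(s$samples, window_ms, fs = s$fs)
  time_series(s$samples - tr$samples, s$fs)
}

#' Replace amplitude outliers
#'
#' Upper/lower thresholds are the mean plus/minus `k_sd` (default 10) times
#' the standard deviation of the samples inside the EMG-contaminated
#' (mask-high) region. Samples anywhere in the record that fall outside
#' `[mean - k_sd*SD, mean + k_sd*SD]` are replaced by draws from the standard
#' normal distribution; all other samples are returned bit-identically.
#'
#' Note the replacement draws are unit-normal in the literal sense — they are
#' not rescaled to the signal's microvolt level.
#'
#' @param x A [time_series()] or numeric vector.
#' @param mask An [contamination_mask()] of the same length (its high region
#'   defines the threshold statistics).
#' @param k_sd Threshold width in standard deviations (default 10).
#' @param seed Integer seed for the replacement draws, or `NULL`.
#' @param fs Sampling rate when `x` is a bare vector.
#' @return A [time_series()] with attribute `n_replaced`.
#' @export
replace_outliers <- function(x, mask, k_sd = 10, seed = NULL, fs = NULL) {
  s <- as_signal(x, fs)
  stopifnot(inherits(mask, "emg_mask"))
  if (length(mask) != length(s$samples))
    stop("mask length differs from signal length", call. = FALSE)
  hi <- mask$flags
  if (sum(hi) < 2L)
    stop("mask must flag at least 2 contaminated samples", call. = FALSE)
  m <- mean(s$samples[hi])
  sd_ <- stats::sd(s$samples[hi])
  lo_thr <- m - k_sd * sd_
  hi_thr <- m + k_sd * sd_
  bad <- s$samples < lo_thr | s$samples > hi_thr
  out <- s$samples
  if (any(bad))
    out[bad] <- with_seed(seed, stats::rnorm(sum(bad)))
  res <- time_series(out, s$fs)
  attr(res, "n_replaced") <- sum(bad)
  res
}
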