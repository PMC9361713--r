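#' Per-component soft thresholds from noise-region statistics
#'
#' For each component, the threshold is `k` times the standard deviation of
#' the component over the noise (mask-low) samples. By default all mask-low
#' samples are pooled; `noise_window` restricts the statistics to one
#' interval (in seconds) for strict single-window usage.
#'
#' @param cs A [component_set()].
#' @param mask An [contamination_mask()] for the decomposed record (low =
#'   noise-only samples).
#' @param k Threshold multiplier (default 1.5, the typical value).
#' @param noise_window Optional `c(start_s, end_s)` restricting the noise
#'   statistics to one window; samples used are the mask-low samples inside
#'   it.
#' @return An object of class `threshold_vector`: list with `t` (one
#'   nonnegative threshold per component, residual included for
#'   EMD-family sets), `k` and `n_noise`.
#' @export
estimate_thresholds <- function(cs, mask, k = 1.5, noise_window = NULL) {
  stopifnot(inherits(cs, "component_set"), inherits(mask, "emg_mask"))
  if (length(mask) != cs$n)
    stop("mask length differs from component length", call. = FALSE)
  if (k < 0) stop("'k' must be nonnegative", call. = FALSE)
  lo <- !mask$flags
  if (!is.null(noise_window)) {
    sel <- logical(cs$n)
    a <- max(1L, floor(noise_window[1] * cs$fs) + 1L)
    b <- min(cs$n, ceiling(noise_window[2] * cs$fs))
    if (b >= a) sel[a:b] <- TRUE
    lo <- lo & sel
  }
  if (sum(lo) < 2L)
    stop("need at least 2 noise (mask-low) samples for threshold statistics",
         call. = FALSE)
  t <- vapply(all_components(cs), function(c) k * stats::sd(c[lo]), numeric(1))
  structure(list(t = t, k = k, n_noise = sum(lo)),
            class = "threshold_vector")
}

#' @export
print.threshold_vector <- function(x, ...) {
  cat(sprintf("<threshold_vector> k = %g over %d noise samples\n",
              x$k, x$n_noise))
  cat("  t:", paste(sprintf("%.4g", x$t), collapse = " "), "\n")
  invisible(x)
}

#' Soft-threshold (shrink) a component
#'
#' Elementwise shrinkage `sign(c) * max(|c| - t, 0)`: values within the
#' threshold band are zeroed, the rest move toward zero by `t`.
#'
#' @param c_m Numeric vector (one decomposition component).
#' @param t_m Nonnegative scalar threshold.
#' @return Numeric vector of the same length.
#' @examples
#' soft_threshold(c(2, -2, 0.3), 0.5)   # 1.5 -1.5 0.0
#' @export
soft_threshold <- function(c_m, t_m) {
  if (!is.numeric(t_m) || length(t_m) != 1L || is.na(t_m) || t_m < 0)
    stop("'t_m' must be a nonnegative scalar", call. = FALSE)
  sign(c_m) * pmax(abs(c_m) - t_m, 0)
}

#' Build the EMG reference signal
#'
#' Decomposes the contaminated signal, soft-thresholds every component
#' against the noise-region statistics (thresholds `k * SD` over mask-low
#' samples) and sums the shrunk components. In noise-only regions the
#' components rarely exceed their thresholds, so the reference retains
#' mostly the high-amplitude EMG bursts. For method `"EMD_PCA"` the
#' soft-thresholding stage is skipped: the reference is the reduced-rank
#' principal-axis reconstruction itself.
#'
#' @param x A [time_series()] or numeric vector (the contaminated signal).
#' @param method Decomposition method (see [decompose()]), or a ready-made
#'   [component_set()] to skip re-decomposition.
#' @param mask An [contamination_mask()] (low = noise-only samples).
#' @param k Soft-threshold multiplier (default 1.5).
#' @param ... Extra parameters for [decompose()].
#' @param fs Sampling rate when `x` is a bare vector.
#' @return A [time_series()] with attribute `thresholds` (the
#'   `threshold_vector`, or `NULL` for EMD-PCA).
#' @export
make_emg_reference <- function(x, method, mask, k = 1.5, ..., fs = NULL) {
  cs <- if (inherits(method, "component_set")) method else
    decompose(x, method, ..., fs = fs)
  if (identical(cs$method, "EMD_PCA")) {
    out <- reconstruct(cs)
    attr(out, "thresholds") <- NULL
    return(out)
  }
  tv <- estimate_thresholds(cs, mask, k = k)
  comps <- all_components(cs)
  acc <- numeric(cs$n)
  for (m in seq_along(comps))
    acc <- acc + soft_threshold(comps[[m]], tv$t[m])
  out <- time_series(acc, cs$fs)
  attr(out, "thresholds") <- tv
  out
}

#' Build the EEG reference signal
#'
#' The EEG reference is the contaminated signal minus the EMG reference, so
#' the two references always add back to the contaminated record exactly.
#' (The difference is oriented to give the EEG reference EEG polarity; the
#' sign is immaterial to the quadratic adaptive filters.)
#'
#' @param contaminated,emg_ref [time_series()] objects (or numeric vectors
#'   with `fs`) of equal length.
#' @param fs Sampling rate when inputs are bare vectors.
#' @return A [time_series()].
#' @export
make_eeg_reference <- function(contaminated, emg_ref, fs = NULL) {
  a <- as_signal(contaminated, fs)
  b <- as_signal(emg_ref, fs)
  if (length(a$samples) != length(b$samples))
    stop("signal lengths differ", call. = FALSE)
  time_series(a$samples - b$samples, a$fs)
}
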