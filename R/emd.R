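# Empirical mode decomposition by sifting, with monotone piecewise-cubic
# (pchip) envelopes of the local extrema — the interpolant used throughout
# the package's preprocessing as well.

# indices of strict local maxima/minima; plateaus collapse to their first
# sample by carrying the previous slope sign through zero differences
local_extrema <- function(h) {
  d <- diff(h)
  s <- sign(d)
  z <- which(s == 0)
  if (length(z)) {
    for (i in z) s[i] <- if (i > 1) s[i - 1] else 0
  }
  chg <- diff(s)
  list(max = which(chg < 0) + 1L,
       min = which(chg > 0) + 1L)
}

# mean of the upper/lower pchip envelopes; endpoints anchored on the signal
envelope_mean <- function(h) {
  n <- length(h)
  ex <- local_extrema(h)
  if (length(ex$max) < 2L || length(ex$min) < 2L) return(NULL)
  xi_u <- c(1L, ex$max, n)
  xi_l <- c(1L, ex$min, n)
  up <- pracma::pchip(xi_u, h[xi_u], seq_len(n))
  lo <- pracma::pchip(xi_l, h[xi_l], seq_len(n))
  (up + lo) / 2
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by sifting:
#' repeated subtraction of the mean of the pchip-interpolated extrema
#' envelopes until the normalized squared change between consecutive sifts
#' drops below `sd_thresh` (Huang's standard-deviation criterion), then
#' extraction of the next IMF from the residue. Extraction stops at
#' `max_imf` IMFs or when the residue has fewer than two maxima or minima.
#'
#' @param x A [time_series()] or numeric vector.
#' @param max_imf Maximum number of IMFs (default 10).
#' @param sd_thresh Sifting stop criterion (default 0.2).
#' @param max_sift Maximum sifts per IMF (default 100).
#' @param fs Sampling rate when `x` is a bare vector.
#' @return A [component_set()] with the IMFs as components and the final
#'   residue stored separately; IMFs plus residue sum to the input exactly.
#' @export
emd <- function(x, max_imf = 10, sd_thresh = 0.2, max_sift = 100, fs = NULL) {
  s <- as_signal(x, fs)
  resid <- s$samples
  imfs <- list()
  while (length(imfs) < max_imf) {
    h <- resid
    for (it in seq_len(max_sift)) {
      m <- envelope_mean(h)
      if (is.null(m)) break
      h_new <- h - m
      num <- sum((h - h_new)^2)
      den <- sum(h^2)
      h <- h_new
      if (den == 0 || num / den < sd_thresh) break
    }
    ex <- local_extrema(h)
    if (length(ex$max) < 2L || length(ex$min) < 2L) break  # residue is a trend
    imfs[[length(imfs) + 1L]] <- h
    resid <- resid - h
    exr <- local_extrema(resid)
    if (length(exr$max) < 2L || length(exr$min) < 2L) break
  }
  if (!length(imfs)) {
    # monotone-ish input: the whole signal is the residue; expose it as the
    # single component so downstream stages always have one
    imfs <- list(resid)
    resid <- numeric(length(resid))
  }
  component_set(imfs, residual = resid, method = "EMD",
                params = list(max_imf = max_imf, sd_thresh = sd_thresh,
                              max_sift = max_sift),
                fs = s$fs)
}

#' Ensemble empirical mode decomposition
#'
#' Averages the IMFs of `n_ensembles` EMD runs on noise-perturbed copies of
#' the signal (added white noise with standard deviation
#' `noise_sd_frac * sd(x)`), which stabilizes mode mixing. Members producing
#' fewer IMFs than the ensemble maximum are zero-padded before averaging.
#' The averaged IMFs do not sum exactly to the input (the ensemble average
#' of the added noise survives at `O(noise/sqrt(n_ensembles))`).
#'
#' @inheritParams emd
#' @param n_ensembles Ensemble size (default 5).
#' @param noise_sd_frac Added-noise SD as a fraction of the signal SD
#'   (default 0.2).
#' @param seed Integer seed for the ensemble noise, or `NULL`.
#' @return A [component_set()] (method `"EEMD"`); the stored residual is the
#'   ensemble mean of the member residues.
#' @export
eemd <- function(x, n_ensembles = 5, noise_sd_frac = 0.2, max_imf = 10,
                 sd_thresh = 0.2, max_sift = 100, seed = NULL, fs = NULL) {
  s <- as_signal(x, fs)
  n <- length(s$samples)
  amp <- noise_sd_frac * stats::sd(s$samples)
  runs <- with_seed(seed, {
    lapply(seq_len(n_ensembles), function(i) {
      emd(s$samples + stats::rnorm(n, sd = amp), max_imf = max_imf,
          sd_thresh = sd_thresh, max_sift = max_sift, fs = s$fs)
    })
  })
  m_max <- max(vapply(runs, function(r) length(r$components), integer(1)))
  comps <- lapply(seq_len(m_max), function(j) {
    acc <- numeric(n)
    for (r in runs)
      if (j <= length(r$components)) acc <- acc + r$components[[j]]
    acc / n_ensembles
  })
  resid <- Reduce(`+`, lapply(runs, function(r) r$residual)) / n_ensembles
  component_set(comps, residual = resid, method = "EEMD",
                params = list(n_ensembles = n_ensembles,
                              noise_sd_frac = noise_sd_frac,
                              max_imf = max_imf, sd_thresh = sd_thresh,
                              max_sift = max_sift, seed = seed),
                fs = s$fs)
}

#' EMD with principal-axis reduction
#'
#' Runs [emd()], stacks IMFs plus residue as the columns of a component
#' matrix, rotates to uncentered principal axes (SVD), and keeps the leading
#' axes accounting for at least `var_target` (default 80%) of the total
#' component energy. Each returned component is the signal-level
#' contribution of one retained axis; their sum is the reduced-rank
#' reconstruction used directly as the EMG reference (no soft-thresholding
#' stage is needed for this method).
#'
#' @inheritParams emd
#' @param var_target Fraction of component-matrix energy to retain
#'   (default 0.8).
#' @return A [component_set()] (method `"EMD_PCA"`) with per-axis explained
#'   variance fractions; reconstruction is intentionally lossy.
#' @export
emd_pca <- function(x, var_target = 0.8, max_imf = 10, sd_thresh = 0.2,
                    max_sift = 100, fs = NULL) {
  s <- as_signal(x, fs)
  base <- emd(s$samples, max_imf = max_imf, sd_thresh = sd_thresh,
              max_sift = max_sift, fs = s$fs)
  C <- do.call(cbind, c(base$components, list(base$residual)))
  sv <- svd(C)
  shares <- sv$d^2 / sum(sv$d^2)
  r <- which(cumsum(shares) >= var_target)[1]
  if (is.na(r)) r <- length(shares)
  comps <- lapply(seq_len(r), function(j) {
    sv$d[j] * sum(sv$v[, j]) * sv$u[, j]
  })
  component_set(comps, residual = NULL, method = "EMD_PCA",
                params = list(var_target = var_target, max_imf = max_imf,
                              sd_thresh = sd_thresh, max_sift = max_sift),
                fs = s$fs, explained_variance = shares[seq_len(r)])
}
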