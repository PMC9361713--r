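# Singular spectrum analysis and its circulant variant. Both embed the
# series into an L x K trajectory matrix; reconstruction of any rank-one
# piece uses diagonal (anti-diagonal) averaging, computed here in
# O(n log n) via convolution.

# trajectory (Hankel) matrix, rows are lagged copies
trajectory_matrix <- function(x, L) {
  n <- length(x)
  K <- n - L + 1L
  X <- matrix(0, L, K)
  for (i in seq_len(L)) X[i, ] <- x[i:(i + K - 1L)]
  X
}

# diagonal-average the rank-one matrix u w^T (L x K) back to a length-n
# series: anti-diagonal sums are the full linear convolution of u and w
diag_average <- function(u, w, counts = NULL) {
  z <- stats::convolve(u, rev(w), type = "open")
  if (is.null(counts))
    counts <- stats::convolve(rep(1, length(u)), rep(1, length(w)),
                              type = "open")
  z / counts
}

diag_counts <- function(L, K) {
  stats::convolve(rep(1, L), rep(1, K), type = "open")
}

#' Singular spectrum analysis
#'
#' Embeds the signal into an `L`-row trajectory matrix, eigendecomposes
#' `X X^T`, and reconstructs one component per leading eigentriple (diagonal
#' averaging), keeping eigentriples in descending eigenvalue order until the
#' cumulative explained variance reaches `var_target` (default 80%). The
#' unexplained remainder is returned as a final residual component so the
#' component set always sums exactly to the input.
#'
#' @param x A [time_series()] or numeric vector.
#' @param L Window (embedding) length (default 100); must be < `length(x)`.
#' @param var_target Cumulative eigenvalue share at which grouping stops
#'   (default 0.8). Use 1 to retain every eigentriple.
#' @param max_components Cap on the number of retained eigentriples
#'   (default `L`, i.e. no cap beyond the embedding rank).
#' @param fs Sampling rate when `x` is a bare vector.
#' @return A [component_set()] (method `"SSA"`): retained eigentriple
#'   reconstructions followed by the remainder component; explained-variance
#'   fractions are the eigenvalue shares (remainder share last).
#' @export
ssa <- function(x, L = 100, var_target = 0.8, max_components = L, fs = NULL) {
  s <- as_signal(x, fs)
  n <- length(s$samples)
  if (L >= n) stop("window length L must be smaller than the signal length",
                   call. = FALSE)
  if (L < 2L) stop("window length L must be at least 2", call. = FALSE)
  X <- trajectory_matrix(s$samples, L)
  K <- ncol(X)
  e <- eigen(tcrossprod(X), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  shares <- ev / sum(ev)
  m <- which(cumsum(shares) >= var_target)[1]
  if (is.na(m)) m <- L
  m <- min(m, max_components, L)
  counts <- diag_counts(L, K)
  comps <- vector("list", m)
  for (j in seq_len(m)) {
    u <- e$vectors[, j]
    w <- drop(crossprod(X, u))            # sigma_j * v_j
    comps[[j]] <- diag_average(u, w, counts)
  }
  total <- Reduce(`+`, comps)
  remainder <- s$samples - total
  component_set(c(comps, list(remainder)), residual = NULL, method = "SSA",
                params = list(L = L, var_target = var_target,
                              max_components = max_components),
                fs = s$fs,
                explained_variance = c(shares[seq_len(m)],
                                       max(0, 1 - sum(shares[seq_len(m)]))))
}

#' Circulant singular spectrum analysis
#'
#' Variant of SSA in which the second-order structure is summarized by a
#' circulant matrix whose eigenvectors are the Fourier basis, so every
#' elementary component is tied to a known frequency `j/L` cycles/sample.
#' Conjugate frequency pairs (`j` and `L-j`) are merged, yielding real
#' components. The per-frequency components are ranked by energy share; the
#' largest are kept as individual components (at most `max_components - 1`)
#' and all remaining bins are aggregated into one final component, so the
#' full set reconstructs the input exactly.
#'
#' @inheritParams ssa
#' @param max_components Cap on the number of returned components
#'   (default 10).
#' @return A [component_set()] (method `"CiSSA"`) with per-component energy
#'   shares and an attached `frequency_hz` vector (NA for the aggregate).
#' @export
cissa <- function(x, L = 100, max_components = 10, fs = NULL) {
  s <- as_signal(x, fs)
  n <- length(s$samples)
  if (L >= n) stop("window length L must be smaller than the signal length",
                   call. = FALSE)
  X <- trajectory_matrix(s$samples, L)
  K <- ncol(X)
  counts <- diag_counts(L, K)

  # frequency-bin groups: bin 0, conjugate pairs (j, L-j), Nyquist if L even
  half <- floor(L / 2)
  groups <- lapply(0:half, function(j) {
    if (j == 0 || (L %% 2 == 0 && j == half)) j else c(j, L - j)
  })

  # component per frequency group via projection onto Fourier vectors
  om <- 2 * pi * (seq_len(L) - 1L) / L
  series <- vector("list", length(groups))
  energy <- numeric(length(groups))
  for (g in seq_along(groups)) {
    acc <- numeric(n)
    for (j in groups[[g]]) {
      u <- exp(1i * om * j) / sqrt(L)
      a <- drop(Conj(u) %*% X)            # u^H X, length K
      re <- diag_average(Re(u), Re(a), counts) -
        diag_average(Im(u), Im(a), counts)
      acc <- acc + re
    }
    series[[g]] <- acc
    energy[g] <- sum(acc^2)
  }

  shares <- energy / sum(energy)
  ord <- order(shares, decreasing = TRUE)
  n_keep <- min(max_components - 1L, length(groups) - 1L)
  keep <- ord[seq_len(n_keep)]
  rest <- setdiff(seq_along(groups), keep)
  comps <- series[keep]
  freqs <- vapply(groups[keep], function(g) g[1] / L * s$fs, numeric(1))
  if (length(rest)) {
    comps <- c(comps, list(Reduce(`+`, series[rest])))
    freqs <- c(freqs, NA_real_)
  }
  evar <- c(shares[keep], if (length(rest)) sum(shares[rest]))
  cs <- component_set(comps, residual = NULL, method = "CiSSA",
                      params = list(L = L, max_components = max_components),
                      fs = s$fs, explained_variance = evar)
  attr(cs, "frequency_hz") <- freqs
  cs
}
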