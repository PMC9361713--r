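# Periodized orthogonal discrete wavelet transform with the coif5 filter,
# and the multiresolution (per-level band) decomposition built on it.

# coif5 orthonormal scaling (low-pass decomposition) filter, 30 taps
coif5_dec_lo <- c(
  -9.60401011276789415e-08, -1.62379951720483376e-07,
   2.06122039857887835e-06,  3.70072771133947962e-06,
  -2.12702216725156143e-05, -4.12198619242655010e-05,
   1.40356328123732431e-04,  3.01857941668244784e-04,
  -6.37558926125881154e-04, -1.66162730392987882e-03,
   2.43157544253828862e-03,  6.76152022062041693e-03,
  -9.15950733867616253e-03, -1.97583916009654650e-02,
   3.26747994670573555e-02,  4.12875304721178338e-02,
  -1.05563151307337233e-01, -6.20377515749819600e-02,
   4.37982306659163378e-01,  7.74293622860327435e-01,
   4.21571266730754346e-01, -5.20466702535547637e-02,
  -9.19215880600860874e-02,  2.81697442705323535e-02,
   2.34083221189277831e-02, -1.01315848469002764e-02,
  -4.15931262757864018e-03,  2.17829437784569473e-03,
   3.58577741161757678e-04, -2.12081862067494000e-04)

# quadrature-mirror high-pass companion
coif5_dec_hi <- local({
  h <- rev(coif5_dec_lo)
  h * (-1)^(seq_along(h) - 1L)
})

# one periodized analysis step: x (even length n) -> list(a, d) of length n/2
# a[j] = sum_k h0[k] x[(2(j-1)+k-1) mod n], the rows of an orthogonal matrix
dwt_step <- function(x, h0 = coif5_dec_lo, h1 = coif5_dec_hi) {
  n <- length(x)
  stopifnot(n %% 2L == 0L)
  n2 <- n %/% 2L
  a <- numeric(n2)
  d <- numeric(n2)
  base <- 2L * (seq_len(n2) - 1L)
  for (k in seq_along(h0)) {
    idx <- (base + (k - 1L)) %% n + 1L
    a <- a + h0[k] * x[idx]
    d <- d + h1[k] * x[idx]
  }
  list(a = a, d = d)
}

# inverse of dwt_step (transpose of the orthogonal analysis matrix)
idwt_step <- function(a, d, h0 = coif5_dec_lo, h1 = coif5_dec_hi) {
  n2 <- length(a)
  n <- 2L * n2
  y <- numeric(n)
  base <- 2L * (seq_len(n2) - 1L)
  for (k in seq_along(h0)) {
    idx <- (base + (k - 1L)) %% n + 1L
    y[idx] <- y[idx] + h0[k] * a + h1[k] * d
  }
  y
}

# deepest level at which every analysis stage still halves an even length
# and the data outnumber the filter
wavelet_max_level <- function(n, filter_len = length(coif5_dec_lo)) {
  v2 <- 0L
  m <- n
  while (m %% 2L == 0L) { m <- m %/% 2L; v2 <- v2 + 1L }
  feas <- 0L
  m <- n
  while (m %/% 2L >= filter_len) { m <- m %/% 2L; feas <- feas + 1L }
  min(v2, feas)
}

#' Wavelet multiresolution decomposition (coif5)
#'
#' Multilevel periodized orthogonal discrete wavelet transform with the
#' coif5 mother wavelet. One reconstructed component is returned per detail
#' level (finest first) plus the final approximation, so the components are
#' band-limited pieces that sum to the input exactly (perfect
#' reconstruction).
#'
#' The decomposition depth is `min(max_level, feasible depth)` where the
#' feasible depth requires every analysis stage to split an even number of
#' samples and to keep more coefficients than filter taps.
#'
#' @param x A [time_series()] or numeric vector.
#' @param max_level Depth cap (default 10).
#' @param fs Sampling rate when `x` is a bare vector.
#' @return A [component_set()] (method `"Wavelet"`): detail components
#'   D1..DJ then the approximation AJ.
#' @export
wavelet_decompose <- function(x, max_level = 10, fs = NULL) {
  s <- as_signal(x, fs)
  n <- length(s$samples)
  J <- min(max_level, wavelet_max_level(n))
  if (J < 1L)
    stop("signal too short for a coif5 decomposition (need an even length ",
         "with at least ", 2L * length(coif5_dec_lo), " samples)",
         call. = FALSE)
  details <- vector("list", J)
  a <- s$samples
  for (j in seq_len(J)) {
    st <- dwt_step(a)
    details[[j]] <- st$d
    a <- st$a
  }
  # reconstruct each band by zeroing all other coefficient vectors
  comps <- vector("list", J + 1L)
  for (j in seq_len(J)) {
    y <- idwt_step(numeric(length(details[[j]])), details[[j]])
    if (j > 1L) for (l in (j - 1L):1L) y <- idwt_step(y, numeric(length(y)))
    comps[[j]] <- y
  }
  y <- a
  for (l in J:1L) y <- idwt_step(y, numeric(length(y)))
  comps[[J + 1L]] <- y
  names(comps) <- c(paste0("D", seq_len(J)), paste0("A", J))
  component_set(comps, residual = NULL, method = "Wavelet",
                params = list(wavelet = "coif5", levels = J,
                              max_level = max_level),
                fs = s$fs)
}
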