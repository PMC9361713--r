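#' Uniformly sampled single-channel signal
#'
#' Lightweight container for a uniformly sampled time series in microvolts.
#' Most functions in the package accept either a `ts_uv` object or a plain
#' numeric vector plus an `fs` argument.
#'
#' @param samples Numeric vector of amplitudes (microvolts).
#' @param fs Sampling rate in Hz (positive scalar).
#' @return An object of class `ts_uv`: a list with elements `samples` and
#'   `fs`.
#' @examples
#' x <- time_series(sin(2 * pi * 10 * seq(0, 1, by = 1 / 500)), fs = 500)
#' x
#' @export
time_series <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a positive finite scalar", call. = FALSE)
  if (length(samples) < 1L)
    stop("'samples' must contain at least one value", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("'samples' must be finite", call. = FALSE)
  structure(list(samples = samples, fs = fs), class = "ts_uv")
}

#' @export
print.ts_uv <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("<ts_uv> %d samples @ %g Hz (%.3f s)\n", n, x$fs, n / x$fs))
  cat(sprintf("  range [%.4g, %.4g] uV, RMS %.4g uV\n",
              min(x$samples), max(x$samples), sqrt(mean(x$samples^2))))
  invisible(x)
}

#' @export
length.ts_uv <- function(x) length(x$samples)

# Coerce ts_uv / numeric to a bare sample vector; returns list(samples, fs).
# fs argument wins over an object's stored rate only when the object has none.
as_signal <- function(x, fs = NULL) {
  if (inherits(x, "ts_uv")) {
    list(samples = x$samples, fs = x$fs)
  } else {
    if (is.null(fs))
      stop("'fs' is required when the input is a plain numeric vector",
           call. = FALSE)
    list(samples = as.numeric(x), fs = fs)
  }
}

# rebuild a ts_uv carrying the rate of a template
rewrap <- function(samples, template) time_series(samples, template$fs)

#' Per-sample EMG contamination mask
#'
#' Binary labelling of a record: high (`TRUE`) samples carry EMG activity,
#' low (`FALSE`) samples are noise-only (clean EEG) periods.
#'
#' @param flags Logical (or 0/1) vector, one flag per sample.
#' @param fs Sampling rate in Hz.
#' @return Object of class `emg_mask` with elements `flags` and `fs`.
#' @seealso [mask_intervals()], [intervals_to_mask()]
#' @export
contamination_mask <- function(flags, fs) {
  flags <- as.logical(flags)
  if (anyNA(flags)) stop("mask flags must be TRUE/FALSE or 0/1", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a positive scalar", call. = FALSE)
  structure(list(flags = flags, fs = fs), class = "emg_mask")
}

#' @export
print.emg_mask <- function(x, ...) {
  iv <- mask_intervals(x)
  cat(sprintf("<emg_mask> %d samples @ %g Hz: %d high runs, %.3f s high time\n",
              length(x$flags), x$fs, nrow(iv), sum(x$flags) / x$fs))
  invisible(x)
}

#' @export
length.emg_mask <- function(x) length(x$flags)

#' Interval view of a contamination mask
#'
#' Converts per-sample flags to half-open runs of high samples.
#'
#' @param mask An `emg_mask`.
#' @return Data frame with columns `start_sample`, `end_sample` (half-open,
#'   1-based: the run covers `start_sample .. end_sample - 1`), `start_s`,
#'   `end_s`.
#' @export
mask_intervals <- function(mask) {
  stopifnot(inherits(mask, "emg_mask"))
  f <- mask$flags
  if (!any(f))
    return(data.frame(start_sample = integer(0), end_sample = integer(0),
                      start_s = numeric(0), end_s = numeric(0)))
  r <- rle(f)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_sample = starts[keep],
             end_sample = ends[keep] + 1L,
             start_s = (starts[keep] - 1L) / mask$fs,
             end_s = ends[keep] / mask$fs)
}

#' Build a contamination mask from intervals in seconds
#'
#' @param start_s,end_s Numeric vectors of interval bounds in seconds
#'   (half-open `[start_s, end_s)`).
#' @param n Total number of samples of the record.
#' @param fs Sampling rate in Hz.
#' @return An `emg_mask` of length `n`.
#' @export
intervals_to_mask <- function(start_s, end_s, n, fs) {
  stopifnot(length(start_s) == length(end_s), all(end_s >= start_s))
  flags <- logical(n)
  for (i in seq_along(start_s)) {
    a <- max(1L, floor(start_s[i] * fs) + 1L)
    b <- min(n, ceiling(end_s[i] * fs))
    if (b >= a) flags[a:b] <- TRUE
  }
  contamination_mask(flags, fs)
}

# run body with a private, seeded RNG stream; global .Random.seed untouched.
# seed = NULL runs under the ambient RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# derive a reproducible child seed from a root seed and a stream label,
# kept below 2^31
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  # double arithmetic stays exact well below 2^53, result fits in 32 bits
  as.integer((as.numeric(seed) %% 65521 * 2654435 + h * 97) %% 2147483629)
}
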