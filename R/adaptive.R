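#' Adaptive-filter configuration
#'
#' Defaults follow the study settings: order 10 for LMS/RLS/Wiener, order 4
#' for NLMS, LMS step 1e-7 (microvolt-squared input scale). Since a
#' literal step has no meaning for the normalized and recursive filters, the
#' stated 1e-7 maps to the NLMS regularizer `eps` and the RLS
#' inverse-correlation initialization `delta`; the NLMS normalized step is
#' 0.1 and the RLS forgetting factor 0.999.
#'
#' @param method One of `"LMS"`, `"NLMS"`, `"RLS"`, `"Wiener"`
#'   (case-insensitive).
#' @param order Tap count (default 10; 4 for NLMS).
#' @param step LMS adaptation step mu (default 1e-7).
#' @param nlms_step Normalized NLMS step (default 0.1).
#' @param nlms_eps NLMS power regularizer (default 1e-7).
#' @param rls_forgetting RLS forgetting factor lambda in (0, 1]
#'   (default 0.999).
#' @param rls_delta RLS initialization scale delta: P(0) = I/delta
#'   (default 1e-7).
#' @param reference_kind `"EMG_ref"` (reference predicts the artifact; the
#'   cleaned signal is the cancellation error) or `"EEG_ref"` (reference
#'   resembles the brain signal; the cleaned signal is the filter output).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(method = c("RLS", "Wiener", "LMS", "NLMS"),
                          order = NULL, step = 1e-7,
                          nlms_step = 0.1, nlms_eps = 1e-7,
                          rls_forgetting = 0.999, rls_delta = 1e-7,
                          reference_kind = c("EMG_ref", "EEG_ref")) {
  method <- toupper(match.arg(toupper(method[1]),
                              c("RLS", "WIENER", "LMS", "NLMS")))
  method <- c(RLS = "RLS", WIENER = "Wiener", LMS = "LMS",
              NLMS = "NLMS")[[method]]
  if (is.null(order)) order <- if (method == "NLMS") 4L else 10L
  reference_kind <- match.arg(reference_kind)
  stopifnot(order >= 1, step > 0,
            rls_forgetting > 0, rls_forgetting <= 1, rls_delta > 0)
  structure(list(method = method, order = as.integer(order), step = step,
                 nlms_step = nlms_step, nlms_eps = nlms_eps,
                 rls_forgetting = rls_forgetting, rls_delta = rls_delta,
                 reference_kind = reference_kind),
            class = "filter_config")
}

#' Adaptive noise cancellation
#'
#' Runs the configured filter with the contaminated signal as the desired
#' input `d` and the reference as the tap-delay input, returning the filter
#' output `y`, the cancellation error `e = d - y`, the final weights, and
#' the cleaned signal selected by `reference_kind` (error for an EMG-like
#' reference, output for an EEG-like reference).
#'
#' LMS updates `w <- w + 2*mu*e*x`; NLMS normalizes the step by the
#' tap-vector power; RLS is exponentially weighted recursive least squares
#' with inverse-correlation initialization `I/delta`; Wiener solves the
#' batch FIR normal equations (Toeplitz autocorrelation of the reference vs
#' cross-correlation to the desired signal) and applies the resulting taps
#' by causal convolution.
#'
#' @param desired A [time_series()] or numeric vector: the contaminated EEG.
#' @param reference A [time_series()] or numeric vector of equal length.
#' @param cfg A [filter_config()].
#' @param fs Sampling rate when inputs are bare vectors.
#' @return An object of class `filter_result`: list with `output`, `error`,
#'   `cleaned` (all [time_series()]), `weights` and `cfg`.
#' @export
adaptive_filter <- function(desired, reference, cfg = filter_config(),
                            fs = NULL) {
  d <- as_signal(desired, fs)
  r <- as_signal(reference, fs)
  n <- length(d$samples)
  if (length(r$samples) != n)
    stop("'desired' and 'reference' lengths differ", call. = FALSE)
  if (n < cfg$order)
    stop("signal shorter than the filter order", call. = FALSE)
  if (!all(is.finite(d$samples)) || !all(is.finite(r$samples)))
    stop("inputs must be finite", call. = FALSE)

  res <- switch(cfg$method,
    LMS = lms_filter_cpp(d$samples, r$samples, cfg$order, cfg$step),
    NLMS = nlms_filter_cpp(d$samples, r$samples, cfg$order, cfg$nlms_step,
                           cfg$nlms_eps),
    RLS = rls_filter_cpp(d$samples, r$samples, cfg$order,
                         cfg$rls_forgetting, cfg$rls_delta),
    Wiener = wiener_fir(d$samples, r$samples, cfg$order))
  y <- res$y
  e <- d$samples - y
  cleaned <- if (cfg$reference_kind == "EMG_ref") e else y
  structure(list(output = time_series(y, d$fs),
                 error = time_series(e, d$fs),
                 cleaned = time_series(cleaned, d$fs),
                 weights = res$w, cfg = cfg),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> %s order %d (%s): n = %d\n",
              x$cfg$method, x$cfg$order, x$cfg$reference_kind,
              length(x$output)))
  cat(sprintf("  error power / desired power = %.4g\n",
              mean(x$error$samples^2) /
                mean((x$output$samples + x$error$samples)^2)))
  invisible(x)
}

# batch Wiener FIR: solve R w = p with R the Toeplitz autocorrelation of the
# reference and p the reference->desired cross-correlation
wiener_fir <- function(d, ref, order) {
  n <- length(d)
  r <- sapply(0:(order - 1L), function(k) {
    sum(ref[1:(n - k)] * ref[(1 + k):n]) / n
  })
  p <- sapply(0:(order - 1L), function(k) {
    sum(d[(1 + k):n] * ref[1:(n - k)]) / n
  })
  R <- stats::toeplitz(r)
  w <- tryCatch(solve(R, p),
                error = function(e)
                  stop("Wiener normal equations are singular: ",
                       conditionMessage(e), call. = FALSE))
  # causal FIR application with zero-padded history
  y <- as.numeric(stats::filter(ref, w, method = "convolution", sides = 1))
  head_i <- seq_len(min(order - 1L, n))
  y[head_i] <- vapply(head_i, function(i) {
    sum(w[seq_len(i)] * ref[i - seq_len(i) + 1L])
  }, numeric(1))
  list(y = y, w = w)
}

#' Clean a contaminated EEG signal with a reference
#'
#' Thin wrapper over [adaptive_filter()] returning just the cleaned signal:
#' the cancellation error for an EMG-like reference, the filter output for
#' an EEG-like reference.
#'
#' @inheritParams adaptive_filter
#' @param contaminated The contaminated EEG.
#' @return A [time_series()].
#' @export
clean_eeg <- function(contaminated, reference, cfg = filter_config(),
                      fs = NULL) {
  adaptive_filter(contaminated, reference, cfg, fs = fs)$cleaned
}
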