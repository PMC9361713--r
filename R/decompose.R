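#' Ordered set of decomposition components
#'
#' Container returned by all decomposition methods. Components are
#' equal-length amplitude arrays; methods with a complete expansion (EMD,
#' SSA, CiSSA, Wavelet) reconstruct the input as the sum of all components
#' plus any stored residual.
#'
#' @param components List of equal-length numeric vectors.
#' @param residual Optional residual vector (EMD-family residue), or `NULL`.
#' @param method Method label: one of `"EMD"`, `"EEMD"`, `"SSA"`, `"CiSSA"`,
#'   `"Wavelet"`, `"EMD_PCA"`.
#' @param params Method parameter record (list).
#' @param fs Sampling rate in Hz.
#' @param explained_variance Optional per-component variance fractions.
#' @return An object of class `component_set`.
#' @export
component_set <- function(components, residual = NULL, method, params = list(),
                          fs, explained_variance = NULL) {
  stopifnot(is.list(components), length(components) >= 1L)
  n <- length(components[[1]])
  ok <- vapply(components, function(c) length(c) == n, logical(1))
  if (!all(ok)) stop("components must have equal lengths", call. = FALSE)
  if (!is.null(residual) && length(residual) != n)
    stop("residual length differs from component length", call. = FALSE)
  structure(list(components = components, residual = residual,
                 method = method, params = params, fs = fs,
                 explained_variance = explained_variance,
                 n = n),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %s: %d components x %d samples @ %g Hz%s\n",
              x$method, length(x$components), x$n, x$fs,
              if (!is.null(x$residual)) " (+ residual)" else ""))
  if (!is.null(x$explained_variance))
    cat("  explained variance:",
        paste(sprintf("%.3f", x$explained_variance), collapse = " "), "\n")
  invisible(x)
}

# every array that participates in reconstruction (components + residual)
all_components <- function(cs) {
  stopifnot(inherits(cs, "component_set"))
  if (is.null(cs$residual)) cs$components else
    c(cs$components, list(cs$residual))
}

#' Reconstruct a signal from its component set
#'
#' Sum of all components plus the stored residual (if any). Exact for the
#' complete methods; the reduced-rank approximation for EMD-PCA.
#'
#' @param cs A [component_set()].
#' @return A [time_series()].
#' @export
reconstruct <- function(cs) {
  time_series(Reduce(`+`, all_components(cs)), cs$fs)
}

#' Decompose a signal by one of six methods
#'
#' Front end dispatching to [emd()], [eemd()], [ssa()], [cissa()],
#' [wavelet_decompose()] or [emd_pca()] with the package defaults: pchip
#' envelopes and at most 10 IMFs for EMD/EEMD, 5 ensembles for EEMD, window
#' length 100 and 80% explained variance for SSA, at most 10 components for
#' CiSSA, the coif5 mother wavelet with at most 10 levels, and an 80%
#' variance target for EMD-PCA.
#'
#' @param x A [time_series()] or numeric vector.
#' @param method One of `"EMD"`, `"EEMD"`, `"SSA"`, `"CiSSA"`, `"Wavelet"`,
#'   `"EMD_PCA"` (case-insensitive; `"emd-pca"` also accepted).
#' @param ... Method-specific parameters passed through (e.g. `L`,
#'   `var_target`, `max_imf`, `seed`).
#' @param fs Sampling rate when `x` is a bare vector.
#' @return A [component_set()].
#' @export
decompose <- function(x, method, ..., fs = NULL) {
  m <- toupper(gsub("-", "_", method))
  switch(m,
         EMD = emd(x, ..., fs = fs),
         EEMD = eemd(x, ..., fs = fs),
         SSA = ssa(x, ..., fs = fs),
         CISSA = cissa(x, ..., fs = fs),
         WAVELET = wavelet_decompose(x, ..., fs = fs),
         EMD_PCA = emd_pca(x, ..., fs = fs),
         stop("unknown decomposition method: ", method, call. = FALSE))
}

#' Explained-variance fractions of a component set
#'
#' Eigenvalue shares for SSA, per-frequency energy shares for CiSSA, and
#' principal-axis shares for EMD-PCA. Methods without a variance notion
#' (raw EMD/EEMD, Wavelet) raise an error.
#'
#' @param cs A [component_set()].
#' @return Numeric vector of nonnegative fractions (sum at most 1, up to
#'   rounding), one per component.
#' @export
explained_variance <- function(cs) {
  stopifnot(inherits(cs, "component_set"))
  if (is.null(cs$explained_variance))
    stop("method '", cs$method, "' has no explained-variance notion",
         call. = FALSE)
  cs$explained_variance
}
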