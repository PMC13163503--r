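# Spectral preprocessing battery.
#
# Eight patterns: raw spectra, Savitzky-Golay smoothing, first and second
# SG derivatives (window 9, polyorder 2), SNV, and SNV followed by each of
# the three SG variants. One code path serves both the ROI-averaged
# calibration spectra and the pixel-wise imaging spectra, so any noise
# amplification a pattern causes is identical on both sides.
#
# The SG filter is a linear operator; we materialize it once per
# (length, window, polyorder, derivative) as a dense matrix whose edge rows
# fit the polynomial on the truncated window, keeping the full band axis
# intact (needed so pixel spectra can be projected with the calibration
# W* matrix). Derivatives are in per-band units (no division by the nm
# spacing): PLSR is scale-equivariant, so the physical unit is immaterial.

PATTERNS <- c("none", "smooth", "d1", "d2", "snv", "snv_smooth", "snv_d1", "snv_d2")

#' Preprocessing specification
#'
#' @param pattern One of `"none"`, `"smooth"`, `"d1"`, `"d2"`, `"snv"`,
#'   `"snv_smooth"`, `"snv_d1"`, `"snv_d2"`.
#' @param window Odd Savitzky-Golay window length (default 9).
#' @param polyorder Polynomial order (default 2); must be < window.
#' @return Object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(pattern = "none", window = 9L, polyorder = 2L) {
  if (!pattern %in% PATTERNS) {
    stop(sprintf("unknown pattern '%s'; valid: %s", pattern,
                 paste(PATTERNS, collapse = ", ")))
  }
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L || window <= polyorder) {
    stop("`window` must be odd and greater than `polyorder`")
  }
  structure(list(pattern = pattern, window = window, polyorder = polyorder),
            class = "preprocess_spec")
}

#' All eight preprocessing patterns
#'
#' @param window,polyorder Passed to [preprocess_spec].
#' @return Named list of eight `preprocess_spec` objects.
#' @export
all_patterns <- function(window = 9L, polyorder = 2L) {
  stats::setNames(lapply(PATTERNS, preprocess_spec, window = window,
                         polyorder = polyorder), PATTERNS)
}

sg_cache <- new.env(parent = emptyenv())

# Dense n x n Savitzky-Golay operator: row i holds the convolution weights
# producing the filtered value (or derivative) at band i. Edge rows use the
# window truncated to available bands.
sg_matrix <- function(n, window, polyorder, deriv) {
  key <- paste(n, window, polyorder, deriv, sep = "_")
  if (!is.null(sg_cache[[key]])) return(sg_cache[[key]])
  if (n < window) stop("spectrum shorter than the SG window")
  half <- (window - 1L) %/% 2L
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    m <- (lo:hi) - i                      # offsets within the window
    A <- outer(m, 0:polyorder, `^`)
    # value/derivative at offset 0 of the fitted polynomial:
    # coefficient d of the LS fit, times d!
    coefs <- solve(crossprod(A), t(A))[deriv + 1L, ] * factorial(deriv)
    S[i, lo:hi] <- coefs
  }
  sg_cache[[key]] <- S
  S
}

#' Savitzky-Golay filtering and differentiation
#'
#' Local least-squares polynomial filtering. `deriv = 0` smooths; 1 and 2
#' return first and second derivatives in per-band units. Edges are handled
#' by fitting the polynomial on the truncated window, so the output keeps
#' the full band axis. Exact for polynomials up to degree `polyorder`.
#'
#' @param x Numeric vector (one spectrum) or matrix (spectra in rows).
#' @param window Odd window length.
#' @param polyorder Polynomial order (< window).
#' @param deriv Derivative order 0, 1 or 2.
#' @return Filtered vector or matrix of the same shape.
#' @export
savitzky_golay <- function(x, window = 9L, polyorder = 2L, deriv = 0L) {
  if (!deriv %in% 0:2) stop("`deriv` must be 0, 1 or 2")
  if (window %% 2L == 0L || window <= polyorder) {
    stop("`window` must be odd and greater than `polyorder`")
  }
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  S <- sg_matrix(ncol(X), as.integer(window), as.integer(polyorder),
                 as.integer(deriv))
  out <- X %*% t(S)
  if (vec) drop(out) else out
}

#' Standard normal variate transform
#'
#' Per-spectrum standardization `(x - mean(x)) / sd(x)` (sd with n-1
#' denominator), removing additive offsets and multiplicative scatter.
#' Spectra with zero variance cannot be standardized and are returned as
#' all-NA rows with a count in attribute `n_failed` (downstream maps mask
#' those pixels).
#'
#' @param x Numeric vector or matrix (spectra in rows).
#' @return Transformed vector/matrix; attribute `n_failed` counts constant
#'   spectra.
#' @export
snv <- function(x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1L))
  bad <- !is.finite(sdv) | sdv == 0
  sdv[bad] <- NA_real_
  out <- (X - mu) / sdv
  attr(out, "n_failed") <- sum(bad)
  if (vec) {
    if (bad[1]) stop("constant spectrum: SNV undefined")
    out <- drop(out)
    attr(out, "n_failed") <- NULL
  }
  out
}

#' Apply a preprocessing pattern
#'
#' Applies the named pattern row-wise (each row an independent spectrum).
#' Combined patterns run SNV first, then the SG stage, matching the
#' "SNV-1st derivative" naming convention. `none` is the identity.
#'
#' @param x Numeric vector or matrix (spectra in rows).
#' @param spec A [preprocess_spec] (or pattern name).
#' @return Transformed vector/matrix; attribute `n_failed` present when SNV
#'   encountered constant spectra.
#' @export
apply_pattern <- function(x, spec = preprocess_spec("none")) {
  if (is.character(spec)) spec <- preprocess_spec(spec)
  p <- spec$pattern
  if (p == "none") return(x)
  out <- x
  n_failed <- 0L
  if (startsWith(p, "snv")) {
    out <- snv(out)
    n_failed <- attr(out, "n_failed") %||% 0L
    p <- sub("^snv_?", "", p)
    if (p == "") {
      return(out)
    }
  }
  d <- switch(p, smooth = 0L, d1 = 1L, d2 = 2L)
  out <- savitzky_golay(out, spec$window, spec$polyorder, d)
  if (n_failed > 0L) attr(out, "n_failed") <- n_failed
  out
}
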