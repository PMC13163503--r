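# Imaging reliability in PLS score space.
#
# A PLSR model is calibrated on ROI-averaged spectra but applied to single
# pixels, whose spectra can be far noisier or structurally different. To
# quantify whether pixel spectra are statistically consistent with the
# calibration data, each pixel spectrum is projected into the model's
# latent space (t = (x - x_mean) W*), and its squared Mahalanobis distance
# to the calibration score cloud (mean mu, covariance Sigma) is compared
# with a chi-square quantile: under multivariate normality of calibration
# scores, D^2 ~ chi^2(A). The threshold is parameterized by a k-sigma rule:
# alpha = erf(k / sqrt(2)) (two-sided normal coverage; 0.9973 at k = 3) and
# tau = qchisq(alpha, A). The reliability index of an SSC map is the
# fraction of its pixels with D^2 <= tau.

#' Project spectra into a model's PLS score space
#'
#' `T = (X - x_mean) W*`, using the calibration centering vector. Spectra
#' must be preprocessed with the identical pattern used for calibration.
#'
#' @param model A [pls_model].
#' @param spectra Matrix of preprocessed spectra (rows) or a single vector.
#' @param center Center with the calibration mean (default `TRUE`; the
#'   latent space is defined on centered data).
#' @return Score matrix with `model$A` columns.
#' @export
project_scores <- function(model, spectra, center = TRUE) {
  X <- if (is.null(dim(spectra))) matrix(spectra, nrow = 1L) else as.matrix(spectra)
  if (ncol(X) != length(model$x_mean)) stop("band-count mismatch")
  if (center) X <- sweep(X, 2L, model$x_mean)
  X %*% model$Wstar
}

#' Fit the calibration manifold (score-space normal model)
#'
#' Column mean and sample covariance (n-1 denominator) of the calibration
#' scores, plus the k-sigma chi-square threshold
#' `tau = qchisq(erf(k/sqrt(2)), A)`. Alternatively a coverage probability
#' `alpha` can be given directly (e.g. 0.99), overriding `k`.
#'
#' @param Ttrain Calibration score matrix (m x A).
#' @param k Sigma multiplier (default 3, i.e. alpha = 0.9973).
#' @param alpha Optional explicit coverage probability in (0, 1).
#' @return Object of class `calibration_manifold` with fields `mu`, `sigma`,
#'   `A`, `k`, `alpha`, `tau`.
#' @export
fit_manifold <- function(Ttrain, k = 3, alpha = NULL) {
  Tm <- as.matrix(Ttrain)
  m <- nrow(Tm); A <- ncol(Tm)
  if (m <= A) stop("need more calibration samples than score dimensions")
  if (is.null(alpha)) {
    alpha <- ksigma_coverage(k)
  } else {
    if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
    k <- stats::qnorm((1 + alpha) / 2)
  }
  mu <- colMeans(Tm)
  sigma <- stats::cov(Tm)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("singular score covariance; refit with fewer latent variables")
  }
  if (max(ev) / min(ev) > 1e10) {
    warning(sprintf("ill-conditioned score covariance (condition %.2e)",
                    max(ev) / min(ev)))
  }
  structure(list(mu = mu, sigma = sigma, A = A, k = k, alpha = alpha,
                 tau = stats::qchisq(alpha, df = A)),
            class = "calibration_manifold")
}

#' @export
print.calibration_manifold <- function(x, ...) {
  cat(sprintf("<calibration_manifold> A=%d, k=%.3g, alpha=%.5f, tau=%.4f\n",
              x$A, x$k, x$alpha, x$tau))
  invisible(x)
}

#' Squared Mahalanobis distances to the calibration manifold
#'
#' `D^2 = (t - mu)' Sigma^{-1} (t - mu)` per score vector, computed through
#' a Cholesky solve of the (symmetric positive definite) covariance rather
#' than an explicit inverse.
#'
#' @param t Score matrix (rows) or a single score vector.
#' @param manifold A [calibration_manifold].
#' @return Numeric vector of squared distances (>= 0).
#' @export
mahalanobis_sq <- function(t, manifold) {
  Tm <- if (is.null(dim(t))) matrix(t, nrow = 1L) else as.matrix(t)
  if (ncol(Tm) != manifold$A) stop("score dimension mismatch")
  ctr <- sweep(Tm, 2L, manifold$mu)
  R <- chol(manifold$sigma)
  z <- backsolve(R, t(ctr), transpose = TRUE)
  colSums(z^2)
}

#' Reliability index from squared distances
#'
#' Fraction of pixels whose squared Mahalanobis distance does not exceed
#' the threshold (boundary pixels count as inliers).
#'
#' @param d2 Numeric vector of squared distances (NA entries, e.g. failed
#'   preprocessing pixels, count as outliers).
#' @param tau Threshold (or a [calibration_manifold], whose `tau` is used).
#' @return Object of class `reliability_result`: list with `d2`,
#'   `inlier_mask`, `reliability`, `n_pixels`.
#' @export
reliability_index <- function(d2, tau) {
  if (inherits(tau, "calibration_manifold")) tau <- tau$tau
  n <- length(d2)
  if (n < 1L) stop("empty pixel set")
  inlier <- !is.na(d2) & d2 <= tau
  structure(list(d2 = d2, inlier_mask = inlier,
                 reliability = sum(inlier) / n, n_pixels = n),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability_result> %.4f (%d / %d inliers)\n",
              x$reliability, sum(x$inlier_mask), x$n_pixels))
  invisible(x)
}

#' Model-level reliability: unweighted mean over test samples
#'
#' Each test fruit contributes its own per-image reliability; the model
#' metric is their unweighted mean (images with many pixels do not dominate
#' ones with few).
#'
#' @param per_sample_results List of [reliability_result] objects or a
#'   numeric vector of per-sample reliabilities.
#' @return Scalar mean reliability.
#' @export
model_reliability <- function(per_sample_results) {
  vals <- if (is.numeric(per_sample_results)) per_sample_results else
    vapply(per_sample_results, function(r) r$reliability, numeric(1))
  if (length(vals) < 1L) stop("need at least one test sample")
  mean(vals)
}

#' Threshold sensitivity of the sweep ranking
#'
#' Recomputes the reliability column of a sweep for each `k` from the
#' cached per-record squared-distance distributions and reports whether the
#' reliability-maximizing configuration is invariant to the choice of `k`.
#'
#' @param sweep A sweep `data.frame` from [run_sweep] carrying the
#'   `d2_cache` attribute (per record: list of per-sample `d2` vectors and
#'   the score dimension `A`).
#' @param k_values Sigma multipliers to try (default `c(2, 3, 4)`).
#' @return List with `table` (one reliability column per k), `argmax`
#'   (winning record index per k) and `invariant` (logical).
#' @export
threshold_sensitivity <- function(sweep, k_values = c(2, 3, 4)) {
  cache <- attr(sweep, "d2_cache")
  if (is.null(cache)) stop("sweep carries no d2 cache")
  tab <- sapply(k_values, function(k) {
    vapply(cache, function(rec) {
      if (is.null(rec)) return(NA_real_)
      tau <- stats::qchisq(ksigma_coverage(k), df = rec$A)
      model_reliability(vapply(rec$d2, function(d) {
        sum(!is.na(d) & d <= tau) / length(d)
      }, numeric(1)))
    }, numeric(1))
  })
  tab <- matrix(tab, ncol = length(k_values),
                dimnames = list(NULL, paste0("k", k_values)))
  argmax <- apply(tab, 2L, which.max)
  list(table = cbind(sweep[, c("geometry_mode", "pattern")], tab),
       argmax = argmax,
       invariant = length(unique(argmax)) == 1L)
}
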