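# Region-of-interest extraction.
#
# Flesh segmentation proceeds in three stages: (1) remove the background by
# thresholding a single-band image; (2) score every remaining pixel on the
# first principal component of its spectrum over a wavelength window (flesh
# and achene spectra separate along PC1); (3) binarize the score image with
# Otsu's method and keep the class containing the median score (flesh is
# the majority class in a fruit scene).

#' ROI mask container
#'
#' @param mask Logical matrix.
#' @param stage `"background_removed"` or `"flesh"`.
#' @param params_used Named list recording the parameters that produced it.
#' @return Object of class `roi_mask`.
#' @export
roi_mask <- function(mask, stage = c("background_removed", "flesh"),
                     params_used = list()) {
  stage <- match.arg(stage)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, stage = stage, params_used = params_used),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> stage=%s, %d / %d pixels\n", x$stage,
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Background mask from a single-band threshold
#'
#' Selects pixels whose value at the band nearest `band_nm` exceeds
#' `threshold`. Works on reflectance cubes (e.g. 1204 nm at 0.2) or raw
#' intensity cubes (e.g. 1123 nm at 12000 counts), matching the two
#' instrument presets.
#'
#' @param cube A [hypercube].
#' @param band_nm Wavelength (nm) of the thresholding band.
#' @param threshold Scalar threshold; pixels strictly above it are kept.
#' @return A [roi_mask] at stage `background_removed`.
#' @export
background_mask <- function(cube, band_nm, threshold) {
  wl <- cube$wavelengths
  d <- abs(wl - band_nm)
  b <- which.min(d)
  spacing <- stats::median(diff(wl))
  if (d[b] > spacing) {
    stop(sprintf("band %.0f nm is outside the wavelength axis", band_nm))
  }
  img <- cube$values[, , b]
  m <- !is.na(img) & img > threshold
  roi_mask(m, "background_removed",
           params_used = list(band_nm = wl[b], threshold = threshold))
}

#' PC1 score image over a wavelength window
#'
#' Mean-centers the masked pixel spectra restricted to `window_nm`, extracts
#' the first principal component, and assigns each masked pixel its PC1
#' score. The loading sign is fixed so its largest-magnitude element is
#' positive, making scores reproducible across runs.
#'
#' @param cube A [hypercube].
#' @param mask A [roi_mask] (background removed).
#' @param window_nm `c(low, high)` wavelength window (nm).
#' @return Matrix of scores (NA outside the mask) with attribute `loading`.
#' @export
pc1_scores <- function(cube, mask, window_nm = range(cube$wavelengths)) {
  wl <- cube$wavelengths
  sel <- which(wl >= window_nm[1] & wl <= window_nm[2])
  if (length(sel) < 1L) stop("wavelength window selects no bands")
  idx <- which(mask$mask)
  if (length(idx) < 2L) stop("need at least 2 masked pixels")
  npix <- prod(dim(cube$values)[1:2])
  X <- sapply(sel, function(b) cube$values[idx + (b - 1) * npix])
  X <- matrix(X, nrow = length(idx))
  keep <- stats::complete.cases(X)
  Xc <- scale(X[keep, , drop = FALSE], center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-12)) stop("constant spectra: PC1 undefined")
  sv <- svd(Xc, nu = 0, nv = 1)
  v <- sv$v[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  scores <- matrix(NA_real_, nrow(mask$mask), ncol(mask$mask))
  sc <- rep(NA_real_, length(idx))
  sc[keep] <- Xc %*% v
  scores[idx] <- sc
  attr(scores, "loading") <- v
  attr(scores, "bands") <- wl[sel]
  scores
}

# Otsu threshold on a numeric vector: exhaustively maximizes between-class
# variance over a 256-bin histogram of min-max scaled values. Returns the
# threshold on the original scale (boundary between bins).
otsu_threshold <- function(values, bins = 256L) {
  v <- values[is.finite(values)]
  rng <- range(v)
  if (diff(rng) == 0) stop("constant values: Otsu threshold undefined")
  h <- tabulate(pmin(floor((v - rng[1]) / diff(rng) * bins) + 1L, bins), bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(bins))
  mu_t <- mu[bins]
  k <- seq_len(bins - 1L)
  denom <- omega[k] * (1 - omega[k])
  sigma_b2 <- ifelse(denom > 0, (mu_t * omega[k] - mu[k])^2 / denom, -Inf)
  k_star <- which.max(sigma_b2)
  rng[1] + k_star / bins * diff(rng)
}

#' Flesh mask by Otsu binarization of PC1 scores
#'
#' Thresholds the masked score image with Otsu's method (256-bin histogram)
#' and keeps the class that contains the median masked score, which for a
#' fruit scene is the flesh majority; achene speckles fall on the other
#' side.
#'
#' @param scores Score image from [pc1_scores].
#' @param mask The [roi_mask] the scores were computed on.
#' @return A [roi_mask] at stage `flesh`.
#' @export
otsu_flesh_mask <- function(scores, mask) {
  idx <- mask$mask & is.finite(scores)
  vals <- scores[idx]
  thr <- otsu_threshold(vals)
  med <- stats::median(vals)
  flesh <- if (med <= thr) idx & (scores <= thr) else idx & (scores > thr)
  roi_mask(flesh, "flesh",
           params_used = c(mask$params_used, list(otsu_threshold = thr)))
}

#' Segment flesh with an instrument preset
#'
#' Convenience wrapper running background threshold, PC1 scoring and Otsu
#' binarization with one of two named presets (the two acquisition systems
#' use different thresholding bands and PCA windows):
#' `preset_linescan`: reflectance at 1204 nm > 0.2, PCA window 1160-2168 nm.
#' `preset_rotation`: intensity at 1123 nm > 12000, PCA window 1476-1917 nm.
#'
#' @param cube Reflectance cube (linescan preset) or intensity cube
#'   (rotation preset).
#' @param preset `"preset_linescan"` or `"preset_rotation"`.
#' @return A flesh [roi_mask].
#' @export
segment_flesh <- function(cube, preset = c("preset_linescan", "preset_rotation")) {
  preset <- match.arg(preset)
  p <- switch(preset,
    preset_linescan = list(band_nm = 1204, threshold = 0.2,
                           window_nm = c(1160, 2168)),
    preset_rotation = list(band_nm = 1123, threshold = 12000,
                           window_nm = c(1476, 1917))
  )
  bg <- background_mask(cube, p$band_nm, p$threshold)
  sc <- pc1_scores(cube, bg, p$window_nm)
  otsu_flesh_mask(sc, bg)
}

#' Section-mean spectra (fruit top and bottom)
#'
#' Splits the flesh mask at its centroid along `apex_axis` and returns the
#' mean spectrum and pixel count of each half. The apex half is the one on
#' the low-index side (image top for `apex_axis = "row"`).
#'
#' @param cube A [hypercube].
#' @param flesh Flesh [roi_mask].
#' @param sample_id Identifier attached to the output rows.
#' @param apex_axis `"row"` (default) or `"column"`.
#' @return List of two records, each with `sample_id`, `section`,
#'   `spectrum` (per-band), `n_pixels`.
#' @export
section_mean_spectra <- function(cube, flesh, sample_id = "S1",
                                 apex_axis = c("row", "column")) {
  apex_axis <- match.arg(apex_axis)
  m <- flesh$mask
  if (!any(m)) stop("empty flesh mask")
  pos <- if (apex_axis == "row") row(m) else col(m)
  centroid <- mean(pos[m])
  halves <- list(top = m & (pos <= centroid), bottom = m & (pos > centroid))
  npix <- prod(dim(cube$values)[1:2])
  nb <- dim(cube$values)[3]
  lapply(names(halves), function(sec) {
    idx <- which(halves[[sec]])
    if (length(idx) == 0L) stop(sprintf("empty %s half", sec))
    spec <- vapply(seq_len(nb), function(b) {
      mean(cube$values[idx + (b - 1) * npix], na.rm = TRUE)
    }, numeric(1))
    list(sample_id = sample_id, section = sec, spectrum = spec,
         n_pixels = length(idx))
  })
}

#' Section masks (top/bottom halves of the flesh mask)
#'
#' @inheritParams section_mean_spectra
#' @return Named list of two logical matrices, `top` and `bottom`.
#' @export
section_masks <- function(flesh, apex_axis = c("row", "column")) {
  apex_axis <- match.arg(apex_axis)
  m <- flesh$mask
  if (!any(m)) stop("empty flesh mask")
  pos <- if (apex_axis == "row") row(m) else col(m)
  centroid <- mean(pos[m])
  list(top = m & (pos <= centroid), bottom = m & (pos > centroid))
}
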