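# Pixel-wise SSC mapping and 3D fusion.
#
# A calibrated model is applied to every flesh pixel of a corrected cube
# (after the identical preprocessing used in calibration); no spatial
# smoothing is applied to the resulting map, so its noise texture reflects
# the preprocessing pattern honestly. Maps are fused with the height map
# into simple point clouds for 3D display.

#' Extract flesh-pixel spectra as a matrix
#'
#' @param cube A [hypercube].
#' @param flesh Flesh [roi_mask] (or logical matrix).
#' @return Matrix (one row per flesh pixel) with attribute `pixel_idx`
#'   giving the linear pixel indices.
#' @export
flesh_spectra <- function(cube, flesh) {
  m <- if (inherits(flesh, "roi_mask")) flesh$mask else flesh
  idx <- which(m)
  if (!length(idx)) stop("empty flesh mask")
  d <- dim(cube$values)
  npix <- d[1] * d[2]
  X <- vapply(seq_len(d[3]), function(b) cube$values[idx + (b - 1) * npix],
              numeric(length(idx)))
  X <- matrix(X, nrow = length(idx))
  attr(X, "pixel_idx") <- idx
  X
}

#' Pixel-wise SSC prediction map
#'
#' Preprocesses each flesh pixel's spectrum with `spec` and predicts SSC
#' with the model. Pixels whose spectrum cannot be preprocessed (constant
#' spectrum under SNV) or contains NA (e.g. masked by the cosine floor) are
#' left undefined and counted.
#'
#' @param cube_corrected Reflectance [hypercube], corrected with the same
#'   geometry mode the model was calibrated on (checked when both carry a
#'   `correction`/`geometry_mode` tag).
#' @param flesh Flesh [roi_mask].
#' @param model A [pls_model].
#' @param spec A [preprocess_spec].
#' @return Object of class `ssc_map`: list with `values` (matrix, NA off
#'   flesh), `n_failed`, `pattern`, `geometry_mode`, plus the score matrix
#'   of defined pixels as `scores` and their linear indices `pixel_idx`.
#' @export
predict_map <- function(cube_corrected, flesh, model, spec = preprocess_spec("none")) {
  mode_cube <- cube_corrected$correction %||% NULL
  mode_model <- attr(model, "geometry_mode")
  if (!is.null(mode_cube) && !is.null(mode_model) && mode_cube != mode_model) {
    stop(sprintf("geometry-mode mismatch: cube '%s' vs model '%s'",
                 mode_cube, mode_model))
  }
  X <- flesh_spectra(cube_corrected, flesh)
  idx <- attr(X, "pixel_idx")
  Xp <- apply_pattern(X, spec)
  ok <- stats::complete.cases(Xp)
  vals <- matrix(NA_real_,
                 nrow(if (inherits(flesh, "roi_mask")) flesh$mask else flesh),
                 ncol(if (inherits(flesh, "roi_mask")) flesh$mask else flesh))
  pred <- rep(NA_real_, length(idx))
  scores <- NULL
  if (any(ok)) {
    pred[ok] <- predict(model, Xp[ok, , drop = FALSE])
    scores <- project_scores(model, Xp[ok, , drop = FALSE])
  }
  vals[idx] <- pred
  structure(
    list(values = vals, n_failed = sum(!ok),
         pattern = spec$pattern, geometry_mode = mode_cube,
         scores = scores, pixel_idx = idx[ok]),
    class = "ssc_map"
  )
}

#' @export
print.ssc_map <- function(x, ...) {
  cat(sprintf("<ssc_map> %d defined pixels (%d failed), pattern=%s, mode=%s\n",
              sum(!is.na(x$values)), x$n_failed, x$pattern,
              x$geometry_mode %||% "?"))
  invisible(x)
}

#' Region-averaged imaging SSC values
#'
#' Mean of the defined map pixels over each section mask (the imaging-side
#' counterpart of the reference juice measurements).
#'
#' @param map An [ssc_map].
#' @param sections Named list of logical matrices (see [section_masks]).
#' @return Named numeric vector of per-section means.
#' @export
region_imaging_values <- function(map, sections) {
  vapply(sections, function(s) {
    v <- map$values[s]
    v <- v[!is.na(v)]
    if (!length(v)) stop("section has no defined map pixels")
    mean(v)
  }, numeric(1))
}

#' Correlation between reference and imaging SSC values
#'
#' Pearson correlation over pooled (reference, imaging) section pairs of
#' the test set.
#'
#' @param imaging_values Numeric vector of section-averaged map predictions.
#' @param references Matching reference Brix values.
#' @return Scalar correlation coefficient.
#' @export
r_star <- function(imaging_values, references) {
  if (length(imaging_values) != length(references)) stop("length mismatch")
  if (length(imaging_values) < 3L) stop("need at least 3 paired values")
  if (stats::sd(imaging_values) == 0 || stats::sd(references) == 0) {
    stop("zero variance in one of the vectors")
  }
  stats::cor(imaging_values, references)
}

#' Fuse an SSC map with a height map into a point cloud (line scan)
#'
#' One 3D point per defined map pixel: x/y from pixel indices times the
#' pixel pitch, z from the height map, SSC attached as a per-point scalar.
#'
#' @param map An [ssc_map].
#' @param height Aligned [height_map].
#' @return Object of class `fruit_point_cloud`: `data.frame` of `x`, `y`,
#'   `z` (mm) and `ssc` plus a `source` attribute.
#' @export
fuse_line_scan <- function(map, height) {
  if (!all(dim(map$values) == dim(height$values))) stop("grid mismatch")
  idx <- which(!is.na(map$values), arr.ind = TRUE)
  pitch <- height$pixel_pitch_mm
  pc <- data.frame(
    x = (idx[, 2] - 0.5) * pitch,
    y = (idx[, 1] - 0.5) * pitch,
    z = height$values[idx],
    ssc = map$values[idx]
  )
  structure(pc, class = c("fruit_point_cloud", "data.frame"),
            source = "line")
}

#' Reconstruct a rotation-scan point cloud
#'
#' Each frame (map column) corresponds to an azimuth increment of
#' `turn_rate_deg_s / frame_rate_hz` degrees about the turntable axis; a
#' laser radius profile per frame places each row on the surface in
#' cylindrical coordinates, converted to Cartesian. Coverage short of a
#' full turn yields a warning and a partial cloud; frames beyond 360
#' degrees are dropped (first pass kept).
#'
#' @param map An [ssc_map] whose columns are frames and rows are heights
#'   along the rotation axis.
#' @param radius_profiles Matrix of laser radii (mm), same shape as the map
#'   (row = axial position, column = frame).
#' @param frame_rate_hz Camera frame rate (default 100).
#' @param turn_rate_deg_s Turntable rate in degrees per second (default 30).
#' @param axial_pitch_mm Axial distance between rows (mm).
#' @return A `fruit_point_cloud` with `source = "rotation"`; attribute
#'   `deg_per_frame` records the azimuth step.
#' @export
fuse_rotation_scan <- function(map, radius_profiles, frame_rate_hz = 100,
                               turn_rate_deg_s = 30, axial_pitch_mm = 1) {
  stop_if_not_scalar_pos(frame_rate_hz, "frame_rate_hz")
  stop_if_not_scalar_pos(turn_rate_deg_s, "turn_rate_deg_s")
  if (!all(dim(map$values) == dim(radius_profiles))) stop("grid mismatch")
  step <- turn_rate_deg_s / frame_rate_hz
  n_frames <- ncol(map$values)
  az <- (seq_len(n_frames) - 1L) * step
  if (max(az) + step < 360) {
    warning(sprintf("frames cover only %.1f degrees; partial cloud", max(az) + step))
  }
  keep_frames <- which(az < 360)
  idx <- which(!is.na(map$values[, keep_frames, drop = FALSE]), arr.ind = TRUE)
  if (!nrow(idx)) stop("no defined pixels to fuse")
  phi <- az[keep_frames][idx[, 2]] * pi / 180
  r <- radius_profiles[cbind(idx[, 1], keep_frames[idx[, 2]])]
  pc <- data.frame(
    x = r * cos(phi),
    y = r * sin(phi),
    z = (idx[, 1] - 0.5) * axial_pitch_mm,
    ssc = map$values[cbind(idx[, 1], keep_frames[idx[, 2]])]
  )
  structure(pc, class = c("fruit_point_cloud", "data.frame"),
            source = "rotation", deg_per_frame = step)
}

#' Write a point cloud as ASCII PLY
#'
#' Vertices carry `x`, `y`, `z` and a scalar property `ssc`.
#'
#' @param cloud A `fruit_point_cloud`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(cloud)),
    "property float x", "property float y", "property float z",
    "property float ssc", "end_header"
  ), con)
  writeLines(sprintf("%.4f %.4f %.4f %.4f",
                     cloud$x, cloud$y, cloud$z, cloud$ssc), con)
  invisible(path)
}
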