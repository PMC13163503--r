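# Radiometric calibration and shape-aware correction.
#
# The measured intensity of a curved Lambertian sample departs from that of
# the flat white panel in two ways: pixels above the panel plane sit at a
# different distance from the source (H1) and lens (H2), changing intensity
# roughly as an inverse-square product, and tilted surface elements return
# intensity attenuated by the cosine of the angle between the surface normal
# and the vertical. The corrections below invert each effect on the
# dark-subtracted intensity before converting to relative reflectance.

# Replicate a [column, band] reference across rows to match a cube's array.
expand_ref <- function(ref_mat, n_row) {
  d <- dim(ref_mat)
  aperm(array(ref_mat, dim = c(d[1], d[2], n_row)), c(3, 1, 2))
}

check_ref_dims <- function(cube, mat, what) {
  d <- dim(cube$values)
  if (nrow(mat) != d[2] || ncol(mat) != d[3]) {
    stop(sprintf("%s must be a [column x band] matrix matching the cube (%d x %d)",
                 what, d[2], d[3]))
  }
}

#' Resample a height map onto a cube's spatial grid
#'
#' Bilinear interpolation between cell centers, assuming height map and cube
#' cover the same physical extent (the instrument crops both to a common
#' landmark block before analysis). A map already on the cube grid is
#' returned unchanged.
#'
#' @param height A [height_map].
#' @param cube A [hypercube] defining the target grid.
#' @return A [height_map] on the cube's grid.
#' @export
align_height_to_cube <- function(height, cube) {
  d <- dim(cube$values)
  src <- height$values
  if (nrow(src) == d[1] && ncol(src) == d[2]) return(height)
  out <- bilinear_resize(src, d[1], d[2])
  pitch <- height$pixel_pitch_mm * nrow(src) / d[1]
  height_map(out, pixel_pitch_mm = pitch)
}

# Bilinear resize on cell-center coordinates; both grids span [0, 1].
bilinear_resize <- function(src, n_row, n_col) {
  r1 <- nrow(src); c1 <- ncol(src)
  # target cell centers in source index space (1..r1 at source centers)
  ri <- (seq_len(n_row) - 0.5) * r1 / n_row + 0.5
  ci <- (seq_len(n_col) - 0.5) * c1 / n_col + 0.5
  ri <- pmin(pmax(ri, 1), r1)
  ci <- pmin(pmax(ci, 1), c1)
  r0 <- pmin(floor(ri), r1 - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), c1 - 1L); fc <- ci - c0
  if (r1 == 1L) { r0 <- rep(1L, n_row); fr <- rep(0, n_row) }
  if (c1 == 1L) { c0 <- rep(1L, n_col); fc <- rep(0, n_col) }
  out <- matrix(0, n_row, n_col)
  for (j in seq_len(n_col)) {
    j0 <- c0[j]; j1 <- min(j0 + 1L, c1)
    a <- src[cbind(r0, rep(j0, n_row))]
    b <- src[cbind(pmin(r0 + 1L, r1), rep(j0, n_row))]
    cc <- src[cbind(r0, rep(j1, n_row))]
    dd <- src[cbind(pmin(r0 + 1L, r1), rep(j1, n_row))]
    out[, j] <- (1 - fr) * (1 - fc[j]) * a + fr * (1 - fc[j]) * b +
      (1 - fr) * fc[j] * cc + fr * fc[j] * dd
  }
  out
}

#' Convert intensity to relative reflectance
#'
#' Standard white/dark calibration: `R = (I - D) / (W - D)` per detector
#' column and band. Cubes produced by the intensity-stage corrections carry
#' `dark_removed = TRUE` and are divided by `W - D` without subtracting the
#' dark frame a second time.
#'
#' @param cube Intensity [hypercube].
#' @param white Single-height [white_reference].
#' @param dark [dark_reference].
#' @return Reflectance [hypercube].
#' @export
compute_reflectance <- function(cube, white, dark) {
  if (cube$kind != "intensity") stop("cube must be an intensity cube")
  if (is_white_stack(white)) {
    stop("compute_reflectance requires a single-height white reference")
  }
  check_ref_dims(cube, white$values, "white reference")
  check_ref_dims(cube, dark$values, "dark reference")
  denom <- white$values - dark$values
  if (any(denom <= 0)) {
    bad <- which(denom <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("white - dark <= 0 at column %d, band %d", bad[1], bad[2]))
  }
  d <- dim(cube$values)
  denom_arr <- expand_ref(denom, d[1])
  num <- if (isTRUE(cube$dark_removed)) cube$values else
    cube$values - expand_ref(dark$values, d[1])
  out <- hypercube(num / denom_arr, cube$wavelengths,
                   kind = "reflectance", scan_mode = cube$scan_mode)
  out$correction <- cube$correction %||% "none"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inverse-square height attenuation factor
#'
#' `((H1 + Hs) / H1)^2 * ((H2 + Hs) / H2)^2`: the factor by which the
#' dark-subtracted intensity of a pixel at height `Hs` above the panel plane
#' is multiplied to refer it back to panel-plane illumination and viewing
#' distance. Strictly increasing in `Hs`; equals 1 at the panel plane.
#'
#' @param Hs_mm Pixel height(s) above the white-panel plane (mm); vectorized.
#' @param params [geometry_params] supplying `H1_mm`, `H2_mm`.
#' @return Numeric factor(s).
#' @export
height_factor <- function(Hs_mm, params = geometry_params()) {
  Hs <- params$height_sign * Hs_mm
  if (any(params$H1_mm + Hs <= 0, na.rm = TRUE) ||
      any(params$H2_mm + Hs <= 0, na.rm = TRUE)) {
    stop("degenerate geometry: H1 + Hs and H2 + Hs must be positive")
  }
  ((params$H1_mm + Hs) / params$H1_mm)^2 *
    ((params$H2_mm + Hs) / params$H2_mm)^2
}

#' Height-correct a cube's intensities (closed-form model)
#'
#' `I'_h = (I - D) * height_factor(Hs)` per pixel. The result carries
#' `dark_removed = TRUE`; convert to reflectance with [compute_reflectance].
#'
#' @param cube Intensity [hypercube].
#' @param dark [dark_reference].
#' @param height [height_map] aligned to the cube grid.
#' @param params [geometry_params].
#' @return Corrected intensity [hypercube].
#' @export
height_correct_intensity <- function(cube, dark, height,
                                     params = geometry_params()) {
  if (cube$kind != "intensity") stop("cube must be an intensity cube")
  check_ref_dims(cube, dark$values, "dark reference")
  d <- dim(cube$values)
  hv <- height$values
  if (nrow(hv) != d[1] || ncol(hv) != d[2]) {
    stop("height map not aligned to cube grid; call align_height_to_cube()")
  }
  Hs <- params$height_sign * hv
  ok <- (params$H1_mm + Hs > 0) & (params$H2_mm + Hs > 0)
  g <- matrix(NA_real_, d[1], d[2])
  g[ok] <- ((params$H1_mm + Hs[ok]) / params$H1_mm)^2 *
    ((params$H2_mm + Hs[ok]) / params$H2_mm)^2
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warning(sprintf("%d pixel(s) with degenerate geometry masked", n_bad))
  }
  num <- if (isTRUE(cube$dark_removed)) cube$values else
    cube$values - expand_ref(dark$values, d[1])
  out_vals <- num * array(g, dim = d)   # g recycles over bands
  out <- hypercube(out_vals, cube$wavelengths, kind = "intensity",
                   scan_mode = cube$scan_mode)
  out$dark_removed <- TRUE
  out$correction <- "height"
  out$n_masked <- n_bad
  out
}

#' Interpolate a white-reference stack to arbitrary heights
#'
#' Linear interpolation along the height axis of a stack of white-panel
#' measurements; heights outside the measured range are clamped to the
#' nearest measured slab (the panel was only measured over a finite range,
#' so extrapolation is not attempted).
#'
#' @param white Stack [white_reference] (`[height, column, band]`).
#' @param Hs_mm Scalar height (mm).
#' @param column Optional detector column; if `NULL` the full
#'   `[column, band]` matrix at that height is returned, otherwise the
#'   per-band vector for that column.
#' @return Matrix `[column, band]` or numeric vector of per-band values.
#' @export
interpolated_white <- function(white, Hs_mm, column = NULL) {
  if (!is_white_stack(white)) stop("`white` must be a height stack")
  h <- white$heights_mm
  nh <- length(h)
  if (nh == 0L) stop("empty white stack")
  Hs <- min(max(Hs_mm, h[1]), h[nh])        # clamp
  k <- findInterval(Hs, h, rightmost.closed = TRUE)
  k <- min(max(k, 1L), nh - 1L)
  if (nh == 1L) {
    w <- white$values[1, , ]
  } else {
    f <- (Hs - h[k]) / (h[k + 1] - h[k])
    w <- (1 - f) * white$values[k, , ] + f * white$values[k + 1, , ]
  }
  w <- matrix(w, nrow = dim(white$values)[2])
  if (is.null(column)) w else w[column, ]
}

#' Height-correct intensities via an interpolated white-reference stack
#'
#' Empirical variant of the height correction: instead of the closed-form
#' inverse-square factor, the white reference measured at the pixel's own
#' height replaces the panel-plane white, i.e.
#' `I'_h = (I - D) * (W0 - D) / (W(Hs) - D)` so that dividing by `W0 - D`
#' afterwards yields `R = (I - D) / (W(Hs) - D)`.
#'
#' @param cube Intensity [hypercube].
#' @param dark [dark_reference].
#' @param white Stack [white_reference].
#' @param height Aligned [height_map].
#' @param params [geometry_params] (`height_sign` honored).
#' @return Corrected intensity [hypercube] (`dark_removed = TRUE`).
#' @export
height_correct_interp <- function(cube, dark, white, height,
                                  params = geometry_params()) {
  if (!is_white_stack(white)) stop("`white` must be a height stack")
  d <- dim(cube$values)
  hv <- params$height_sign * height$values
  if (nrow(hv) != d[1] || ncol(hv) != d[2]) {
    stop("height map not aligned to cube grid")
  }
  w0 <- interpolated_white(white, 0)
  denom0 <- w0 - dark$values
  num <- if (isTRUE(cube$dark_removed)) cube$values else
    cube$values - expand_ref(dark$values, d[1])
  out_vals <- array(NA_real_, d)
  # group pixels by quantized height to limit interpolation calls
  hq <- round(hv, 3)
  for (hval in unique(as.vector(hq))) {
    sel <- which(hq == hval, arr.ind = TRUE)
    wh <- interpolated_white(white, hval)
    ratio <- denom0 / (wh - dark$values)     # [column, band]
    for (b in seq_len(d[3])) {
      out_vals[cbind(sel, b)] <- num[cbind(sel, b)] * ratio[cbind(sel[, 2], b)]
    }
  }
  out <- hypercube(out_vals, cube$wavelengths, kind = "intensity",
                   scan_mode = cube$scan_mode)
  out$dark_removed <- TRUE
  out$correction <- "height"
  out
}

#' Surface angle from a height map
#'
#' Angle between the surface normal and the vertical, computed from height
#' gradients by central differences with edge replication. The default
#' follows the line-scan instrument convention of using only the width
#' (column) direction; `gradient = "full"` uses the full 2D gradient.
#'
#' @param height Aligned [height_map].
#' @param gradient `"width"` (default) or `"full"`.
#' @return An [angle_map].
#' @export
surface_angle <- function(height, gradient = c("width", "full")) {
  gradient <- match.arg(gradient)
  hv <- height$values
  pitch <- height$pixel_pitch_mm
  if (ncol(hv) < 3 && gradient == "width") {
    stop("width-only gradient needs at least 3 columns")
  }
  gx <- central_diff(hv, along = "col") / pitch
  if (gradient == "width") {
    theta <- atan(abs(gx))
  } else {
    gy <- central_diff(hv, along = "row") / pitch
    theta <- atan(sqrt(gx^2 + gy^2))
  }
  angle_map(theta)
}

central_diff <- function(m, along = c("col", "row")) {
  along <- match.arg(along)
  if (along == "row") return(t(central_diff(t(m), "col")))
  n <- ncol(m)
  if (n == 1L) return(matrix(0, nrow(m), 1L))
  left <- m[, c(1L, seq_len(n - 1L)), drop = FALSE]
  right <- m[, c(seq_len(n)[-1L], n), drop = FALSE]
  span <- matrix(rep(c(1, rep(2, max(n - 2L, 0L)), 1), each = nrow(m)),
                 nrow(m), n)
  (right - left) / span
}

#' Lambertian cosine correction of intensities
#'
#' `I'_a = (I - D) / cos(theta)` for pixels whose `cos(theta)` is at least
#' `params$cos_floor`; steeper pixels are masked (set `NA`) and counted
#' rather than amplified without bound.
#'
#' @param cube Intensity [hypercube] (raw, or height-corrected with
#'   `dark_removed = TRUE`).
#' @param dark [dark_reference].
#' @param theta [angle_map] on the cube grid.
#' @param params [geometry_params].
#' @return Corrected intensity [hypercube]; `n_masked` counts floored pixels.
#' @export
angle_correct_intensity <- function(cube, dark, theta,
                                    params = geometry_params()) {
  if (cube$kind != "intensity") stop("cube must be an intensity cube")
  d <- dim(cube$values)
  th <- theta$theta
  if (nrow(th) != d[1] || ncol(th) != d[2]) stop("angle map not on cube grid")
  ct <- cos(th)
  ct[ct < params$cos_floor] <- NA_real_
  n_bad <- sum(is.na(ct))
  num <- if (isTRUE(cube$dark_removed)) cube$values else
    cube$values - expand_ref(dark$values, d[1])
  out_vals <- num / array(ct, dim = d)
  out <- hypercube(out_vals, cube$wavelengths, kind = "intensity",
                   scan_mode = cube$scan_mode)
  out$dark_removed <- TRUE
  out$correction <- if (isTRUE(cube$correction == "height")) "height_angle" else "angle"
  out$n_masked <- n_bad
  out
}

#' Combined height and angle correction
#'
#' `I'_ha = I'_h / cos(theta)`: the height correction followed by the
#' Lambertian cosine correction on the intensity stage. Identical to
#' composing [height_correct_intensity] and [angle_correct_intensity].
#'
#' @inheritParams angle_correct_intensity
#' @param height Aligned [height_map].
#' @return Corrected intensity [hypercube].
#' @export
combined_correct <- function(cube, dark, height, theta,
                             params = geometry_params()) {
  hc <- height_correct_intensity(cube, dark, height, params)
  angle_correct_intensity(hc, dark, theta, params)
}

#' Correct a cube and convert to reflectance in one call
#'
#' Dispatcher over the four correction modes (`none`, `height`, `angle`,
#' `height_angle`); applies the requested intensity-stage correction then
#' white/dark calibration. When `white` is a height stack the empirical
#' interpolated-white height correction is used; otherwise the closed-form
#' inverse-square model.
#'
#' @param cube Intensity [hypercube].
#' @param dark [dark_reference].
#' @param white [white_reference] (single height or stack).
#' @param height Aligned [height_map] (required unless mode `none`/`angle`).
#' @param params [geometry_params]; `params$mode` selects the correction.
#' @param theta Optional precomputed [angle_map]; derived from `height`
#'   otherwise.
#' @return Reflectance [hypercube] with `correction` recording the mode.
#' @export
correct_cube <- function(cube, dark, white, height = NULL,
                         params = geometry_params(), theta = NULL) {
  mode <- params$mode
  needs_height <- mode %in% c("height", "height_angle")
  needs_angle <- mode %in% c("angle", "height_angle")
  if ((needs_height || needs_angle) && is.null(height)) {
    stop(sprintf("mode '%s' requires a height map", mode))
  }
  if (needs_angle && is.null(theta)) theta <- surface_angle(height)
  white0 <- if (is_white_stack(white)) {
    white_reference(interpolated_white(white, 0))
  } else white
  stage <- cube
  if (needs_height) {
    stage <- if (is_white_stack(white)) {
      height_correct_interp(stage, dark, white, height, params)
    } else {
      height_correct_intensity(stage, dark, height, params)
    }
  }
  if (needs_angle) {
    stage <- angle_correct_intensity(stage, dark, theta, params)
  }
  out <- compute_reflectance(stage, white0, dark)
  out$correction <- mode
  out
}
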