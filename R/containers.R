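# Core data containers. Lightweight S3: each is a validated list, printed
# compactly. Spatial convention throughout the package:
#   cube$values[i_scan, i_width, band]  -- rows are scan lines, columns are
#   detector positions across the scan width, third axis is wavelength.
# Dark and white references are indexed per detector column and band only.

#' Construct a hyperspectral cube
#'
#' @param values Numeric 3D array `[row, column, band]`.
#' @param wavelengths Strictly increasing numeric vector of band centers (nm);
#'   length must equal `dim(values)[3]`.
#' @param kind `"intensity"` (raw counts) or `"reflectance"`.
#' @param scan_mode `"line"` or `"rotation"`; informational.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(values, wavelengths,
                      kind = c("intensity", "reflectance"),
                      scan_mode = c("line", "rotation")) {
  kind <- match.arg(kind)
  scan_mode <- match.arg(scan_mode)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array [row, column, band]")
  }
  if (any(dim(values)[1:2] < 1L)) stop("spatial dimensions must be >= 1")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(values)[3]) {
    stop("length(wavelengths) must equal the number of bands")
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("`wavelengths` must be strictly increasing")
  }
  structure(
    list(values = values, wavelengths = wavelengths,
         kind = kind, scan_mode = scan_mode),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.0f-%.0f nm), kind=%s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$kind))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$values)

#' Dark reference (closed-shutter counts per detector column and band)
#'
#' @param values Numeric matrix `[column, band]`.
#' @return Object of class `dark_reference`.
#' @export
dark_reference <- function(values) {
  values <- as.matrix(values)
  structure(list(values = values), class = "dark_reference")
}

#' White reference (reflectance standard counts)
#'
#' Either a single-height reference (matrix `[column, band]`) or a stack of
#' references measured at several panel heights (array
#' `[height, column, band]` with strictly increasing `heights_mm`), as used
#' by the interpolated-white height correction.
#'
#' @param values Matrix `[column, band]` or 3D array `[height, column, band]`.
#' @param heights_mm Heights (mm above the panel plane) for a stack; `NULL`
#'   for a single-height reference.
#' @return Object of class `white_reference`.
#' @export
white_reference <- function(values, heights_mm = NULL) {
  if (is.matrix(values)) {
    if (!is.null(heights_mm) && length(heights_mm) != 1L) {
      stop("matrix white reference takes at most one height")
    }
  } else if (is.array(values) && length(dim(values)) == 3L) {
    if (is.null(heights_mm) || length(heights_mm) != dim(values)[1]) {
      stop("stack white reference requires one height per slab")
    }
    if (any(diff(heights_mm) <= 0)) {
      stop("stack heights must be strictly increasing")
    }
  } else {
    stop("`values` must be a [column, band] matrix or [height, column, band] array")
  }
  structure(list(values = values, heights_mm = heights_mm),
            class = "white_reference")
}

is_white_stack <- function(white) {
  length(dim(white$values)) == 3L
}

#' Per-pixel surface height map
#'
#' Heights are in millimetres relative to the white-panel plane (panel = 0).
#'
#' @param values Numeric matrix of heights (mm), same spatial grid as the
#'   cube after alignment.
#' @param pixel_pitch_mm Physical size of one pixel (mm), needed to convert
#'   height gradients to surface angles.
#' @return Object of class `height_map`.
#' @export
height_map <- function(values, pixel_pitch_mm = 1) {
  values <- as.matrix(values)
  stop_if_not_scalar_pos(pixel_pitch_mm, "pixel_pitch_mm")
  structure(list(values = values, pixel_pitch_mm = pixel_pitch_mm),
            class = "height_map")
}

#' Geometry parameters for radiometric shape correction
#'
#' @param H1_mm Light-source to white-panel distance (mm); default 100.
#' @param H2_mm Lens to white-panel distance (mm); default 200.
#' @param mode Correction mode: `"none"`, `"height"`, `"angle"` or
#'   `"height_angle"`.
#' @param cos_floor Minimum usable cosine of the surface angle; pixels below
#'   it are masked rather than divided by a near-zero cosine. Default 0.2.
#' @param height_sign +1 to use heights as stored, -1 to negate them for
#'   instruments with the opposite height convention.
#' @return Object of class `geometry_params`.
#' @export
geometry_params <- function(H1_mm = 100, H2_mm = 200,
                            mode = c("none", "height", "angle", "height_angle"),
                            cos_floor = 0.2, height_sign = 1) {
  mode <- match.arg(mode)
  stop_if_not_scalar_pos(H1_mm, "H1_mm")
  stop_if_not_scalar_pos(H2_mm, "H2_mm")
  if (!is.numeric(cos_floor) || cos_floor <= 0 || cos_floor >= 1) {
    stop("`cos_floor` must lie in (0, 1)")
  }
  if (!height_sign %in% c(-1, 1)) stop("`height_sign` must be +1 or -1")
  structure(list(H1_mm = H1_mm, H2_mm = H2_mm, mode = mode,
                 cos_floor = cos_floor, height_sign = height_sign),
            class = "geometry_params")
}

#' Surface angle map
#'
#' Angle (radians) between the surface normal and the vertical viewing
#' direction, per pixel; 0 on flat regions.
#'
#' @param theta Numeric matrix of angles in `[0, pi/2]`.
#' @return Object of class `angle_map`.
#' @export
angle_map <- function(theta) {
  theta <- as.matrix(theta)
  if (any(theta < 0 | theta > pi / 2 + 1e-12, na.rm = TRUE)) {
    stop("angles must lie in [0, pi/2]")
  }
  structure(list(theta = theta), class = "angle_map")
}
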