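# Synthetic strawberry-like phantoms with known ground truth.
#
# A phantom is an ellipsoidal (or flat-disc) Lambertian fruit on a dark
# belt, imaged by a line-scan NIR system. The forward model applies, per
# pixel and band,
#
#   I = D + (W - D) * R_true * cos(theta) / g(Hs) + noise
#
# where g is the inverse-square height factor and theta the surface angle
# computed from the phantom's own height map with the same width-only
# finite-difference convention the correction chain uses, so that the
# correction chain inverts the distortion exactly in the noise-free case.
# True reflectance follows a Beer-Lambert-style continuum with Gaussian
# absorption features; the depths of the sugar-related features (1165 and
# 1780 nm) scale linearly with the local soluble-solids content, giving the
# regression something real to recover. Achenes (the seed speckles) get a
# flat high-reflectance signature so that a PC1 score separates them from
# flesh.

#' Phantom scene configuration
#'
#' Defaults describe a medium strawberry (50 x 40 x 30 mm) on a 64 x 64
#' grid at 1 mm pitch, imaged over 913-2166 nm in 200 bands, with an
#' apex-to-base SSC gradient from 12 to 8 Brix, water absorption features at
#' 970/1420/1900 nm and sugar-related features at 1165/1780 nm.
#'
#' @param shape_mode `"ellipsoid"` or `"flat_disc"` (disc lies in the panel
#'   plane: identity geometry).
#' @param semi_axes_mm Semi-axes (mm): along rows (apex-base), along columns
#'   (width), and height.
#' @param n_rows,n_cols Grid size in pixels.
#' @param pixel_pitch_mm Pixel size (mm).
#' @param wavelength_axis Band centers in nm, strictly increasing.
#' @param ssc_apex_brix,ssc_base_brix SSC (Brix) at fruit apex (image top)
#'   and base; both in [0, 30].
#' @param absorption_centers_nm,absorption_widths_nm,absorption_strengths
#'   Gaussian absorbance features of the flesh spectrum.
#' @param sugar_bands Indices into the absorption features whose strength is
#'   SSC-coupled (default the 1165 and 1780 nm features).
#' @param ssc_coupling Fractional change of sugar-feature strength per Brix
#'   about a 10 Brix reference (default 0.08).
#' @param achene_density Fraction of silhouette pixels carrying an achene.
#' @param noise_sd Additive Gaussian noise sd on intensity counts.
#' @param H1_mm,H2_mm Source and lens distances to the panel plane (mm).
#' @param dark_level,white_level Detector counts for the dark frame and the
#'   white panel peak.
#' @param seed Integer seed; the scene is deterministic given the config.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape_mode = c("ellipsoid", "flat_disc"),
                           semi_axes_mm = c(25, 20, 15),
                           n_rows = 64, n_cols = 64,
                           pixel_pitch_mm = 1,
                           wavelength_axis = seq(913, 2166, length.out = 200),
                           ssc_apex_brix = 12, ssc_base_brix = 8,
                           absorption_centers_nm = c(970, 1165, 1420, 1780, 1900),
                           absorption_widths_nm = c(40, 35, 45, 35, 40),
                           absorption_strengths = c(0.35, 0.20, 0.55, 0.18, 0.85),
                           sugar_bands = c(2L, 4L),
                           ssc_coupling = 0.08,
                           achene_density = 0.03,
                           noise_sd = 20,
                           H1_mm = 100, H2_mm = 200,
                           dark_level = 1000, white_level = 9000,
                           seed = 1L) {
  shape_mode <- match.arg(shape_mode)
  stopifnot(length(semi_axes_mm) == 3L, all(is.finite(semi_axes_mm)),
            all(semi_axes_mm > 0))
  stop_if_not_scalar_pos(pixel_pitch_mm, "pixel_pitch_mm")
  wavelength_axis <- as.numeric(wavelength_axis)
  if (any(!is.finite(wavelength_axis)) || any(diff(wavelength_axis) <= 0)) {
    stop("`wavelength_axis` must be finite and strictly increasing")
  }
  for (v in c(ssc_apex_brix, ssc_base_brix)) {
    if (!is.finite(v) || v < 0 || v > 30) stop("SSC must lie in [0, 30] Brix")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (achene_density < 0 || achene_density > 1) {
    stop("`achene_density` must lie in [0, 1]")
  }
  nf <- length(absorption_centers_nm)
  stopifnot(length(absorption_widths_nm) == nf,
            length(absorption_strengths) == nf,
            all(sugar_bands %in% seq_len(nf)))
  stop_if_not_scalar_pos(H1_mm, "H1_mm"); stop_if_not_scalar_pos(H2_mm, "H2_mm")
  structure(
    list(shape_mode = shape_mode, semi_axes_mm = semi_axes_mm,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pixel_pitch_mm = pixel_pitch_mm,
         wavelength_axis = wavelength_axis,
         ssc_apex_brix = ssc_apex_brix, ssc_base_brix = ssc_base_brix,
         absorption_centers_nm = absorption_centers_nm,
         absorption_widths_nm = absorption_widths_nm,
         absorption_strengths = absorption_strengths,
         sugar_bands = as.integer(sugar_bands),
         ssc_coupling = ssc_coupling,
         achene_density = achene_density, noise_sd = noise_sd,
         H1_mm = H1_mm, H2_mm = H2_mm,
         dark_level = dark_level, white_level = white_level,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Flesh absorbance spectrum at a given SSC (vectorized over wavelength).
flesh_absorbance <- function(wl, config, ssc) {
  s <- config$absorption_strengths
  s[config$sugar_bands] <- s[config$sugar_bands] *
    (1 + config$ssc_coupling * (ssc - 10))
  s <- pmax(s, 0)
  a <- numeric(length(wl))
  for (f in seq_along(s)) {
    a <- a + s[f] * exp(-(wl - config$absorption_centers_nm[f])^2 /
                          (2 * config$absorption_widths_nm[f]^2))
  }
  a
}

# Smooth reflectance continuum of flesh before absorption.
flesh_continuum <- function(wl) {
  0.85 - 0.10 * (wl - min(wl)) / max(diff(range(wl)), 1)
}

BACKGROUND_REFLECTANCE <- 0.05
ACHENE_REFLECTANCE <- 0.70

#' Generate a phantom scene
#'
#' Builds geometry (silhouette, height map), the true SSC field (linear
#' apex-to-base gradient over the silhouette), true reflectance per pixel
#' and band, achene speckles, and the measured intensity cube under the
#' forward model described in the package vignette. Deterministic given
#' `config$seed`.
#'
#' @param config A [phantom_config].
#' @param sample_id Identifier stored in the scene (default "P1").
#' @return An object of class `phantom_scene`: list with elements `cube`
#'   (intensity [hypercube]), `height` ([height_map]), `white`
#'   ([white_reference]), `dark` ([dark_reference]), `true_reflectance`
#'   (3D array), `true_ssc_map` (matrix, NA outside the fruit),
#'   `achene_mask`, `flesh_mask`, `silhouette`, `theta` ([angle_map]),
#'   `sample_id`, `config`.
#' @export
make_phantom <- function(config = phantom_config(), sample_id = "P1") {
  wl <- config$wavelength_axis
  nr <- config$n_rows; nc <- config$n_cols; nb <- length(wl)
  pitch <- config$pixel_pitch_mm
  ax <- config$semi_axes_mm
  # pixel-center coordinates relative to grid center (mm)
  y <- (seq_len(nr) - (nr + 1) / 2) * pitch   # along rows (apex-base)
  x <- (seq_len(nc) - (nc + 1) / 2) * pitch   # along columns (width)
  if (2 * ax[1] > nr * pitch || 2 * ax[2] > nc * pitch) {
    stop("grid too small to contain the ellipsoid")
  }
  yy <- matrix(y, nr, nc); xx <- matrix(x, nr, nc, byrow = TRUE)
  rad2 <- (yy / ax[1])^2 + (xx / ax[2])^2
  silhouette <- rad2 <= 1
  hs <- matrix(0, nr, nc)
  if (config$shape_mode == "ellipsoid") {
    hs[silhouette] <- ax[3] * sqrt(pmax(1 - rad2[silhouette], 0))
  }
  height <- height_map(hs, pixel_pitch_mm = pitch)
  theta <- surface_angle(height)

  # true SSC: linear gradient from apex row (top) to base row over silhouette
  ssc <- matrix(NA_real_, nr, nc)
  frows <- range(which(rowSums(silhouette) > 0))
  t_row <- if (frows[2] > frows[1]) {
    (row(ssc) - frows[1]) / (frows[2] - frows[1])
  } else matrix(0, nr, nc)
  grad <- config$ssc_apex_brix + (config$ssc_base_brix - config$ssc_apex_brix) * t_row
  ssc[silhouette] <- grad[silhouette]

  scene_rng <- with_seed(config$seed, {
    ach <- matrix(stats::runif(nr * nc) < config$achene_density, nr, nc) & silhouette
    noise <- if (config$noise_sd > 0) {
      array(stats::rnorm(nr * nc * nb, sd = config$noise_sd), c(nr, nc, nb))
    } else 0
    list(achene = ach, noise = noise)
  })
  achene <- scene_rng$achene
  flesh <- silhouette & !achene

  # true reflectance cube
  refl <- array(BACKGROUND_REFLECTANCE, c(nr, nc, nb))
  cont <- flesh_continuum(wl)
  flesh_idx <- which(flesh)
  if (length(flesh_idx)) {
    # absorbance is linear in SSC, so build from two endpoint spectra
    a0 <- flesh_absorbance(wl, config, 0)
    a1 <- flesh_absorbance(wl, config, 1)
    dssc <- a1 - a0
    ssc_f <- ssc[flesh_idx]
    for (b in seq_len(nb)) {
      refl[flesh_idx + (b - 1) * nr * nc] <-
        cont[b] * exp(-(a0[b] + dssc[b] * ssc_f))
    }
  }
  ach_idx <- which(achene)
  for (b in seq_len(nb)) {
    refl[ach_idx + (b - 1) * nr * nc] <- ACHENE_REFLECTANCE
  }

  # references: white varies gently across columns and bands
  col_shade <- 1 - 0.05 * ((seq_len(nc) - (nc + 1) / 2) / ((nc + 1) / 2))^2
  band_slope <- 1 - 0.10 * (wl - min(wl)) / max(diff(range(wl)), 1)
  white_mat <- config$dark_level +
    (config$white_level - config$dark_level) * outer(col_shade, band_slope)
  dark_mat <- matrix(config$dark_level, nc, nb)
  white <- white_reference(white_mat)
  dark <- dark_reference(dark_mat)

  # forward model
  params <- geometry_params(H1_mm = config$H1_mm, H2_mm = config$H2_mm)
  g <- matrix(height_factor(as.vector(hs), params), nr, nc)
  ct <- cos(theta$theta)
  gain <- ct / g
  wd <- expand_ref(white_mat - dark_mat, nr)
  vals <- config$dark_level + wd * refl * array(gain, c(nr, nc, nb)) +
    scene_rng$noise
  cube <- hypercube(vals, wl, kind = "intensity", scan_mode = "line")

  structure(
    list(cube = cube, height = height, white = white, dark = dark,
         true_reflectance = refl, true_ssc_map = ssc,
         achene_mask = achene, flesh_mask = flesh, silhouette = silhouette,
         theta = theta, sample_id = sample_id, config = config),
    class = "phantom_scene"
  )
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> %s: %dx%d px, %d bands, %d flesh px, %d achenes\n",
              x$sample_id, nrow(x$flesh_mask), ncol(x$flesh_mask),
              length(x$cube$wavelengths), sum(x$flesh_mask),
              sum(x$achene_mask)))
  invisible(x)
}

#' White-reference stack consistent with a phantom's forward model
#'
#' White-panel measurements at a ladder of heights, derived from the scene's
#' panel-plane white by the same inverse-square factor the forward model
#' uses: `W(h) = D + (W0 - D) / g(h)`.
#'
#' @param scene A [phantom_scene].
#' @param heights_mm Measurement heights (default 0 to 30 mm by 2 mm).
#' @return A stack [white_reference].
#' @export
make_white_stack <- function(scene, heights_mm = seq(0, 30, by = 2)) {
  cfg <- scene$config
  params <- geometry_params(H1_mm = cfg$H1_mm, H2_mm = cfg$H2_mm)
  w0 <- scene$white$values; d0 <- scene$dark$values
  st <- array(0, c(length(heights_mm), nrow(w0), ncol(w0)))
  for (k in seq_along(heights_mm)) {
    st[k, , ] <- d0 + (w0 - d0) / height_factor(heights_mm[k], params)
  }
  white_reference(st, heights_mm = heights_mm)
}

#' Reference SSC table for a phantom (destructive measurement surrogate)
#'
#' Splits the flesh mask into apex (top) and base (bottom) halves at the
#' mask's row centroid and averages the true SSC field over each half,
#' mimicking the juice Brix measurement of the two fruit sections.
#'
#' @param scene A [phantom_scene].
#' @return `data.frame` with columns `sample_id`, `section` ("top"/"bottom"),
#'   `brix`.
#' @export
make_reference_table <- function(scene) {
  flesh <- scene$flesh_mask
  if (!any(flesh)) stop("empty flesh mask")
  rows <- row(flesh)[flesh]
  centroid <- mean(rows)
  top <- flesh & (row(flesh) <= centroid)
  bottom <- flesh & (row(flesh) > centroid)
  if (!any(top) || !any(bottom)) stop("degenerate flesh split")
  data.frame(
    sample_id = scene$sample_id,
    section = c("top", "bottom"),
    brix = c(mean(scene$true_ssc_map[top]), mean(scene$true_ssc_map[bottom])),
    stringsAsFactors = FALSE
  )
}

#' Generate a fleet of phantoms with fruit-to-fruit variation
#'
#' Draws per-fruit apex SSC ~ N(11.5, 1.5) truncated to [6, 16] and an
#' apex-base drop ~ N(3, 0.75) truncated to [0.5, 6] (apices are sweeter),
#' plus +/-10% size variation, then builds one scene per fruit with derived
#' seeds. Deterministic given `seed`.
#'
#' @param n Number of fruits.
#' @param config Base [phantom_config] (per-fruit fields overridden).
#' @param seed Root seed for the fleet.
#' @return List of [make_phantom] scenes with ids "F01", "F02", ...
#' @export
make_phantom_set <- function(n, config = phantom_config(), seed = 1L) {
  draws <- with_seed(seed, {
    list(
      apex = pmin(pmax(stats::rnorm(n, 11.5, 1.5), 6), 16),
      drop = pmin(pmax(stats::rnorm(n, 3, 0.75), 0.5), 6),
      size = stats::runif(n, 0.9, 1.1),
      sub_seed = sample.int(.Machine$integer.max - 1L, n)
    )
  })
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$ssc_apex_brix <- draws$apex[i]
    cfg$ssc_base_brix <- max(draws$apex[i] - draws$drop[i], 0)
    cfg$semi_axes_mm <- config$semi_axes_mm * draws$size[i]
    cfg$seed <- draws$sub_seed[i]
    make_phantom(cfg, sample_id = sprintf("F%02d", i))
  })
}
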