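test_that("compute_reflectance implements (I-D)/(W-D)", {
  n <- 4; nb <- 3
  dk <- const_dark(n, nb); wh <- const_white(n, nb)
  vw <- array(9000, c(n, n, nb))
  expect_equal(compute_reflectance(flat_cube(vw), wh, dk)$values,
               array(1, c(n, n, nb)))
  vd <- array(1000, c(n, n, nb))
  expect_equal(compute_reflectance(flat_cube(vd), wh, dk)$values,
               array(0, c(n, n, nb)))
  v5 <- array(5000, c(n, n, nb))
  expect_equal(compute_reflectance(flat_cube(v5), wh, dk)$values,
               array(0.5, c(n, n, nb)))
  # scale invariance: common gain on I, W, D leaves R unchanged
  g <- 3.7
  r1 <- compute_reflectance(flat_cube(v5), wh, dk)$values
  r2 <- compute_reflectance(
    flat_cube(v5 * g),
    white_reference(wh$values * g), dark_reference(dk$values * g))$values
  expect_equal(r1, r2)
  # offending band/column named on W - D <= 0
  bad <- wh$values; bad[2, 3] <- 999
  expect_error(compute_reflectance(flat_cube(v5), white_reference(bad), dk),
               "column 2, band 3")
})

test_that("height_factor matches the printed closed form and is monotone", {
  p <- geometry_params(H1_mm = 100, H2_mm = 200)
  expect_equal(height_factor(0, p), 1.0)
  expect_equal(height_factor(-10, p), 0.9^2 * 0.95^2)  # 0.731025
  expect_equal(height_factor(-10, p), 0.731025)
  hs <- seq(-50, 80, by = 0.5)
  expect_true(all(diff(height_factor(hs, p)) > 0))
  expect_error(height_factor(-100, p), "degenerate")
  # sign flag negates the height before applying the printed form
  pneg <- geometry_params(height_sign = -1)
  expect_equal(height_factor(10, pneg), height_factor(-10, p))
})

test_that("height correction scales dark-subtracted intensity by the factor", {
  n <- 5; nb <- 4
  dk <- const_dark(n, nb); wh <- const_white(n, nb)
  vals <- array(5000, c(n, n, nb))
  cube <- flat_cube(vals)
  hm0 <- height_map(matrix(0, n, n))
  out0 <- height_correct_intensity(cube, dk, hm0)
  expect_equal(out0$values, array(4000, c(n, n, nb)))
  expect_true(out0$dark_removed)
  hv <- matrix(0, n, n); hv[2, 3] <- -10
  out <- height_correct_intensity(cube, dk, height_map(hv))
  expect_equal(out$values[2, 3, 1], 4000 * 0.731025)
  expect_equal(out$values[1, 1, 1], 4000)
})

test_that("height correction removes distance-induced bias on a synthetic scene", {
  # constant true reflectance 0.5 over varying height; forward-distort with
  # the same model, then correct and calibrate: per-band variance ~ 0
  n <- 12; nb <- 5
  p <- geometry_params(mode = "height")
  hv <- matrix(seq(0, 20, length.out = n * n), n, n)
  dk <- const_dark(n, nb); wh <- const_white(n, nb)
  g <- matrix(height_factor(as.vector(hv), p), n, n)
  vals <- 1000 + 8000 * 0.5 / array(g, c(n, n, nb))
  refl <- correct_cube(flat_cube(vals), dk, wh, height_map(hv), p)
  for (b in seq_len(nb)) {
    expect_lt(stats::var(as.vector(refl$values[, , b])), 1e-10)
  }
  expect_equal(mean(refl$values), 0.5, tolerance = 1e-12)
})

test_that("interpolated white matches knots, midpoints and a brute-force oracle", {
  set.seed(8)
  st <- array(runif(5 * 3 * 4, 5000, 9000), c(5, 3, 4))
  wh <- white_reference(st, heights_mm = c(0, 2, 4, 8, 16))
  expect_equal(interpolated_white(wh, 4), st[3, , ])
  expect_equal(interpolated_white(wh, 3), (st[2, , ] + st[3, , ]) / 2)
  for (hs in runif(10, -2, 20)) {
    expect_equal(interpolated_white(wh, hs), brute_interp_white(wh, hs),
                 info = sprintf("Hs = %.3f", hs))
  }
  # clamped at the ends, column extraction consistent
  expect_equal(interpolated_white(wh, -5), st[1, , ])
  expect_equal(interpolated_white(wh, 99), st[5, , ])
  expect_equal(interpolated_white(wh, 3, column = 2),
               interpolated_white(wh, 3)[2, ])
})

test_that("surface_angle follows the width-only convention", {
  flat <- height_map(matrix(2, 6, 6))
  expect_equal(surface_angle(flat)$theta, matrix(0, 6, 6))
  # plane rising 1 mm per 1 mm pixel across the width -> 45 degrees
  ramp <- height_map(matrix(rep(1:8, each = 6), 6, 8), pixel_pitch_mm = 1)
  th <- surface_angle(ramp)$theta
  expect_equal(th[3, 4], pi / 4)
  # slope only along the scan direction: zero in width mode, > 0 in full
  scan_ramp <- height_map(matrix(rep(1:6, times = 8), 6, 8))
  expect_equal(surface_angle(scan_ramp)$theta, matrix(0, 6, 8))
  expect_gt(max(surface_angle(scan_ramp, "full")$theta), 0)
  expect_error(surface_angle(height_map(matrix(0, 4, 2))), "3 columns")
})

test_that("angle correction divides by the cosine and floors grazing pixels", {
  n <- 4; nb <- 2
  dk <- const_dark(n, nb)
  cube <- flat_cube(array(5000, c(n, n, nb)))
  th0 <- angle_map(matrix(0, n, n))
  expect_equal(angle_correct_intensity(cube, dk, th0)$values,
               array(4000, c(n, n, nb)))
  thm <- matrix(0, n, n); thm[1, 1] <- pi / 3; thm[2, 2] <- 1.45  # cos < 0.2
  out <- angle_correct_intensity(cube, dk, angle_map(thm))
  expect_equal(out$values[1, 1, 1], 8000)   # cos 60 deg = 0.5 doubles it
  expect_true(all(is.na(out$values[2, 2, ])))
  expect_equal(out$n_masked, 1L)
})

test_that("combined correction equals the composition and the identity cases", {
  sc <- make_phantom(small_cfg())
  p <- geometry_params()
  comp <- angle_correct_intensity(
    height_correct_intensity(sc$cube, sc$dark, sc$height, p),
    sc$dark, sc$theta, p)
  comb <- combined_correct(sc$cube, sc$dark, sc$height, sc$theta, p)
  expect_equal(comb$values, comp$values)
  # flat geometry: all four modes agree exactly
  fl <- make_phantom(small_cfg(shape_mode = "flat_disc"))
  outs <- lapply(c("none", "height", "angle", "height_angle"), function(m) {
    pm <- geometry_params(mode = m)
    correct_cube(fl$cube, fl$dark, fl$white, fl$height, pm)$values
  })
  for (k in 2:4) expect_equal(outs[[k]], outs[[1]], tolerance = 1e-12)
})

test_that("full correction chain inverts the phantom forward model", {
  sc <- make_phantom(small_cfg())
  refl <- correct_cube(sc$cube, sc$dark, sc$white, sc$height,
                       geometry_params(mode = "height_angle"))
  usable <- cos(sc$theta$theta) >= 0.2
  rel_err <- abs(refl$values - sc$true_reflectance) /
    abs(sc$true_reflectance)
  for (b in c(1, dim(rel_err)[3])) {
    expect_lt(max(rel_err[, , b][usable]), 1e-6)
  }
  # interpolated-white variant agrees at stack knots (heights quantized to
  # the measured ladder)
  hq <- height_map(2 * round(sc$height$values / 2), sc$height$pixel_pitch_mm)
  st <- make_white_stack(sc)
  ci <- height_correct_interp(sc$cube, sc$dark, st, hq)
  cf <- height_correct_intensity(sc$cube, sc$dark, hq)
  expect_equal(ci$values, cf$values, tolerance = 1e-9)
})

test_that("corrections commute with band subsetting", {
  sc <- make_phantom(small_cfg())
  p <- geometry_params(mode = "height_angle")
  full <- correct_cube(sc$cube, sc$dark, sc$white, sc$height, p)
  keep <- c(2, 5, 9)
  sub_cube <- hypercube(sc$cube$values[, , keep],
                        sc$cube$wavelengths[keep])
  sub_white <- white_reference(sc$white$values[, keep])
  sub_dark <- dark_reference(sc$dark$values[, keep])
  sub <- correct_cube(sub_cube, sub_dark, sub_white, sc$height, p)
  expect_equal(sub$values, full$values[, , keep])
})

test_that("post-correction spectral spread shrinks over the fruit cap", {
  # uniform-SSC fruit: all cap variation is geometric, so the corrected
  # coefficient of variation collapses to <= 1% of the uncorrected one
  sc <- make_phantom(small_cfg(ssc_apex_brix = 10, ssc_base_brix = 10))
  raw <- correct_cube(sc$cube, sc$dark, sc$white, sc$height,
                      geometry_params(mode = "none"))
  cor <- correct_cube(sc$cube, sc$dark, sc$white, sc$height,
                      geometry_params(mode = "height_angle"))
  cap <- sc$flesh_mask & cos(sc$theta$theta) >= 0.5
  cv <- function(x) stats::sd(x) / mean(x)
  for (b in c(5, 20)) {
    expect_lt(cv(cor$values[, , b][cap]), 0.01 * cv(raw$values[, , b][cap]))
  }
  # gradient fruit: spread still strictly decreases after correction
  sg <- make_phantom(small_cfg())
  rawg <- correct_cube(sg$cube, sg$dark, sg$white, sg$height,
                       geometry_params(mode = "none"))
  corg <- correct_cube(sg$cube, sg$dark, sg$white, sg$height,
                       geometry_params(mode = "height_angle"))
  capg <- sg$flesh_mask & cos(sg$theta$theta) >= 0.5
  expect_lt(stats::sd(corg$values[, , 10][capg]),
            stats::sd(rawg$values[, , 10][capg]))
})

test_that("height maps align onto cube grids", {
  cube <- flat_cube(array(0, c(6, 6, 2)))
  hm <- height_map(matrix(1:36, 6, 6))
  expect_identical(align_height_to_cube(hm, cube), hm)
  # 2x oversampled constant map stays constant
  big <- height_map(matrix(5, 12, 12), pixel_pitch_mm = 0.5)
  al <- align_height_to_cube(big, cube)
  expect_equal(al$values, matrix(5, 6, 6))
  expect_equal(al$pixel_pitch_mm, 1)
  # linear ramp resampled matches the analytic ramp at cell centers
  src <- matrix(rep(seq(0, 11), each = 12), 12, 12)  # h = column index - 1
  al2 <- align_height_to_cube(height_map(src, 0.5), cube)
  # target column j center lies at source coordinate (j - 0.5) * 2 + 0.5,
  # where the ramp value is that coordinate minus 1
  expected <- (seq_len(6) - 0.5) * 2 + 0.5 - 1
  for (j in 2:5) expect_equal(al2$values[3, j], expected[j])
})

test_that("ENVI round trip preserves cubes", {
  sc <- make_phantom(small_cfg(n_rows = 10, n_cols = 12,
                               semi_axes_mm = c(4, 4, 3),
                               wavelength_axis = seq(913, 2166, length.out = 7)))
  path <- file.path(tempdir(), "cube_roundtrip")
  write_envi(sc$cube, path)
  back <- read_envi(path)
  expect_equal(back$values, sc$cube$values)
  expect_equal(back$wavelengths, sc$cube$wavelengths, tolerance = 1e-6)
  expect_equal(back$kind, "intensity")
  unlink(paste0(path, c(".hdr", ".img")))
})
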