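toy_map_setup <- function(seed = 2, n_bands = 15) {
  set.seed(seed)
  X <- matrix(rnorm(24 * n_bands), 24, n_bands)
  y <- drop(X %*% rnorm(n_bands) * 0.3) + 10
  model <- fit_plsr(calibration_table(X, y, as.character(1:24)), 3)
  list(X = X, y = y, model = model, wl = seq(1000, 1000 + 10 * (n_bands - 1),
                                             by = 10))
}

test_that("predict_map predicts flesh pixels and respects the mask", {
  s <- toy_map_setup()
  # cube whose every pixel equals calibration spectrum 1
  nb <- length(s$wl)
  vals <- array(rep(s$X[1, ], each = 36), c(6, 6, nb))
  cube <- hypercube(vals, s$wl, kind = "reflectance")
  flesh <- roi_mask(matrix(c(TRUE, FALSE), 6, 6), "flesh")
  map <- predict_map(cube, flesh, s$model)
  yhat <- predict(s$model, s$X[1, , drop = FALSE])
  expect_equal(unique(map$values[flesh$mask]), yhat)
  expect_true(all(is.na(map$values[!flesh$mask])))
  expect_equal(map$n_failed, 0L)
  # SNV on a constant-spectrum pixel fails and is masked + counted
  vals2 <- vals; vals2[3, 1, ] <- 7   # constant spectrum on a flesh pixel
  map2 <- predict_map(hypercube(vals2, s$wl, kind = "reflectance"), flesh,
                      s$model, preprocess_spec("snv"))
  expect_equal(map2$n_failed, 1L)
  expect_true(is.na(map2$values[3, 1]))
  # geometry-mode mismatch is an error
  cube_h <- cube; cube_h$correction <- "height"
  m2 <- s$model; attr(m2, "geometry_mode") <- "none"
  expect_error(predict_map(cube_h, flesh, m2), "mismatch")
})

test_that("region_imaging_values averages defined pixels per section", {
  vals <- matrix(NA_real_, 6, 6)
  vals[1:3, 1:4] <- 8; vals[4:6, 1:4] <- 12
  map <- structure(list(values = vals), class = "ssc_map")
  secs <- list(top = row(vals) <= 3 & col(vals) <= 4,
               bottom = row(vals) > 3 & col(vals) <= 4)
  expect_equal(region_imaging_values(map, secs), c(top = 8, bottom = 12))
  # constant map
  vals2 <- matrix(5, 6, 6)
  expect_equal(region_imaging_values(structure(list(values = vals2),
                                               class = "ssc_map"), secs),
               c(top = 5, bottom = 5))
  # random map equals a brute-force masked loop
  set.seed(9)
  vr <- matrix(rnorm(36), 6, 6); vr[1, 5] <- NA
  mr <- structure(list(values = vr), class = "ssc_map")
  got <- region_imaging_values(mr, secs)
  for (sec in names(secs)) {
    acc <- 0; n <- 0
    for (i in 1:6) for (j in 1:6) {
      if (secs[[sec]][i, j] && !is.na(vr[i, j])) { acc <- acc + vr[i, j]; n <- n + 1 }
    }
    expect_equal(unname(got[sec]), acc / n)
  }
  expect_error(region_imaging_values(mr, list(empty = matrix(FALSE, 6, 6))),
               "no defined")
})

test_that("section means commute with prediction for linear patterns", {
  s <- toy_map_setup(seed = 5)
  nb <- length(s$wl)
  set.seed(5)
  pix <- matrix(rnorm(50 * nb), 50, nb)
  for (p in c("none", "smooth", "d1", "d2")) {
    spec <- preprocess_spec(p)
    mean_of_pred <- mean(predict(s$model, apply_pattern(pix, spec)))
    pred_of_mean <- predict(s$model,
                            apply_pattern(colMeans(pix), spec))
    expect_equal(mean_of_pred, pred_of_mean, tolerance = 1e-9,
                 label = sprintf("pattern %s commutation", p))
  }
})

test_that("r_star is the Pearson correlation of pooled pairs", {
  ref <- c(8, 9, 10, 11, 12)
  expect_equal(r_star(ref, ref), 1)
  expect_equal(r_star(-ref, ref), -1)
  set.seed(3)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(r_star(a, b),
               sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))
  expect_error(r_star(a[1:2], b[1:2]), "3 paired")
  expect_error(r_star(rep(1, 5), ref), "zero variance")
})

test_that("pixel maps of zero-noise phantoms track the true SSC field", {
  cfg <- small_cfg(wavelength_axis = seq(913, 2166, length.out = 60))
  scenes <- make_phantom_set(8, cfg, seed = 31L)
  refs <- do.call(rbind, lapply(scenes, make_reference_table))
  sw_cfg <- sweep_config(modes = "height_angle", patterns = "none",
                         seed = 31L)
  prep <- sscmap:::prepare_mode(scenes, "height_angle", sw_cfg)
  st <- sscmap:::section_table(prep, refs)
  split <- stratified_split(refs, seed = 31L)
  tr <- st$sample_id %in% split$train_ids
  tab <- calibration_table(st$X[tr, ], st$y[tr], st$sample_id[tr])
  model <- fit_plsr(tab, select_lv_one_se(cross_validate(tab, 6, seed = 31L)))
  test_id <- split$test_ids[1]
  i <- which(vapply(scenes, `[[`, "", "sample_id") == test_id)
  map <- predict_map(prep[[i]]$refl, prep[[i]]$flesh, model)
  ok <- !is.na(map$values) & !is.na(scenes[[i]]$true_ssc_map)
  expect_gte(cor(map$values[ok], scenes[[i]]$true_ssc_map[ok]), 0.95)
})

test_that("line-scan fusion is a bijection from defined pixels", {
  vals <- matrix(NA_real_, 8, 8)
  vals[3:6, 3:6] <- 10
  map <- structure(list(values = vals), class = "ssc_map")
  flat <- height_map(matrix(2, 8, 8), pixel_pitch_mm = 0.5)
  pc <- fuse_line_scan(map, flat)
  expect_equal(nrow(pc), sum(!is.na(vals)))
  expect_true(all(pc$z == 2))                        # coplanar
  expect_true(all(pc$ssc == 10))
  # hemisphere phantom: max z equals the height semi-axis within a pitch
  sc <- make_phantom(small_cfg())
  full <- matrix(1, nrow(sc$flesh_mask), ncol(sc$flesh_mask))
  full[!sc$silhouette] <- NA
  mp <- structure(list(values = full), class = "ssc_map")
  pc2 <- fuse_line_scan(mp, sc$height)
  expect_lt(abs(max(pc2$z) - sc$config$semi_axes_mm[3]),
            sc$height$pixel_pitch_mm)
  # geometry channel independent of the SSC attribute
  mp2 <- structure(list(values = full * 3), class = "ssc_map")
  pc3 <- fuse_line_scan(mp2, sc$height)
  expect_identical(pc3[, c("x", "y", "z")], pc2[, c("x", "y", "z")])
})

test_that("rotation-scan fusion follows the printed rates", {
  # 100 fps at 30 deg/s -> 0.3 deg per frame, 1200 frames per rotation
  n_rows <- 5; n_frames <- 1200
  vals <- matrix(10, n_rows, n_frames)
  map <- structure(list(values = vals), class = "ssc_map")
  radii <- matrix(15, n_rows, n_frames)
  pc <- fuse_rotation_scan(map, radii, frame_rate_hz = 100,
                           turn_rate_deg_s = 30)
  expect_equal(attr(pc, "deg_per_frame"), 0.3)
  expect_equal(nrow(pc), n_rows * n_frames)
  # constant radius -> circular cross-sections
  expect_equal(unique(round(sqrt(pc$x^2 + pc$y^2), 9)), 15)
  # closure: first and last azimuths within one angular step
  az <- sort(unique(atan2(pc$y, pc$x))) * 180 / pi
  expect_lt(360 + min(az) - max(az), 0.3 + 1e-9)
  # partial coverage warns
  short <- structure(list(values = vals[, 1:600]), class = "ssc_map")
  expect_warning(fuse_rotation_scan(short, radii[, 1:600], 100, 30),
                 "partial")
})

test_that("PLY export writes a readable vertex list", {
  pc <- structure(data.frame(x = 1:3, y = 4:6, z = 7:9, ssc = c(8, 9, 10)),
                  class = c("fruit_point_cloud", "data.frame"))
  f <- tempfile(fileext = ".ply")
  write_ply(pc, f)
  lines <- readLines(f)
  expect_equal(lines[1], "ply")
  expect_equal(sum(lines == "end_header"), 1L)
  expect_equal(length(lines) - which(lines == "end_header"), 3L)
  expect_match(lines[which(lines == "end_header") + 1], "^1.0000 4.0000")
  unlink(f)
})
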