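# End-to-end pipeline: phantom generation (or user data), correction, ROI,
# sweep, mapping, reliability, fusion, with every artifact written to an
# output directory and a manifest of checksums. All randomness flows from
# one root seed.

#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir Output directory (created if missing).
#' @param n_fruits Number of phantom fruits to simulate.
#' @param phantom Base [phantom_config] for the fleet.
#' @param sweep A [sweep_config]; its `seed` is overridden by `seed`.
#' @param seed Root seed recorded in the manifest.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, n_fruits = 12L,
                       phantom = phantom_config(),
                       sweep = sweep_config(), seed = 1L) {
  if (!is.character(out_dir) || length(out_dir) != 1L) {
    stop("`out_dir` must be a single path")
  }
  n_fruits <- as.integer(n_fruits)
  if (n_fruits < 4L) stop("need at least 4 fruits for a 7:3 split with folds")
  sweep$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, n_fruits = n_fruits, phantom = phantom,
                 sweep = sweep, seed = as.integer(seed)),
            class = "run_config")
}

#' Parse a flat key = value config file
#'
#' Recognized keys: `n_fruits`, `seed`, `n_rows`, `n_cols`, `n_bands`,
#' `noise_sd`, `achene_density`, `modes` (comma separated), `patterns`
#' (comma separated), `folds`, `A_max`, `k`, `ratio`. Unknown keys raise an
#' error so typos do not pass silently.
#'
#' @param path Config file path; lines `key = value`, `#` comments.
#' @param out_dir Output directory for the run.
#' @return A [run_config].
#' @export
read_run_config <- function(path, out_dir) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 0L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  known <- c("n_fruits", "seed", "n_rows", "n_cols", "n_bands", "noise_sd",
             "achene_density", "modes", "patterns", "folds", "A_max", "k",
             "ratio")
  if (any(!keys %in% known)) {
    stop("unknown config key: ", paste(setdiff(keys, known), collapse = ", "))
  }
  g <- function(key, default) if (key %in% keys) vals[keys == key][1] else default
  n_bands <- as.integer(g("n_bands", 200L))
  ph <- phantom_config(
    wavelength_axis = seq(913, 2166, length.out = n_bands),
    n_rows = as.integer(g("n_rows", 64L)),
    n_cols = as.integer(g("n_cols", 64L)),
    noise_sd = as.numeric(g("noise_sd", 20)),
    achene_density = as.numeric(g("achene_density", 0.03))
  )
  sw <- sweep_config(
    modes = strsplit(g("modes", paste(GEOMETRY_MODES, collapse = ",")), ",")[[1]],
    patterns = strsplit(g("patterns", paste(PATTERNS, collapse = ",")), ",")[[1]],
    folds = as.integer(g("folds", 5L)),
    A_max = as.integer(g("A_max", 10L)),
    k = as.numeric(g("k", 3)),
    ratio = as.numeric(g("ratio", 0.7))
  )
  run_config(out_dir, n_fruits = as.integer(g("n_fruits", 12L)),
             phantom = ph, sweep = sw, seed = as.integer(g("seed", 1L)))
}

#' Run the full pipeline and write artifacts
#'
#' Stages: phantom generation, reference table, sweep (correction, ROI,
#' preprocessing, calibration, mapping, reliability), SSC maps and point
#' clouds for the winning configuration, and a manifest. Byte-identical
#' outputs for identical config and seed.
#'
#' @param config A [run_config].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the sweep table, the scenes, the
#'   reference table and the artifact paths.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  say <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("phantom", "generating %d fruits", config$n_fruits)
  scenes <- make_phantom_set(config$n_fruits, config$phantom,
                             seed = config$seed)
  references <- do.call(rbind, lapply(scenes, make_reference_table))
  ref_path <- file.path(config$out_dir, "references.csv")
  utils::write.csv(references, ref_path, row.names = FALSE)

  say("sweep", "%d modes x %d patterns",
      length(config$sweep$modes), length(config$sweep$patterns))
  sweep <- run_sweep(scenes, references, config$sweep)
  sweep_path <- file.path(config$out_dir, "sweep.csv")
  utils::write.csv(format(sweep, digits = 12), sweep_path, row.names = FALSE)

  # winning configuration by reliability; build its artifacts on one test fruit
  ok_rows <- which(is.na(sweep$error))
  if (!length(ok_rows)) stop("pipeline failed at stage sweep: no configuration succeeded")
  best <- ok_rows[which.max(sweep$reliability[ok_rows])]
  mode <- sweep$geometry_mode[best]; pattern <- sweep$pattern[best]
  say("map", "best configuration: %s / %s", mode, pattern)
  split <- attr(sweep, "split")
  test_scene <- scenes[[match(split$test_ids[1],
                              vapply(scenes, `[[`, "", "sample_id"))]]
  params <- config$sweep$params; params$mode <- mode
  refl <- correct_cube(test_scene$cube, test_scene$dark, test_scene$white,
                       test_scene$height, params)
  flesh <- segment_flesh(refl, config$sweep$roi_preset)
  # refit the winning model on the training fruits
  prep <- prepare_mode(scenes, mode, config$sweep)
  st <- section_table(prep, references)
  spec <- preprocess_spec(pattern, config$sweep$window, config$sweep$polyorder)
  Xp <- apply_pattern(st$X, spec)
  is_train <- st$sample_id %in% split$train_ids
  tab <- calibration_table(Xp[is_train, , drop = FALSE], st$y[is_train],
                           st$sample_id[is_train])
  model <- fit_plsr(tab, sweep$A[best])
  attr(model, "geometry_mode") <- mode
  map <- predict_map(refl, flesh, model, spec)
  map_path <- file.path(config$out_dir, "ssc_map.csv")
  write_matrix_csv(map$values, map_path)
  mask_path <- file.path(config$out_dir, "flesh_mask.csv")
  write_matrix_csv(flesh$mask, mask_path)
  cube_path <- file.path(config$out_dir, "test_cube")
  write_envi(refl, cube_path)

  say("reliability", "k = %g", config$sweep$k)
  manifold <- fit_manifold(model$scores, k = config$sweep$k)
  d2 <- rep(NA_real_, length(map$pixel_idx))
  if (!is.null(map$scores)) d2 <- mahalanobis_sq(map$scores, manifold)
  d2_map <- matrix(NA_real_, nrow(map$values), ncol(map$values))
  d2_map[map$pixel_idx] <- d2
  d2_path <- file.path(config$out_dir, "d2_map.csv")
  write_matrix_csv(d2_map, d2_path)

  say("fuse", "point cloud")
  cloud <- fuse_line_scan(map, test_scene$height)
  ply_path <- file.path(config$out_dir, "fruit.ply")
  write_ply(cloud, ply_path)

  paths <- c(references = ref_path, sweep = sweep_path, ssc_map = map_path,
             flesh_mask = mask_path, d2_map = d2_path, ply = ply_path,
             cube_hdr = paste0(cube_path, ".hdr"),
             cube_img = paste0(cube_path, ".img"))
  manifest <- data.frame(
    file = basename(unname(paths)),
    md5 = vapply(unname(paths), function(p) unname(tools::md5sum(p)), ""),
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(config$out_dir, "manifest.csv")
  utils::write.csv(cbind(seed = config$seed, manifest), manifest_path,
                   row.names = FALSE)
  say("done", "%d artifacts in %s", length(paths), config$out_dir)
  invisible(list(sweep = sweep, scenes = scenes, references = references,
                 paths = c(paths, manifest = manifest_path)))
}

#' Report the dual winners of a completed sweep
#'
#' Prints (and returns) the best configuration by test-set R2 and the best
#' by imaging reliability side by side; the two need not coincide, which is
#' the point of the reliability index. The ranking is independent of row
#' order in the sweep file.
#'
#' @param sweep A sweep `data.frame`, or a path to a directory containing
#'   `sweep.csv`.
#' @return `data.frame` with two rows (`best_R2p`, `best_reliability`),
#'   invisibly if printed.
#' @export
pipeline_report <- function(sweep) {
  if (is.character(sweep)) {
    f <- file.path(sweep, "sweep.csv")
    if (!file.exists(f)) stop("missing sweep file: ", f)
    sweep <- utils::read.csv(f)
  }
  ok <- which(!is.na(sweep$R2p))
  if (!length(ok)) stop("sweep has no successful configurations")
  ord <- order(sweep$geometry_mode, sweep$pattern)   # stable under permutation
  sweep <- sweep[ord, ]
  ok <- which(!is.na(sweep$R2p))
  i_r2 <- ok[which.max(sweep$R2p[ok])]
  i_rel <- ok[which.max(sweep$reliability[ok])]
  out <- sweep[c(i_r2, i_rel),
               c("geometry_mode", "pattern", "A", "RMSEP", "R2p",
                 "reliability", "r_star")]
  rownames(out) <- c("best_R2p", "best_reliability")
  print(out)
  invisible(out)
}
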