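# The 32-configuration sweep: 4 geometry correction modes x 8 preprocessing
# patterns, each yielding a calibrated PLSR model, test-set figures of
# merit, the pixel-wise imaging reliability index, and the correlation r*
# between reference and imaging section values.

GEOMETRY_MODES <- c("none", "height", "angle", "height_angle")

#' Sweep configuration
#'
#' @param modes Geometry correction modes to include (default all four).
#' @param patterns Preprocessing pattern names (default all eight).
#' @param params [geometry_params] template (`mode` field overridden per
#'   configuration).
#' @param roi_preset ROI preset name for [segment_flesh].
#' @param ratio Train fraction for the stratified split.
#' @param n_bins SSC strata for the split.
#' @param folds Cross-validation folds.
#' @param A_max Largest latent-variable count assessed.
#' @param k Sigma multiplier for the reliability threshold.
#' @param window,polyorder Savitzky-Golay parameters.
#' @param seed Root seed (split and folds derive from it).
#' @return Object of class `sweep_config`.
#' @export
sweep_config <- function(modes = GEOMETRY_MODES, patterns = PATTERNS,
                         params = geometry_params(),
                         roi_preset = "preset_linescan",
                         ratio = 0.7, n_bins = 5L, folds = 5L, A_max = 10L,
                         k = 3, window = 9L, polyorder = 2L, seed = 1L) {
  stopifnot(all(modes %in% GEOMETRY_MODES), all(patterns %in% PATTERNS))
  structure(list(modes = modes, patterns = patterns, params = params,
                 roi_preset = roi_preset, ratio = ratio,
                 n_bins = as.integer(n_bins), folds = as.integer(folds),
                 A_max = as.integer(A_max), k = k,
                 window = as.integer(window),
                 polyorder = as.integer(polyorder),
                 seed = as.integer(seed)),
            class = "sweep_config")
}

# Per-scene, per-mode intermediates reused across the 8 patterns of a mode:
# corrected reflectance cube, flesh mask, section masks, section-mean raw
# spectra, flesh pixel spectra.
prepare_mode <- function(scenes, mode, config) {
  params <- config$params
  params$mode <- mode
  lapply(scenes, function(s) {
    refl <- correct_cube(s$cube, s$dark, s$white, s$height, params)
    flesh <- segment_flesh(refl, config$roi_preset)
    secs <- section_masks(flesh)
    spectra <- section_mean_spectra(refl, flesh, sample_id = s$sample_id)
    X <- flesh_spectra(refl, flesh)
    list(sample_id = s$sample_id, refl = refl, flesh = flesh,
         sections = secs, section_spectra = spectra, pixels = X)
  })
}

# Assemble the (sections x bands) calibration matrix and aligned responses.
section_table <- function(prep, references) {
  rows <- list(); ids <- character(0); secs <- character(0)
  for (p in prep) {
    for (rec in p$section_spectra) {
      rows[[length(rows) + 1L]] <- rec$spectrum
      ids <- c(ids, rec$sample_id)
      secs <- c(secs, rec$section)
    }
  }
  X <- do.call(rbind, rows)
  key <- paste(references$sample_id, references$section)
  y <- references$brix[match(paste(ids, secs), key)]
  if (anyNA(y)) stop("reference table missing entries for some sections")
  list(X = X, y = y, sample_id = ids, section = secs)
}

#' Run the geometry x preprocessing model sweep
#'
#' For every combination of geometry correction mode and preprocessing
#' pattern: correct the cubes, segment flesh, average section spectra,
#' preprocess, split fruits 7:3 stratified by SSC (one split shared by all
#' configurations), select the latent-variable count by 5-fold CV with the
#' one-standard-error rule, fit, evaluate on the held-out fruits, build
#' pixel-wise maps of the test fruits, and compute the imaging reliability
#' index and r*. A configuration that fails is recorded with its error
#' message and NA metrics, and still counts toward the sweep cardinality.
#'
#' @param scenes List of [phantom_scene] objects (or compatible lists with
#'   `cube`, `dark`, `white`, `height`, `sample_id`).
#' @param references `data.frame` with `sample_id`, `section`, `brix`.
#' @param config A [sweep_config].
#' @return `data.frame` with one row per configuration (columns
#'   `geometry_mode`, `pattern`, `A`, `RMSECV`, `RMSEC`, `RMSEP`, `R2cv`,
#'   `R2c`, `R2p`, `reliability`, `r_star`, `error`), sorted by (mode,
#'   pattern) in config order; attribute `d2_cache` retains per-record
#'   distance distributions for [threshold_sensitivity], and `split` the
#'   train/test fruit ids.
#' @export
run_sweep <- function(scenes, references, config = sweep_config()) {
  split <- stratified_split(references, ratio = config$ratio,
                            n_bins = config$n_bins, seed = config$seed)
  rows <- list(); cache <- list()
  for (mode in config$modes) {
    prep <- prepare_mode(scenes, mode, config)
    st <- section_table(prep, references)
    is_train <- st$sample_id %in% split$train_ids
    test_prep <- prep[vapply(prep, function(p)
      p$sample_id %in% split$test_ids, logical(1))]
    for (pat in config$patterns) {
      spec <- preprocess_spec(pat, config$window, config$polyorder)
      rec <- tryCatch(
        fit_one_config(st, is_train, test_prep, references, spec, mode, config),
        error = function(e) list(row = data.frame(
          geometry_mode = mode, pattern = pat, A = NA_integer_,
          RMSECV = NA_real_, RMSEC = NA_real_, RMSEP = NA_real_,
          R2cv = NA_real_, R2c = NA_real_, R2p = NA_real_,
          reliability = NA_real_, r_star = NA_real_,
          error = conditionMessage(e), stringsAsFactors = FALSE),
          d2 = NULL)
      )
      rows[[length(rows) + 1L]] <- rec$row
      cache[[length(cache) + 1L]] <- rec$d2
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "d2_cache") <- cache
  attr(out, "split") <- split
  out
}

fit_one_config <- function(st, is_train, test_prep, references, spec, mode,
                           config) {
  Xp <- apply_pattern(st$X, spec)
  if (anyNA(Xp)) stop("preprocessing produced NA calibration spectra")
  tab_train <- calibration_table(Xp[is_train, , drop = FALSE],
                                 st$y[is_train], st$sample_id[is_train],
                                 st$section[is_train])
  cv <- cross_validate(tab_train, A_max = config$A_max,
                       folds = config$folds, seed = config$seed)
  A <- select_lv_one_se(cv)
  model <- fit_plsr(tab_train, A)
  attr(model, "geometry_mode") <- mode
  cal <- evaluate(model, tab_train$X, tab_train$y)
  tst <- evaluate(model, Xp[!is_train, , drop = FALSE], st$y[!is_train])
  rmsecv <- cv$RMSECV[cv$A == A]
  sstot_tr <- sum((tab_train$y - mean(tab_train$y))^2)
  r2cv <- 1 - rmsecv^2 * length(tab_train$y) / sstot_tr
  manifold <- fit_manifold(model$scores, k = config$k)

  d2_list <- list(); rel <- numeric(0)
  imaging <- numeric(0); refvals <- numeric(0)
  key <- paste(references$sample_id, references$section)
  for (p in test_prep) {
    Xpix <- apply_pattern(p$pixels, spec)
    ok <- stats::complete.cases(Xpix)
    n_pix <- nrow(Xpix)
    d2 <- rep(NA_real_, n_pix)
    if (any(ok)) {
      sc <- project_scores(model, Xpix[ok, , drop = FALSE])
      d2[ok] <- mahalanobis_sq(sc, manifold)
    }
    d2_list[[p$sample_id]] <- d2
    rel <- c(rel, reliability_index(d2, manifold)$reliability)
    # section-averaged imaging values vs reference
    pred <- rep(NA_real_, n_pix)
    if (any(ok)) pred[ok] <- predict(model, Xpix[ok, , drop = FALSE])
    idx <- attr(p$pixels, "pixel_idx")
    pm <- matrix(NA_real_, nrow(p$flesh$mask), ncol(p$flesh$mask))
    pm[idx] <- pred
    for (sec in names(p$sections)) {
      v <- pm[p$sections[[sec]]]
      v <- v[!is.na(v)]
      if (length(v)) {
        imaging <- c(imaging, mean(v))
        refvals <- c(refvals,
                     references$brix[match(paste(p$sample_id, sec), key)])
      }
    }
  }
  rel_model <- model_reliability(rel)
  rs <- if (length(imaging) >= 3L) r_star(imaging, refvals) else NA_real_
  list(
    row = data.frame(
      geometry_mode = mode, pattern = spec$pattern, A = A,
      RMSECV = rmsecv, RMSEC = cal$RMSE, RMSEP = tst$RMSE,
      R2cv = r2cv, R2c = cal$R2, R2p = tst$R2,
      reliability = rel_model, r_star = rs, error = NA_character_,
      stringsAsFactors = FALSE),
    d2 = list(d2 = d2_list, A = model$A)
  )
}
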