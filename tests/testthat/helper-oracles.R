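# Independent oracles and small fixtures shared across test files.

# Small, fast phantom configuration for unit tests.
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_rows = 40, n_cols = 40, semi_axes_mm = c(15, 12, 10),
         wavelength_axis = seq(913, 2166, length.out = 40), noise_sd = 0),
    list(...)
  )
  do.call(phantom_config, args)
}

# PLS regression vector via the Krylov-subspace characterization: the
# A-component PLS fit is the least-squares fit of centered y on the
# centered X restricted to span{s, Cs, ..., C^{A-1}s} with s = X0'y0,
# C = X0'X0. Entirely independent of the NIPALS deflation path.
krylov_pls_b <- function(X, y, A) {
  X0 <- sweep(X, 2, colMeans(X)); y0 <- y - mean(y)
  s <- crossprod(X0, y0)
  C <- crossprod(X0)
  K <- matrix(0, ncol(X), A)
  v <- s
  for (a in seq_len(A)) {
    K[, a] <- v / sqrt(sum(v^2))
    v <- C %*% K[, a]
  }
  Q <- qr.Q(qr(K))
  drop(Q %*% qr.solve(X0 %*% Q, y0))
}

# Brute-force Otsu: explicit loop over candidate bin boundaries with class
# statistics recomputed from scratch at every candidate.
brute_otsu <- function(values, bins = 256L) {
  v <- values[is.finite(values)]
  rng <- range(v)
  binned <- pmin(floor((v - rng[1]) / diff(rng) * bins) + 1L, bins)
  best_k <- NA_integer_; best_var <- -Inf
  for (k in seq_len(bins - 1L)) {
    lo <- binned <= k; hi <- !lo
    if (!any(lo) || !any(hi)) next
    w0 <- mean(lo); w1 <- mean(hi)
    bc <- w0 * w1 * (mean(binned[lo]) - mean(binned[hi]))^2
    if (bc > best_var) { best_var <- bc; best_k <- k }
  }
  rng[1] + best_k / bins * diff(rng)
}

# Two-point linear interpolation oracle for the white stack.
brute_interp_white <- function(white, Hs) {
  h <- white$heights_mm
  Hs <- min(max(Hs, min(h)), max(h))
  if (Hs <= h[1]) return(white$values[1, , ])
  if (Hs >= h[length(h)]) return(white$values[length(h), , ])
  k <- max(which(h <= Hs))
  if (h[k] == Hs) return(white$values[k, , ])
  f <- (Hs - h[k]) / (h[k + 1] - h[k])
  (1 - f) * white$values[k, , ] + f * white$values[k + 1, , ]
}

# Flat synthetic cube builder for geometry tests: constant references,
# explicit value array.
flat_cube <- function(vals, wl = seq(1000, 1000 + 10 * (dim(vals)[3] - 1),
                                     by = 10)) {
  hypercube(vals, wl, kind = "intensity")
}
const_dark <- function(n_col, n_band, level = 1000) {
  dark_reference(matrix(level, n_col, n_band))
}
const_white <- function(n_col, n_band, level = 9000) {
  white_reference(matrix(level, n_col, n_band))
}

# Constructed world for the accuracy-vs-reliability dissociation: a
# per-section multiplicative scatter gain confounds raw spectra (helped by
# SNV + differentiation), while pixel-level white noise is amplified by the
# second derivative (hurting its reliability). Calibration rows are section
# means; pixel matrices carry the noise.
make_dissociation_case <- function(n_fruits = 24, n_bands = 60,
                                   n_pix = 400, gain_sd = 0.08,
                                   pixel_noise_sd = 0.01, seed = 11L) {
  wl <- seq(913, 2166, length.out = n_bands)
  continuum <- 0.8 - 0.05 * (wl - min(wl)) / diff(range(wl))
  feature <- exp(-(wl - 1165)^2 / (2 * 25^2))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  ids <- sprintf("F%02d", seq_len(n_fruits))
  rows <- list(); y <- c(); sid <- c(); sec <- c()
  pixels <- list()
  for (i in seq_len(n_fruits)) {
    for (s in c("top", "bottom")) {
      brix <- runif(1, 7, 13)
      gain <- 1 + rnorm(1, 0, gain_sd)
      clean <- gain * (continuum - 0.004 * brix * feature)
      rows[[length(rows) + 1L]] <- clean
      y <- c(y, brix); sid <- c(sid, ids[i]); sec <- c(sec, s)
      pixels[[length(pixels) + 1L]] <-
        matrix(rep(clean, each = n_pix), n_pix, n_bands) +
        matrix(rnorm(n_pix * n_bands, 0, pixel_noise_sd), n_pix, n_bands)
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(X = do.call(rbind, rows), y = y, sample_id = sid, section = sec,
       pixels = pixels, wavelengths = wl)
}

# Fit + score one preprocessing pattern on the dissociation world; returns
# R2p on held-out sections and the mean pixel reliability of the held-out
# sections.
dissociation_metrics <- function(world, pattern, A_max = 6L, k = 3) {
  spec <- preprocess_spec(pattern)
  Xp <- apply_pattern(world$X, spec)
  refs <- data.frame(sample_id = world$sample_id, brix = world$y)
  split <- stratified_split(refs, seed = 5L)
  tr <- world$sample_id %in% split$train_ids
  tab <- calibration_table(Xp[tr, , drop = FALSE], world$y[tr],
                           world$sample_id[tr])
  cv <- cross_validate(tab, A_max = A_max, seed = 5L)
  model <- fit_plsr(tab, select_lv_one_se(cv))
  r2p <- evaluate(model, Xp[!tr, , drop = FALSE], world$y[!tr])$R2
  manifold <- fit_manifold(model$scores, k = k)
  rel <- vapply(which(!tr), function(i) {
    Pp <- apply_pattern(world$pixels[[i]], spec)
    d2 <- mahalanobis_sq(project_scores(model, Pp), manifold)
    reliability_index(d2, manifold)$reliability
  }, numeric(1))
  list(R2p = r2p, reliability = model_reliability(rel))
}
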