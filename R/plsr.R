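# Partial least squares regression (NIPALS, mean-centering only) and the
# model-selection machinery around it: SSC-stratified train/test splitting
# at the fruit level, 5-fold cross-validation with fruit-level folds, and
# the one-standard-error rule for choosing the number of latent variables.

#' Calibration table
#'
#' @param X Matrix of preprocessed spectra, one row per observation (a fruit
#'   section), one column per band.
#' @param y Response vector (Brix), length `nrow(X)`.
#' @param sample_id Fruit identifier per row (sections of one fruit share
#'   an id and are kept on the same side of every split).
#' @param section `"top"`/`"bottom"` per row.
#' @return Object of class `calibration_table`.
#' @export
calibration_table <- function(X, y, sample_id, section = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (length(sample_id) != length(y)) stop("one sample_id per row required")
  if (anyNA(X) || anyNA(y)) stop("calibration table must have no missing values")
  structure(list(X = X, y = as.numeric(y),
                 sample_id = as.character(sample_id),
                 section = section),
            class = "calibration_table")
}

#' SSC-stratified train/test split at the fruit level
#'
#' Fruits are binned by their mean Brix (quantile bins); within each bin a
#' seeded shuffle allocates `floor(ratio * n_bin)` fruits to training and
#' `floor((1-ratio) * n_bin)` to test, and the leftover fruits are assigned
#' round-robin (train first) under the global `round(ratio * n)` training
#' target. Both sections of a fruit always land on the same side.
#'
#' @param records `data.frame` with columns `sample_id` and `brix` (one or
#'   two rows per fruit).
#' @param ratio Training fraction (default 0.7).
#' @param n_bins Number of SSC strata (default 5, reduced if fewer fruits).
#' @param seed Integer seed; the split is deterministic given it.
#' @return List with `train_ids` and `test_ids` (fruit ids).
#' @export
stratified_split <- function(records, ratio = 0.7, n_bins = 5L, seed = 1L) {
  agg <- stats::aggregate(brix ~ sample_id, data = records, FUN = mean)
  agg <- agg[order(agg$brix, agg$sample_id), ]
  n <- nrow(agg)
  n_bins <- max(1L, min(as.integer(n_bins), n))
  if (n < n_bins) stop("need at least as many fruits as bins")
  breaks <- unique(stats::quantile(agg$brix, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(agg$brix, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  target_train <- round(ratio * n)
  train <- character(0); test <- character(0); leftover <- character(0)
  with_seed(seed, {
    for (b in sort(unique(bin))) {
      ids <- agg$sample_id[bin == b]
      ids <- ids[sample.int(length(ids))]
      nb <- length(ids)
      n_tr <- floor(ratio * nb)
      n_te <- floor((1 - ratio) * nb)
      train <- c(train, ids[seq_len(n_tr)])
      if (n_te > 0) test <- c(test, ids[n_tr + seq_len(n_te)])
      if (n_tr + n_te < nb) leftover <- c(leftover, ids[(n_tr + n_te + 1):nb])
    }
    if (length(leftover)) leftover <- leftover[sample.int(length(leftover))]
  })
  want_train <- TRUE
  for (id in leftover) {
    if (want_train && length(train) < target_train) {
      train <- c(train, id)
    } else if (length(test) < n - target_train) {
      test <- c(test, id)
    } else {
      train <- c(train, id)
    }
    want_train <- !want_train
  }
  list(train_ids = sort(train), test_ids = sort(test))
}

#' Fit a PLS regression model (NIPALS)
#'
#' Mean-centers `X` and `y` (no variance scaling) and extracts `A` latent
#' variables by NIPALS with deflation. Exposes the weight matrix `W`,
#' loadings `P`, response loadings `q`, the direct score projection
#' `Wstar = W (P'W)^{-1}`, the regression vector `b = Wstar q`, and the
#' centering vectors, so that both the regression prediction and the score
#' projection used by the reliability index come from the same fit.
#'
#' @param table A [calibration_table].
#' @param A Number of latent variables.
#' @param strict If `TRUE` (default) an error is raised when `A` exceeds the
#'   attained rank; if `FALSE` the model is truncated to the attained rank.
#' @return Object of class `pls_model`.
#' @export
fit_plsr <- function(table, A, strict = TRUE) {
  X <- table$X; y <- table$y
  m <- nrow(X); p <- ncol(X)
  if (A > min(m - 1L, p)) stop(sprintf("A = %d exceeds min(m-1, bands) = %d",
                                       A, min(m - 1L, p)))
  x_mean <- colMeans(X); y_mean <- mean(y)
  E <- sweep(X, 2L, x_mean); f <- y - y_mean
  W <- matrix(0, p, A); P <- matrix(0, p, A); qv <- numeric(A)
  Tm <- matrix(0, m, A)
  tol <- 1e-12 * max(sum(E^2), 1e-300)
  attained <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw^2 < tol) break
    w <- w / nw
    t_a <- E %*% w
    tt <- sum(t_a^2)
    if (tt < 1e-300) break
    p_a <- crossprod(E, t_a) / tt
    q_a <- sum(f * t_a) / tt
    E <- E - t_a %*% t(p_a)
    f <- f - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; qv[a] <- q_a; Tm[, a] <- t_a
    attained <- a
  }
  if (attained < A) {
    if (strict) stop(sprintf("A = %d exceeds attained rank %d", A, attained))
    W <- W[, seq_len(attained), drop = FALSE]
    P <- P[, seq_len(attained), drop = FALSE]
    qv <- qv[seq_len(attained)]
    Tm <- Tm[, seq_len(attained), drop = FALSE]
    A <- attained
  }
  Wstar <- W %*% solve(crossprod(P, W))
  b <- drop(Wstar %*% qv)
  structure(
    list(A = A, W = W, P = P, q = qv, Wstar = Wstar, scores = Tm,
         x_mean = x_mean, y_mean = y_mean, b = b,
         intercept = y_mean - sum(x_mean * b)),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables, %d bands\n",
              x$A, length(x$x_mean)))
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object A [fit_plsr] model.
#' @param newdata Matrix of spectra (rows), same band axis as calibration.
#' @param A Optionally predict with the first `A <= object$A` components.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, A = object$A, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  if (ncol(X) != length(object$x_mean)) stop("band-count mismatch")
  if (A > object$A) stop("A exceeds the fitted number of components")
  b <- drop(object$Wstar[, seq_len(A), drop = FALSE] %*% object$q[seq_len(A)])
  drop(X %*% b) + object$y_mean - sum(object$x_mean * b)
}

# Deterministic fruit-level fold labels: fruits sorted by (mean brix, id)
# are dealt into folds following a seeded permutation of the fold labels,
# so the assignment depends on the data and the seed but not on row order.
fold_assignment <- function(table, folds, seed) {
  agg <- stats::aggregate(y ~ sample_id,
                          data = data.frame(sample_id = table$sample_id,
                                            y = table$y),
                          FUN = mean)
  agg <- agg[order(agg$y, agg$sample_id), ]
  n <- nrow(agg)
  if (n < folds) stop("fewer fruits than folds")
  perm <- with_seed(seed, sample.int(folds))
  lab <- rep(perm, length.out = n)
  stats::setNames(lab, agg$sample_id)
}

#' Cross-validate PLSR over component counts
#'
#' Fruit-level k-fold cross-validation (both sections of a fruit share a
#' fold): for each fold one model is fitted at `A_max` on the remaining
#' fruits and nested predictions are evaluated for every `A`. RMSECV pools
#' out-of-fold residuals; `SE` is the standard deviation of per-fold RMSEs
#' divided by `sqrt(folds)`.
#'
#' @param table A [calibration_table].
#' @param A_max Largest number of components to assess (truncated to the
#'   rank attainable in every fold).
#' @param folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return `data.frame` with columns `A`, `RMSECV`, `SE`.
#' @export
cross_validate <- function(table, A_max = 10L, folds = 5L, seed = 1L) {
  lab <- fold_assignment(table, folds, seed)
  row_fold <- lab[table$sample_id]
  m <- nrow(table$X)
  models <- vector("list", folds)
  A_eff <- A_max
  for (k in seq_len(folds)) {
    tr <- which(row_fold != k)
    if (length(unique(table$sample_id[tr])) < 2L) stop("fold with < 2 fruits")
    sub <- calibration_table(table$X[tr, , drop = FALSE], table$y[tr],
                             table$sample_id[tr])
    fit <- fit_plsr(sub, min(A_max, length(tr) - 1L, ncol(table$X)),
                    strict = FALSE)
    models[[k]] <- list(fit = fit, holdout = which(row_fold == k))
    A_eff <- min(A_eff, fit$A)
  }
  res <- lapply(seq_len(A_eff), function(a) {
    sq <- numeric(0); fold_rmse <- numeric(folds)
    for (k in seq_len(folds)) {
      ho <- models[[k]]$holdout
      pred <- predict(models[[k]]$fit, table$X[ho, , drop = FALSE], A = a)
      r2 <- (pred - table$y[ho])^2
      sq <- c(sq, r2)
      fold_rmse[k] <- sqrt(mean(r2))
    }
    c(A = a, RMSECV = sqrt(mean(sq)),
      SE = stats::sd(fold_rmse) / sqrt(folds))
  })
  as.data.frame(do.call(rbind, res))
}

#' One-standard-error choice of the number of latent variables
#'
#' Returns the smallest `A` whose RMSECV lies within one standard error of
#' the global RMSECV minimum (the SE taken at the minimizing `A`); ties
#' break toward fewer components.
#'
#' @param cv_curve Output of [cross_validate].
#' @return Integer number of components.
#' @export
select_lv_one_se <- function(cv_curve) {
  if (nrow(cv_curve) == 0L) stop("empty cross-validation curve")
  i_min <- which.min(cv_curve$RMSECV)
  band <- cv_curve$RMSECV[i_min] + cv_curve$SE[i_min]
  as.integer(cv_curve$A[min(which(cv_curve$RMSECV <= band))])
}

#' Regression figures of merit
#'
#' RMSE and the coefficient of determination `R2 = 1 - SSres / SStot`, with
#' the total sum of squares about the evaluation set's own mean.
#'
#' @param model A [pls_model].
#' @param X Spectra matrix.
#' @param y Reference values.
#' @return List with `R2` and `RMSE` (and the predictions as `pred`).
#' @export
evaluate <- function(model, X, y) {
  pred <- predict(model, X)
  ssres <- sum((y - pred)^2)
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) stop("zero-variance reference values")
  list(R2 = 1 - ssres / sstot, RMSE = sqrt(mean((y - pred)^2)), pred = pred)
}
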