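make_refs <- function(brix) {
  data.frame(sample_id = sprintf("F%03d", seq_along(brix)), brix = brix)
}

test_that("stratified_split honors the ratio, determinism and fruit unity", {
  refs <- make_refs(seq(8, 12, length.out = 10))
  sp <- stratified_split(refs, ratio = 0.7, seed = 2L)
  expect_length(sp$train_ids, 7L)
  expect_length(sp$test_ids, 3L)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  expect_identical(sp, stratified_split(refs, ratio = 0.7, seed = 2L))
  expect_false(identical(sp, stratified_split(refs, ratio = 0.7, seed = 3L)))
  # two sections per fruit stay together: split works on fruit ids, so a
  # two-row-per-fruit table yields the same partition as the collapsed one
  refs2 <- rbind(refs, refs)
  refs2$section <- rep(c("top", "bottom"), each = 10)
  refs2$brix <- refs2$brix + rep(c(0.5, -0.5), each = 10)
  sp2 <- stratified_split(refs2, ratio = 0.7, seed = 2L)
  expect_identical(sp2, sp)
})

test_that("stratified splits keep train and test SSC distributions close", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    refs <- make_refs(stats::rnorm(1000, 10, 1))
    sp <- stratified_split(refs, seed = s)
    d <- abs(mean(refs$brix[refs$sample_id %in% sp$train_ids]) -
               mean(refs$brix[refs$sample_id %in% sp$test_ids]))
    if (d < 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("fit_plsr recovers exact linear structure and its identities", {
  set.seed(6)
  n <- 15; p <- 25
  dirv <- rnorm(p)
  Tlat <- rnorm(n)
  X <- outer(Tlat, dirv) + matrix(rnorm(n * p, 0, 1e-9), n, p)
  y <- 2 + 3 * Tlat
  tab <- calibration_table(X, y, as.character(1:n))
  m <- fit_plsr(tab, 1)
  expect_lt(evaluate(m, X, y)$RMSE, 1e-8)
  # Ttrain identity: Xtrain_centered %*% Wstar reproduces stored scores
  Xc <- sweep(X, 2, m$x_mean)
  expect_lt(max(abs(Xc %*% m$Wstar - m$scores)), 1e-10)
  # prediction path equivalence: scores %*% q + y_mean equals X b + intercept
  expect_lt(max(abs((m$scores %*% m$q + m$y_mean) -
                      (X %*% m$b + m$intercept))), 1e-8)
  # single-column X: b equals the univariate least-squares slope
  x1 <- matrix(rnorm(20), 20, 1)
  y1 <- 1.5 * x1[, 1] + rnorm(20, 0, 0.1)
  m1 <- fit_plsr(calibration_table(x1, y1, as.character(1:20)), 1)
  expect_equal(m1$b[1], unname(coef(lm(y1 ~ x1))[2]), tolerance = 1e-10)
  # rank guard
  expect_error(fit_plsr(calibration_table(X, y, as.character(1:n)), 20),
               "exceeds")
  expect_error(fit_plsr(tab, 5), "rank")
})

test_that("NIPALS matches the independent Krylov-subspace oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 50), 20, 50)
    y <- rnorm(20)
    tab <- calibration_table(X, y, as.character(1:20))
    for (A in c(1, 3, 5)) {
      m <- fit_plsr(tab, A)
      expect_lt(max(abs(m$b - krylov_pls_b(X, y, A))), 1e-6,
                label = sprintf("seed %d A %d regression vector gap", seed, A))
    }
  }
})

test_that("RMSEC is non-increasing in the number of components", {
  set.seed(9)
  X <- matrix(rnorm(24 * 30), 24, 30)
  y <- X[, 1:3] %*% c(1, -2, 1) + rnorm(24, 0, 0.3)
  tab <- calibration_table(X, drop(y), as.character(1:24))
  rmsec <- sapply(1:8, function(A) evaluate(fit_plsr(tab, A), X, drop(y))$RMSE)
  expect_true(all(diff(rmsec) <= 1e-10))
})

test_that("cross_validate pools fold residuals correctly", {
  set.seed(10)
  n <- 12; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% rnorm(p) * 0.2) + rnorm(n, 0, 0.01)
  ids <- as.character(seq_len(n))
  tab <- calibration_table(X, y, ids)
  # noiseless rank-1 case: RMSECV near zero for A >= 1
  X1 <- outer(rnorm(n), rnorm(p)); y1 <- 5 + drop(X1 %*% rnorm(p))
  cv1 <- cross_validate(calibration_table(X1, y1, ids), A_max = 3, folds = 4,
                        seed = 1)
  expect_lt(cv1$RMSECV[1], 1e-6)
  # leave-one-fruit-out equals the brute-force enumeration oracle
  n6 <- 6
  X6 <- matrix(rnorm(n6 * 8), n6, 8)
  y6 <- drop(X6 %*% rnorm(8)) + rnorm(n6, 0, 0.1)
  ids6 <- as.character(1:n6)
  tab6 <- calibration_table(X6, y6, ids6)
  cv6 <- cross_validate(tab6, A_max = 2, folds = 6, seed = 4)
  lab <- sscmap:::fold_assignment(tab6, 6, 4)
  for (a in 1:2) {
    sq <- c()
    for (id in ids6) {
      tr <- which(ids6 != id)
      mfit <- fit_plsr(calibration_table(X6[tr, ], y6[tr], ids6[tr]), a)
      sq <- c(sq, (predict(mfit, X6[ids6 == id, , drop = FALSE]) -
                     y6[ids6 == id])^2)
    }
    expect_equal(cv6$RMSECV[a], sqrt(mean(sq)), tolerance = 1e-10)
  }
  # fold assignment keyed to data + seed, not row order
  perm <- sample(n)
  tabp <- calibration_table(X[perm, ], y[perm], ids[perm])
  cv_a <- cross_validate(tab, A_max = 3, folds = 4, seed = 7)
  cv_b <- cross_validate(tabp, A_max = 3, folds = 4, seed = 7)
  expect_equal(cv_a, cv_b, tolerance = 1e-12)
})

test_that("one-standard-error rule picks the smallest A inside the band", {
  cv <- data.frame(A = 1:4, RMSECV = c(1.0, 0.8, 0.70, 0.71),
                   SE = c(0.2, 0.1, 0.05, 0.05))
  expect_equal(select_lv_one_se(cv), 3L)
  cv2 <- data.frame(A = 1:4, RMSECV = c(0.9, 0.7, 0.5, 0.4), SE = rep(0, 4))
  expect_equal(select_lv_one_se(cv2), 4L)
  cv3 <- data.frame(A = 1:4, RMSECV = rep(0.6, 4), SE = rep(0.01, 4))
  expect_equal(select_lv_one_se(cv3), 1L)
})

test_that("evaluate implements RMSE and R2 about the evaluation mean", {
  set.seed(12)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- drop(X %*% rnorm(10)) + rnorm(20)
  tab <- calibration_table(X, y, as.character(1:20))
  m <- fit_plsr(tab, 3)
  ev <- evaluate(m, X, y)
  pred <- predict(m, X)
  expect_equal(ev$RMSE, sqrt(mean((y - pred)^2)))
  expect_equal(ev$R2, 1 - sum((y - pred)^2) / sum((y - mean(y))^2))
  # degenerate evaluations
  expect_error(evaluate(m, X, rep(1, 20)), "zero-variance")
})
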