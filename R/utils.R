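#' @keywords internal
"_PACKAGE"

# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

#' Two-sided standard normal coverage of a k-sigma interval
#'
#' Returns \eqn{P(|Z| < k) = \mathrm{erf}(k/\sqrt{2})} for a standard normal
#' Z. This is the coverage probability used to convert a k-sigma rule into a
#' chi-square quantile for the Mahalanobis reliability threshold; at k = 3 it
#' equals 0.9973 (the familiar "three sigma" coverage).
#'
#' @param k Non-negative sigma multiplier.
#' @return Coverage probability in [0, 1).
#' @examples
#' ksigma_coverage(3)   # 0.9973002
#' @export
ksigma_coverage <- function(k) {
  if (!is.numeric(k) || any(k < 0)) stop("`k` must be non-negative")
  2 * stats::pnorm(k) - 1
}
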