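#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded to `seed`, restoring
#' the caller's RNG state afterwards so library functions never clobber a
#' user's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Seeds for pipeline stages are derived from one base seed so any stage can
# be re-run in isolation; offsets are arbitrary but fixed, result kept < 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(generate = 101L, split = 211L, pca = 307L, spa = 401L,
               ga = 503L, svm = 601L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Regularize a covariance matrix
#'
#' Adds a ridge `lambda * I` with `lambda = 1e-6 * trace/dim` whenever the
#' smallest eigenvalue falls below `1e-10`, so Mahalanobis quadratic forms
#' stay well defined on nearly collinear variable subsets. The amount
#' actually applied is returned so fits can record it.
#'
#' @param C symmetric covariance matrix.
#' @return list with elements `C` (possibly ridged matrix) and `lambda`
#'   (0 when no regularization was needed).
#' @keywords internal
regularize_cov <- function(C) {
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lambda <- 0
  if (min(ev) < 1e-10) {
    lambda <- 1e-6 * sum(diag(C)) / ncol(C)
    if (lambda <= 0) lambda <- 1e-10
    C <- C + diag(lambda, ncol(C))
  }
  list(C = C, lambda = lambda)
}

#' Round half away from zero
#'
#' Display rounding for metric tables: 92.85 prints as 92.9 (base R's
#' `round()` rounds half to even, which does not match reported tables).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# squared Euclidean cross-distances between rows of X and rows of Z
sqdist <- function(X, Z) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  outer(rowSums(X^2), rep(1, nrow(Z))) +
    outer(rep(1, nrow(X)), rowSums(Z^2)) - 2 * tcrossprod(X, Z)
}
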