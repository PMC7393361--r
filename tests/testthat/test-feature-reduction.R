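test_that("squared Mahalanobis distance matches direct arithmetic", {
  expect_equal(mahalanobis_sq(c(1, 2), c(1, 2), diag(2)), 0)
  expect_equal(mahalanobis_sq(c(3, 4), c(0, 0), diag(2)), 25)
  expect_equal(mahalanobis_sq(c(2, 3), c(0, 0),
                              matrix(c(2, 0, 0, 1), 2)), 2^2 / 2 + 3^2 / 1)
})

test_that("cost G is the mean own/wrong Mahalanobis ratio", {
  # 1-D classes with pooled variance 1 and means 0 and 4
  a <- 1 / sqrt(2)
  X <- matrix(c(-a, a, 4 - a, 4 + a), ncol = 1)
  y <- c("A", "A", "B", "B")
  st <- class_statistics(X, y)
  expect_equal(unname(st$means[, 1]), c(0, 4))
  expect_equal(st$cov_pooled[1, 1], 1)
  ev <- cost_g(matrix(1), "A", st)
  expect_equal(ev$G, 1 / 9)
  expect_equal(ev$fitness, 9)
  expect_equal(ev$N_V, 1L)
  # a point at its own class mean scores 0; equidistant scores 1
  expect_equal(cost_g(matrix(0), "A", st)$G, 0)
  expect_equal(cost_g(matrix(2), "A", st)$G, 1)
  # a point exactly at the wrong-class mean is flagged as infinite
  ev4 <- cost_g(matrix(4), "A", st)
  expect_identical(ev4$flagged, 1L)
  expect_identical(ev4$g, Inf)
})

test_that("cost G is invariant under invertible affine transforms", {
  set.seed(21)
  d <- two_class_data(15, 3)
  Xv <- matrix(rnorm(30), 10, 3)
  yv <- rep(c("HC", "BC"), 5)
  G0 <- cost_g(Xv, yv, class_statistics(d$X, d$y))$G
  A <- matrix(rnorm(9), 3) + diag(3)
  b <- rnorm(3)
  tf <- function(M) sweep(M %*% t(A), 2, -b)
  G1 <- cost_g(tf(Xv), yv, class_statistics(tf(d$X), d$y))$G
  expect_equal(G0, G1, tolerance = 1e-8)
})

test_that("PCA recovers structure, centres scores, and reconstructs", {
  X <- cbind(1:10, 1:10 + 0.0)          # points on the line y = x
  m <- pca_fit(X, 1)
  expect_equal(m$explained_variance[1], 1)
  expect_equal(unname(apply_reduction(m, matrix(colMeans(X), 1))),
               matrix(0, 1, 1))
  set.seed(3)
  X2 <- matrix(rnorm(24), 6, 4)
  m2 <- pca_fit(X2, 4)
  S <- apply_reduction(m2, X2)
  back <- sweep(S %*% t(m2$loadings), 2, -m2$center)
  expect_lt(max(abs(back - X2)), 1e-9)
  expect_error(pca_fit(X2, 6), "n_components")
  # sign convention: largest-magnitude loading entry is positive
  expect_true(all(apply(m2$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))
})

test_that("pca_select minimizes validation cost over component counts", {
  set.seed(4)
  d <- two_class_data(20, 5)
  v <- two_class_data(10, 5, seed = 5)
  m <- pca_select(d$X, d$y, v$X, v$y, max_ncomp = 6)
  G <- m$provenance$candidate_G
  expect_identical(m$n_components, which.min(G))
  expect_identical(ncol(m$loadings), m$n_components)
})

test_that("SPA chains follow projected norms on orthogonal designs", {
  X <- diag(c(3, 2, 1))                  # orthogonal columns, norms 3>2>1
  chain <- spectroscreen:::spa_chain(crossprod(X), 1L, 3)
  expect_identical(chain, c(1L, 2L, 3L))
  chain2 <- spectroscreen:::spa_chain(crossprod(X), 3L, 3)
  expect_identical(chain2, c(3L, 1L, 2L))
  # a duplicated column has zero projected norm and is never selected twice
  Xd <- cbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0))
  chd <- spectroscreen:::spa_chain(crossprod(Xd), 1L, 3)
  expect_false(all(c(1L, 3L) %in% chd))
})

test_that("SPA matches exhaustive prefix search with an independent cost", {
  set.seed(31)
  n <- 30; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c("HC", "BC"), each = n / 2)
  X[y == "BC", 2] <- X[y == "BC", 2] + 2
  X[y == "BC", 5] <- X[y == "BC", 5] + 1.5
  Xv <- matrix(rnorm(20 * p), 20, p)
  yv <- rep(c("HC", "BC"), each = 10)
  Xv[yv == "BC", 2] <- Xv[yv == "BC", 2] + 2
  Xv[yv == "BC", 5] <- Xv[yv == "BC", 5] + 1.5

  # oracle: naive chain construction by explicit residual projection,
  # every prefix scored with the independent cost implementation
  naive_chain <- function(X, start, max_vars) {
    R <- X; chain <- start
    for (k in seq_len(max_vars - 1)) {
      v <- R[, chain[length(chain)]]
      R <- R - outer(v, drop(crossprod(v, R)) / sum(v^2))
      norms <- colSums(R^2); norms[chain] <- -Inf
      chain <- c(chain, which.max(norms))
    }
    chain
  }
  best <- list(G = Inf)
  for (s in 1:p) {
    ch <- naive_chain(X, s, 3)
    for (len in 1:3) {
      G <- oracle_cost_G(X[, ch[1:len], drop = FALSE], y,
                         Xv[, ch[1:len], drop = FALSE], yv)
      if (G < best$G) best <- list(G = G, vars = sort(ch[1:len]))
    }
  }
  m <- spa_select(X, y, Xv, yv, max_vars = 3)
  expect_identical(m$selected, as.integer(best$vars))
  expect_equal(m$provenance$G, best$G, tolerance = 1e-10)
})

test_that("GA finds a planted two-variable optimum almost always", {
  set.seed(77)
  n <- 40; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(c("HC", "BC"), each = n / 2)
  X[y == "BC", 3] <- X[y == "BC", 3] + 3
  X[y == "BC", 7] <- X[y == "BC", 7] + 3
  Xv <- matrix(rnorm(n * p), n, p)
  yv <- y
  Xv[yv == "BC", 3] <- Xv[yv == "BC", 3] + 3
  Xv[yv == "BC", 7] <- Xv[yv == "BC", 7] + 3

  # exhaustive optimum over all non-empty subsets, independent cost
  best <- list(G = Inf)
  for (code in 1:(2^p - 1)) {
    vars <- which(bitwAnd(code, 2^(0:(p - 1))) > 0)
    if (length(vars) >= n / 2 - 2) next
    G <- tryCatch(oracle_cost_G(X[, vars, drop = FALSE], y,
                                Xv[, vars, drop = FALSE], yv),
                  error = function(e) Inf)
    if (G < best$G) best <- list(G = G, vars = vars)
  }
  hits <- 0
  params <- ga_params(generations = 30, population = 50, realizations = 2,
                      init_active = 3)
  for (seed in 1:50) {
    m <- ga_select(X, y, Xv, yv, params = params, seed = seed)
    if (identical(m$selected, as.integer(best$vars))) hits <- hits + 1
  }
  expect_gte(hits, 48)  # >= 95% of 50 runs
})

test_that("GA operators behave degenerately when switched off", {
  set.seed(8)
  d <- two_class_data(10, 4)
  v <- two_class_data(6, 4, seed = 9)
  init <- matrix(rep(c(TRUE, FALSE, TRUE, FALSE), each = 6), 6, 4)
  m <- ga_select(d$X, d$y, v$X, v$y,
                 params = ga_params(generations = 5, population = 6,
                                    p_crossover = 0, p_mutation = 0,
                                    realizations = 1),
                 seed = 1, init_population = init)
  expect_identical(m$selected, c(1L, 3L))  # population never changes
})

test_that("GA is deterministic given a seed and its best fitness never drops", {
  set.seed(10)
  d <- two_class_data(12, 6)
  v <- two_class_data(8, 6, seed = 11)
  p <- ga_params(generations = 15, population = 12, realizations = 2)
  a <- ga_select(d$X, d$y, v$X, v$y, params = p, seed = 99)
  b <- ga_select(d$X, d$y, v$X, v$y, params = p, seed = 99)
  expect_identical(a$selected, b$selected)
  trace <- a$provenance$best_trace
  expect_true(all(diff(trace) >= -1e-12))
})

test_that("variable selection stays in the original data space", {
  set.seed(12)
  d <- two_class_data(15, 6)
  v <- two_class_data(10, 6, seed = 13)
  m <- spa_select(d$X, d$y, v$X, v$y, max_vars = 3)
  red <- apply_reduction(m, d$X)
  expect_identical(red, d$X[, m$selected, drop = FALSE])
  expect_identical(m$selected, sort(m$selected))
})
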