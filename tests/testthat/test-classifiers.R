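test_that("discriminant statistics match hand arithmetic", {
  X <- matrix(c(0, 2, 4, 6), ncol = 1)
  y <- c("A", "A", "B", "B")
  m <- fit_discriminant(X, y, "lda", positive = "A")
  expect_equal(unname(m$stats$means[, 1]), c(1, 5))
  expect_equal(m$stats$cov_pooled[1, 1], 2)
  expect_error(fit_discriminant(matrix(c(0, 4, 6), ncol = 1),
                                c("A", "B", "B"), "lda", positive = "A"),
               ">= 2 samples")
})

test_that("discriminant scores are the plain quadratic form", {
  d <- two_class_data(10, 2)
  m <- fit_discriminant(d$X, d$y, "lda")
  mu <- m$stats$means[m$stats$levels == "BC", ]
  expect_equal(discriminant_score(m, mu, "BC"), 0)
  # 2-D worked case: C = diag(1, 4), x - mean = (1, 2) -> 1/1 + 4/4 = 2
  st <- m$stats
  st$cov_pooled <- diag(c(1, 4))
  m2 <- m; m2$stats <- st
  expect_equal(discriminant_score(m2, mu + c(1, 2), "BC"), 2)
  # identity covariance reduces to squared Euclidean distance
  st$cov_pooled <- diag(2)
  m3 <- m; m3$stats <- st
  expect_equal(discriminant_score(m3, mu + c(3, 4), "BC"), 25)
})

test_that("classification picks the minimal score with ties to the positive class", {
  d <- two_class_data(15, 2, delta = 4)
  m <- fit_discriminant(d$X, d$y, "lda")
  mu_bc <- m$stats$means[m$stats$levels == "BC", ]
  expect_identical(classify_discriminant(m, mu_bc)$labels, "BC")
  # independent two-score comparison oracle on random points
  set.seed(14)
  Z <- matrix(rnorm(40), 20, 2)
  pred <- classify_discriminant(m, Z)
  oracle <- vapply(seq_len(20), function(i) {
    s_bc <- discriminant_score(m, Z[i, ], "BC")
    s_hc <- discriminant_score(m, Z[i, ], "HC")
    if (s_bc <= s_hc) "BC" else "HC"
  }, "")
  expect_identical(pred$labels, oracle)
  expect_equal(pred$margin,
               vapply(seq_len(20), function(i)
                 discriminant_score(m, Z[i, ], "HC") -
                   discriminant_score(m, Z[i, ], "BC"), 1))
})

test_that("QDA with pooled covariances reproduces LDA exactly", {
  set.seed(15)
  d <- two_class_data(20, 3, delta = 2)
  lda <- fit_discriminant(d$X, d$y, "lda")
  qda <- fit_discriminant(d$X, d$y, "qda")
  qda$stats$cov_class <- lapply(qda$stats$cov_class,
                                function(...) qda$stats$cov_pooled)
  Z <- matrix(rnorm(60), 20, 3)
  expect_identical(classify_discriminant(qda, Z)$labels,
                   classify_discriminant(lda, Z)$labels)
})

test_that("RBF kernel values and symmetry", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2)), 1)
  expect_equal(rbf_kernel(0, 1, gamma = 1), exp(-1))
  x <- rnorm(3); z <- rnorm(3)
  expect_equal(rbf_kernel(x, z, 0.7), rbf_kernel(z, x, 0.7))
  K <- rbf_kernel(matrix(rnorm(6), 2), matrix(rnorm(9), 3), 1)
  expect_identical(dim(K), c(2L, 3L))
  expect_true(all(K > 0 & K <= 1))
})

test_that("SVM separates separable data and tunes C on validation", {
  X <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- rep(c("HC", "BC"), each = 3)
  m <- fit_svm(X, y, X, y, C_grid = 1000)
  pred <- svm_classify(m, X)
  expect_identical(pred$labels, y)
  # degenerate validation = training reproduces the training-optimal C
  m2 <- fit_svm(X, y, X, y)
  accs <- m2$provenance$val_accuracy
  expect_equal(accs[m2$provenance$C_grid == m2$C], max(accs))
  # dual feasibility: sum alpha_i y_i = 0, 0 <= alpha <= C
  expect_lt(abs(sum(m$alpha_y)), 1e-8)
  expect_true(all(abs(m$alpha_y) <= m$C + 1e-8))
})

test_that("decision values match the explicit support-vector sum and KKT", {
  set.seed(16)
  d <- two_class_data(15, 2, delta = 2.5)
  m <- fit_svm(d$X, d$y, d$X, d$y, C_grid = 10)
  Z <- matrix(rnorm(20), 10, 2)
  dec <- svm_decision(m, Z)
  oracle <- vapply(seq_len(10), function(j) {
    s <- 0
    for (i in seq_len(m$n_sv))
      s <- s + m$alpha_y[i] * exp(-m$gamma * sum((m$SV[i, ] - Z[j, ])^2))
    s + m$b
  }, 1)
  expect_equal(dec, oracle, tolerance = 1e-10)
  # KKT: free support vectors sit on the margin (decision = label)
  ylab <- ifelse(d$y == m$positive, 1, -1)
  dtr <- svm_decision(m, d$X)
  free <- which(abs(m$alpha_y) > 1e-6 & abs(m$alpha_y) < m$C - 1e-6)
  sv_rows <- apply(m$SV, 1, function(v)
    which.min(colSums((t(d$X) - v)^2)))
  for (i in free)
    expect_equal(dtr[sv_rows[i]], ylab[sv_rows[i]], tolerance = 1e-2)
})

test_that("negating the labels negates the decision function", {
  set.seed(17)
  d <- two_class_data(12, 2, delta = 2)
  m1 <- fit_svm(d$X, d$y, d$X, d$y, C_grid = 10, positive = "BC")
  y_swapped <- ifelse(d$y == "BC", "HC", "BC")
  m2 <- fit_svm(d$X, y_swapped, d$X, y_swapped, C_grid = 10,
                positive = "BC")
  Z <- matrix(rnorm(16), 8, 2)
  expect_equal(svm_decision(m1, Z), -svm_decision(m2, Z),
               tolerance = 1e-6)
})

test_that("SVM dual solution matches an independent QP solver", {
  skip_if_not_installed("kernlab")
  set.seed(18)
  n <- 30
  X <- matrix(runif(n * 2, -1, 1), n, 2)
  y <- ifelse(X[, 1] * X[, 2] > 0, "BC", "HC")   # XOR-like layout
  ypm <- ifelse(y == "BC", 1, -1)
  C <- 10
  m <- fit_svm(X, y, X, y, gamma = 1, C_grid = C, tolerance = 1e-8)

  K <- rbf_kernel(X, X, 1)
  H <- (ypm %o% ypm) * K + diag(1e-10, n)
  qp <- kernlab::ipop(c = rep(-1, n), H = H,
                      A = matrix(ypm, 1), b = 0, r = 0,
                      l = rep(0, n), u = rep(C, n),
                      sigf = 9, maxiter = 200)
  alpha <- kernlab::primal(qp)
  f_no_b <- drop(K %*% (alpha * ypm))
  free <- which(alpha > 1e-5 & alpha < C - 1e-5)
  b <- mean(ypm[free] - f_no_b[free])
  expect_equal(svm_decision(m, X), f_no_b + b, tolerance = 1e-4)
})
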