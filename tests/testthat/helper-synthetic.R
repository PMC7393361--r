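# Small cohort configurations used across tests: same structure as the
# full 476-sample study conditions, scaled down for speed.

small_generator_config <- function(n_samples = 60, grid_spacing = 10,
                                   ...) {
  generator_config(n_samples = n_samples, grid_lo = 900, grid_hi = 1800,
                   grid_spacing = grid_spacing, ...)
}

# deterministic toy dataset: 2 samples x 3 wavenumbers, with replicates
toy_dataset <- function() {
  spectral_dataset(
    wavenumbers = c(1000, 1100, 1200),
    absorbance = rbind(c(0.1, 0.2, 0.3), c(0.15, 0.25, 0.35),
                       c(0.4, 0.5, 0.6), c(0.42, 0.52, 0.62)),
    sample_ids = c("a", "a", "b", "b"),
    replicate_ids = c(1L, 2L, 1L, 2L),
    labels = c("BC", "BC", "HC", "HC"))
}

# two well-separated Gaussian classes in d dimensions, for classifier tests
two_class_data <- function(n_per_class, d, delta = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * d), n_per_class),
             matrix(rnorm(n_per_class * d, mean = delta / sqrt(d)),
                    n_per_class))
  list(X = X, y = rep(c("HC", "BC"), each = n_per_class))
}

# independent Mahalanobis-ratio cost, written from the definition with
# plain solve(); used as the oracle against cost_g / subset selection
oracle_cost_G <- function(X_tr, y_tr, X_val, y_val) {
  lv <- sort(unique(y_tr))
  means <- lapply(lv, function(k) colMeans(X_tr[y_tr == k, , drop = FALSE]))
  covs <- lapply(lv, function(k) cov(X_tr[y_tr == k, , drop = FALSE]))
  ns <- vapply(lv, function(k) sum(y_tr == k), 1)
  pooled <- Reduce(`+`, Map(function(S, n) (n - 1) * S, covs,
                            as.list(ns))) / (sum(ns) - length(lv))
  Ci <- solve(pooled)
  g <- vapply(seq_len(nrow(X_val)), function(i) {
    d2 <- vapply(seq_along(lv), function(j) {
      v <- X_val[i, ] - means[[j]]
      drop(t(v) %*% Ci %*% v)
    }, 1)
    own <- which(lv == y_val[i])
    d2[own] / min(d2[-own])
  }, 1)
  mean(g)
}
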