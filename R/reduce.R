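#' Squared Mahalanobis distance
#'
#' `(x - mean)' C^-1 (x - mean)` with the covariance ridged via
#' [regularize_cov()] when nearly singular.
#'
#' @param x numeric vector or matrix of row vectors.
#' @param center mean vector.
#' @param covariance covariance matrix.
#' @return Non-negative distance(s).
#' @export
mahalanobis_sq <- function(x, center, covariance) {
  covariance <- regularize_cov(as.matrix(covariance))$C
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  drop(stats::mahalanobis(x, center, covariance))
}

#' Per-class means and covariances
#'
#' Class means, per-class covariances and the pooled covariance (weighted
#' by class degrees of freedom); each covariance is regularized when nearly
#' singular and the applied ridge is recorded.
#'
#' @param X training matrix (rows = samples).
#' @param y class labels.
#' @return A list of class `class_statistics`: `levels`, `n_k`, `means`
#'   (class-by-feature), `cov_class` (list), `cov_pooled`, `lambda`
#'   (named vector of ridges actually applied).
#' @export
class_statistics <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  levels <- sort(unique(y))
  if (length(levels) < 2) stop("need at least two classes")
  n_k <- vapply(levels, function(k) sum(y == k), 1L)
  if (any(n_k < 2)) stop("every class needs >= 2 samples")
  means <- matrix(unlist(lapply(levels, function(k)
    colMeans(X[y == k, , drop = FALSE]))),
    nrow = length(levels), byrow = TRUE)
  cov_class <- lapply(levels, function(k) stats::cov(X[y == k, , drop = FALSE]))
  names(cov_class) <- levels
  pooled <- Reduce(`+`, Map(function(S, n) (n - 1) * S, cov_class,
                            as.list(n_k))) / (sum(n_k) - length(levels))
  lambda <- c(pooled = 0, stats::setNames(numeric(length(levels)), levels))
  rp <- regularize_cov(pooled)
  lambda["pooled"] <- rp$lambda
  for (k in levels) {
    rk <- regularize_cov(cov_class[[k]])
    cov_class[[k]] <- rk$C
    lambda[k] <- rk$lambda
  }
  structure(list(levels = levels, n_k = n_k, means = means,
                 cov_class = cov_class, cov_pooled = rp$C,
                 lambda = lambda),
            class = "class_statistics")
}

#' Validation cost function G
#'
#' For each validation sample the ratio of its squared Mahalanobis
#' distance to its own class mean over the smallest squared Mahalanobis
#' distance to a wrong-class mean (pooled training covariance throughout);
#' G is the average ratio over validation samples and the selection fitness
#' is 1/G. Small G means validation points sit close to their own class
#' and far from the others.
#'
#' @param X_val validation matrix restricted to the candidate variables.
#' @param y_val validation labels.
#' @param stats a [class_statistics()] fitted on the training rows
#'   restricted to the same variables.
#' @return A list of class `cost_evaluation`: `G`, `g` (per-sample
#'   ratios), `N_V`, `fitness` (= 1/G) and `flagged` (indices with a zero
#'   denominator, reported as `Inf`).
#' @export
cost_g <- function(X_val, y_val, stats) {
  stopifnot(inherits(stats, "class_statistics"))
  X_val <- as.matrix(X_val)
  y_val <- as.character(y_val)
  Cinv_dists <- vapply(seq_along(stats$levels), function(j)
    mahalanobis_sq(X_val, stats$means[j, ], stats$cov_pooled),
    numeric(nrow(X_val)))
  Cinv_dists <- matrix(Cinv_dists, nrow = nrow(X_val))
  own_col <- match(y_val, stats$levels)
  if (anyNA(own_col)) stop("validation label not present in training stats")
  own <- Cinv_dists[cbind(seq_len(nrow(X_val)), own_col)]
  wrong <- Cinv_dists
  wrong[cbind(seq_len(nrow(X_val)), own_col)] <- Inf
  wrong <- apply(wrong, 1, min)
  g <- ifelse(wrong == 0, Inf, own / wrong)
  G <- mean(g)
  structure(list(G = G, g = g, N_V = nrow(X_val),
                 fitness = if (G > 0) 1 / G else Inf,
                 flagged = which(!is.finite(g))),
            class = "cost_evaluation")
}

#' Fit a principal-component basis
#'
#' Mean-centred PCA (no scaling) with loadings ordered by decreasing
#' explained variance; each loading's sign is fixed so its
#' largest-magnitude element is positive.
#'
#' @param X training matrix.
#' @param n_components number of components,
#'   `<= min(nrow(X) - 1, ncol(X))`.
#' @return A `reduction_model` of kind `"pca"` with fields `center`,
#'   `loadings` (feature-by-component), `sdev`, `explained_variance`.
#' @export
pca_fit <- function(X, n_components) {
  X <- as.matrix(X)
  kmax <- min(nrow(X) - 1, ncol(X))
  if (n_components < 1 || n_components > kmax)
    stop("n_components must be in [1, ", kmax, "]")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  L <- pr$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  structure(list(kind = "pca", center = pr$center, loadings = L,
                 sdev = pr$sdev[seq_len(n_components)],
                 explained_variance = pr$sdev^2 / sum(pr$sdev^2),
                 n_components = n_components,
                 provenance = list()),
            class = "reduction_model")
}

#' Apply a reduction model
#'
#' Projects onto the PC basis (PCA) or subsets the selected wavenumber
#' columns (SPA/GA). Variable selection never modifies the data space:
#' selected variables are original wavenumber channels.
#'
#' @param model a `reduction_model`.
#' @param X matrix on the full wavenumber grid used at fit time.
#' @return The reduced matrix.
#' @export
apply_reduction <- function(model, X) {
  stopifnot(inherits(model, "reduction_model"))
  X <- as.matrix(X)
  if (model$kind == "pca")
    sweep(X, 2, model$center) %*% model$loadings
  else
    X[, model$selected, drop = FALSE]
}

#' Choose the PCA component count on the validation set
#'
#' Fits [class_statistics()] on training scores for each candidate count
#' and returns the count minimizing validation [cost_g()] (ties toward
#' fewer components).
#'
#' @param X_train,y_train,X_val,y_val training and validation data.
#' @param max_ncomp largest count tried (capped by the data).
#' @return A `reduction_model` of kind `"pca"` at the selected count, with
#'   the per-count G values in its provenance.
#' @export
pca_select <- function(X_train, y_train, X_val, y_val, max_ncomp = 20) {
  kmax <- min(max_ncomp, nrow(X_train) - 2, ncol(X_train))
  G <- rep(NA_real_, kmax)
  full <- pca_fit(X_train, kmax)
  S_train <- apply_reduction(full, X_train)
  S_val <- apply_reduction(full, X_val)
  for (k in seq_len(kmax)) {
    st <- class_statistics(S_train[, seq_len(k), drop = FALSE], y_train)
    G[k] <- cost_g(S_val[, seq_len(k), drop = FALSE], y_val, st)$G
  }
  best <- which.min(G)
  model <- pca_fit(X_train, best)
  model$provenance <- list(candidate_G = G, selected_ncomp = best)
  model
}

# Fast G for a variable subset: pooled-covariance Mahalanobis ratio as in
# cost_g() but with a single Cholesky solve and no per-class covariances.
# Used in the SPA/GA inner loops where cost_g()'s full class statistics
# (eigendecompositions per candidate subset) would dominate runtime.
subset_cost_G <- function(X_train, y_train, X_val, y_val, vars) {
  Xt <- X_train[, vars, drop = FALSE]
  Xv <- X_val[, vars, drop = FALSE]
  levels <- sort(unique(y_train))
  d <- length(vars)
  pooled <- matrix(0, d, d)
  means <- matrix(0, length(levels), d)
  df <- 0
  for (j in seq_along(levels)) {
    Xi <- Xt[y_train == levels[j], , drop = FALSE]
    if (nrow(Xi) < 2) return(Inf)
    means[j, ] <- colMeans(Xi)
    pooled <- pooled + crossprod(sweep(Xi, 2, means[j, ]))
    df <- df + nrow(Xi) - 1
  }
  pooled <- pooled / df
  R <- tryCatch(chol(pooled), error = function(e) NULL)
  if (is.null(R)) {
    pooled <- pooled + diag(1e-6 * sum(diag(pooled)) / d + 1e-12, d)
    R <- tryCatch(chol(pooled), error = function(e) NULL)
    if (is.null(R)) return(Inf)
  }
  D2 <- matrix(0, nrow(Xv), length(levels))
  for (j in seq_along(levels)) {
    Z <- backsolve(R, t(sweep(Xv, 2, means[j, ])), transpose = TRUE)
    D2[, j] <- colSums(Z^2)
  }
  own_col <- match(y_val, levels)
  own <- D2[cbind(seq_len(nrow(Xv)), own_col)]
  D2[cbind(seq_len(nrow(Xv)), own_col)] <- Inf
  wrong <- apply(D2, 1, min)
  mean(ifelse(wrong == 0, Inf, own / wrong))
}

# Chains of successively least-collinear variables, computed in Gram space:
# after choosing column a, every remaining column's squared norm is reduced
# by its squared correlation with the orthogonalized direction of a.
spa_chain <- function(G_gram, start, max_vars, tol = 1e-12) {
  p <- ncol(G_gram)
  norms <- diag(G_gram)
  scale0 <- max(norms)
  B <- matrix(0, 0, p)  # rows: orthonormal directions' inner products
  chain <- integer(0)
  cur <- start
  for (k in seq_len(max_vars)) {
    if (norms[cur] <= tol * scale0) break  # collinear exhaustion
    r <- G_gram[cur, ] - if (nrow(B)) colSums(B * B[, cur]) else 0
    beta <- r / sqrt(norms[cur])
    norms <- pmax(norms - beta^2, 0)
    B <- rbind(B, beta)
    chain <- c(chain, cur)
    norms[chain] <- -Inf
    if (k == max_vars || all(norms <= tol * scale0)) break
    cur <- which.max(norms)
  }
  chain
}

#' Successive projections algorithm variable selection
#'
#' Forward selection of minimally collinear wavenumbers: from every
#' starting variable a chain is grown by repeatedly appending the variable
#' whose training column has the largest norm after orthogonal projection
#' onto the complement of the span of the already-chosen columns. Every
#' chain prefix (lengths 1..`max_vars`) is then scored with [cost_g()] on
#' the validation set and the prefix with minimal G wins (ties: shorter
#' chain, then lower starting index). Selection happens in the original
#' data space - the chosen variables are wavenumber channels, not linear
#' combinations.
#'
#' @param X_train,y_train,X_val,y_val training and validation data.
#' @param max_vars longest chain considered (default 30).
#' @param starts starting variables to scan (default: all).
#' @return A `reduction_model` of kind `"spa"` with sorted `selected`
#'   indices and scan details in `provenance`.
#' @export
spa_select <- function(X_train, y_train, X_val, y_val, max_vars = 30,
                       starts = NULL) {
  X_train <- as.matrix(X_train)
  X_val <- as.matrix(X_val)
  max_vars <- min(max_vars, nrow(X_train) - 2, ncol(X_train))
  if (is.null(starts)) starts <- seq_len(ncol(X_train))
  G_gram <- crossprod(X_train)
  best <- list(G = Inf, prefix = integer(0), start = NA_integer_, len = NA)
  for (s in starts) {
    chain <- spa_chain(G_gram, s, max_vars)
    for (len in seq_along(chain)) {
      vars <- chain[seq_len(len)]
      Gval <- subset_cost_G(X_train, y_train, X_val, y_val, vars)
      if (!is.finite(Gval)) next
      better <- Gval < best$G ||
        (Gval == best$G && (len < best$len ||
                              (len == best$len && s < best$start)))
      if (isTRUE(better))
        best <- list(G = Gval, prefix = vars, start = s, len = len)
    }
  }
  if (!length(best$prefix)) stop("SPA found no scorable variable subset")
  structure(list(kind = "spa", selected = sort(best$prefix),
                 provenance = list(G = best$G, start = best$start,
                                   chain_length = best$len,
                                   max_vars = max_vars)),
            class = "reduction_model")
}

#' Genetic-algorithm parameters
#'
#' Defaults follow common chemometric practice for wavelength selection:
#' 100 generations of 200 chromosomes, 60% crossover and 10% mutation
#' probability, best-of-3 independent realizations.
#'
#' @param generations generations per realization.
#' @param population chromosomes per generation.
#' @param p_crossover probability a mated pair undergoes single-point
#'   crossover.
#' @param p_mutation expected number of bit flips per chromosome per
#'   generation (applied per bit at rate `p_mutation / length`).
#' @param realizations independent populations; the best final chromosome
#'   across realizations wins.
#' @param init_active expected number of active variables per initial
#'   chromosome.
#' @return A list of class `ga_params`.
#' @export
ga_params <- function(generations = 100, population = 200,
                      p_crossover = 0.60, p_mutation = 0.10,
                      realizations = 3, init_active = 15) {
  stopifnot(generations >= 1, population >= 2,
            p_crossover >= 0, p_crossover <= 1, p_mutation >= 0)
  structure(list(generations = as.integer(generations),
                 population = as.integer(population),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 realizations = as.integer(realizations),
                 init_active = init_active),
            class = "ga_params")
}

# one GA realization; fitness_fn maps a logical chromosome to 1/G
ga_run <- function(p, params, fitness_fn, init_population = NULL) {
  pop_n <- params$population
  pbit <- min(1, params$p_mutation / p)
  repair <- function(ch) {
    if (!any(ch)) ch[sample.int(p, 1)] <- TRUE
    ch
  }
  if (is.null(init_population)) {
    pop <- matrix(stats::runif(pop_n * p) < params$init_active / p,
                  pop_n, p)
    pop <- t(apply(pop, 1, repair))
  } else pop <- init_population
  fit <- apply(pop, 1, fitness_fn)
  best_trace <- numeric(params$generations)
  for (gen in seq_len(params$generations)) {
    # fitness-proportional (roulette) parent selection
    w <- fit
    if (any(!is.finite(w))) w <- ifelse(is.finite(w), 0, 1)
    if (all(w <= 0)) w <- rep(1, pop_n)
    parents <- sample.int(pop_n, 2 * pop_n, replace = TRUE, prob = w)
    children <- matrix(FALSE, pop_n, p)
    for (i in seq_len(pop_n)) {
      a <- pop[parents[2 * i - 1], ]
      b <- pop[parents[2 * i], ]
      child <- a
      if (stats::runif(1) < params$p_crossover && p > 1) {
        cut <- sample.int(p - 1, 1)
        child <- c(a[seq_len(cut)], b[(cut + 1):p])
      }
      flip <- stats::runif(p) < pbit
      child <- xor(child, flip)
      children[i, ] <- repair(child)
    }
    elite <- which.max(fit)
    children[1, ] <- pop[elite, ]  # elitism of 1
    pop <- children
    fit <- apply(pop, 1, fitness_fn)
    best_trace[gen] <- max(fit)
  }
  best <- which.max(fit)
  list(chromosome = pop[best, ], fitness = fit[best],
       best_trace = best_trace)
}

#' Genetic-algorithm variable selection
#'
#' Binary chromosomes over the wavenumber channels, fitness `1/G` from
#' [cost_g()] evaluated on the validation set with statistics fitted on
#' the training set restricted to the active variables. Fitness-
#' proportional (roulette) parent selection, single-point crossover,
#' per-bit mutation, elitism of one, empty chromosomes repaired by
#' activating one random bit. Runs `realizations` independent populations
#' and returns the best final chromosome. Deterministic given `seed`.
#'
#' @param X_train,y_train,X_val,y_val training and validation data.
#' @param params a [ga_params()].
#' @param seed integer seed.
#' @param init_population optional logical matrix
#'   (`population` x n-variables) used as the initial population of every
#'   realization (mainly for tests).
#' @return A `reduction_model` of kind `"ga"` with sorted `selected`
#'   indices; `provenance` records per-realization fitness and the
#'   best-fitness trace per generation.
#' @export
ga_select <- function(X_train, y_train, X_val, y_val,
                      params = ga_params(), seed = 1,
                      init_population = NULL) {
  stopifnot(inherits(params, "ga_params"))
  X_train <- as.matrix(X_train)
  X_val <- as.matrix(X_val)
  p <- ncol(X_train)
  fitness_fn <- function(ch) {
    G <- subset_cost_G(X_train, y_train, X_val, y_val, which(ch))
    if (!is.finite(G)) 0 else if (G > 0) 1 / G else Inf
  }
  with_seed(seed, {
    runs <- lapply(seq_len(params$realizations), function(r)
      ga_run(p, params, fitness_fn, init_population))
    fits <- vapply(runs, `[[`, 1, "fitness")
    best <- which.max(fits)
    structure(list(kind = "ga", selected = which(runs[[best]]$chromosome),
                   provenance = list(
                     realization_fitness = fits, best_realization = best,
                     best_trace = runs[[best]]$best_trace,
                     params = unclass(params), seed = seed)),
              class = "reduction_model")
  })
}

#' @export
print.reduction_model <- function(x, ...) {
  if (x$kind == "pca")
    cat("<reduction_model: pca> ", x$n_components, " components\n", sep = "")
  else
    cat("<reduction_model: ", x$kind, "> ", length(x$selected),
        " selected variables\n", sep = "")
  invisible(x)
}

#' Serialize a reduction model to JSON
#'
#' @param model a `reduction_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reduction_json <- function(model, path) {
  stopifnot(inherits(model, "reduction_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
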