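#' Fit a Mahalanobis discriminant model
#'
#' Non-Bayesian discriminant analysis: a sample is scored against each
#' class by a squared Mahalanobis distance, with no priors or
#' log-determinant terms. `"lda"` uses the pooled training covariance for
#' every class; `"qda"` uses each class's own covariance. When all class
#' covariances are equal the two modes give identical labels.
#'
#' @param X training matrix (already feature-reduced).
#' @param y class labels, >= 2 samples per class.
#' @param mode `"lda"` or `"qda"`.
#' @param positive label of the positive (disease) class, used for
#'   tie-breaking and ROC orientation.
#' @return A list of class `discriminant_model`.
#' @export
fit_discriminant <- function(X, y, mode = c("lda", "qda"),
                             positive = "BC") {
  mode <- match.arg(mode)
  stats <- class_statistics(X, y)
  if (!positive %in% stats$levels)
    stop("positive class '", positive, "' not present in labels")
  structure(list(stats = stats, mode = mode, positive = positive),
            class = "discriminant_model")
}

#' Discriminant score of a sample against a class
#'
#' The quadratic form `(x - xbar_k)' C^-1 (x - xbar_k)` with `C` the
#' pooled covariance (lda) or class `k`'s covariance (qda). Smaller is
#' more class-like.
#'
#' @param model a `discriminant_model`.
#' @param x sample vector or matrix of row vectors.
#' @param k class label.
#' @return Non-negative score(s).
#' @export
discriminant_score <- function(model, x, k) {
  stopifnot(inherits(model, "discriminant_model"))
  j <- match(k, model$stats$levels)
  if (is.na(j)) stop("unknown class: ", k)
  C <- if (model$mode == "lda") model$stats$cov_pooled
       else model$stats$cov_class[[j]]
  mahalanobis_sq(x, model$stats$means[j, ], C)
}

#' Classify by minimal discriminant score
#'
#' Assigns each sample to the class with the smallest score; exact ties go
#' to the positive class (screening favours sensitivity) and are flagged.
#' The ROC score is `score(negative) - score(positive)`: larger means more
#' positive-like.
#'
#' @param model a `discriminant_model`.
#' @param X matrix of row vectors (or one vector).
#' @return list with `labels`, `margin` (ROC scores) and `ties` (indices).
#' @export
classify_discriminant <- function(model, X) {
  stopifnot(inherits(model, "discriminant_model"))
  if (is.null(dim(X)))
    X <- matrix(X, ncol = ncol(model$stats$means), byrow = TRUE)
  S <- vapply(model$stats$levels,
              function(k) discriminant_score(model, X, k),
              numeric(nrow(X)))
  S <- matrix(S, nrow = nrow(X), dimnames = list(NULL, model$stats$levels))
  pos <- model$positive
  neg <- setdiff(model$stats$levels, pos)
  best <- model$stats$levels[apply(S, 1, which.min)]
  ties <- which(apply(S, 1, function(s) sum(s == min(s)) > 1))
  best[ties] <- pos
  margin <- if (length(neg) == 1) S[, neg] - S[, pos]
            else apply(S[, neg, drop = FALSE], 1, min) - S[, pos]
  list(labels = best, margin = unname(margin), ties = ties)
}

#' Radial-basis-function kernel
#'
#' `exp(-gamma * ||x - z||^2)`, in (0, 1], evaluated between all row pairs
#' when matrices are given.
#'
#' @param x,z vectors or matrices of row vectors.
#' @param gamma kernel width parameter (> 0).
#' @return Kernel value or `nrow(x)` by `nrow(z)` matrix.
#' @export
rbf_kernel <- function(x, z, gamma = 1) {
  if (is.null(dim(x)) && is.null(dim(z)))
    return(exp(-gamma * sum((x - z)^2)))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  exp(-gamma * pmax(sqdist(x, z), 0))
}

#' Fit a soft-margin RBF support vector machine
#'
#' Solves the soft-margin dual for each box constraint in `C_grid`
#' (via libsvm) with the RBF width fixed at `gamma = 1` by default, keeps
#' the dual solution (support vectors, multipliers, bias) and picks the C
#' maximizing validation accuracy, ties toward the smaller C. The decision
#' function is oriented so positive values indicate the positive class.
#'
#' @param X_train,y_train training data (already feature-reduced).
#' @param X_val,y_val validation data used to select C.
#' @param gamma RBF width.
#' @param C_grid candidate box constraints.
#' @param positive positive-class label.
#' @param ... further arguments passed to [e1071::svm()] (e.g. solver
#'   `tolerance`).
#' @return A list of class `svm_model` with `SV`, `alpha_y`
#'   (= alpha_i * y_i), `b`, `gamma`, `C`, `n_sv`, `positive` and the
#'   per-C validation accuracies in `provenance`.
#' @export
fit_svm <- function(X_train, y_train, X_val, y_val, gamma = 1,
                    C_grid = c(0.01, 0.1, 1, 10, 100, 1000),
                    positive = "BC", ...) {
  X_train <- as.matrix(X_train)
  y_train <- as.character(y_train)
  if (!positive %in% y_train) stop("positive class absent from training")
  fits <- lapply(C_grid, function(C) {
    m <- e1071::svm(X_train, factor(y_train), scale = FALSE,
                    kernel = "radial", gamma = gamma, cost = C, ...)
    alpha_y <- drop(m$coefs)
    b <- -m$rho
    model <- list(SV = m$SV, alpha_y = alpha_y, b = b, gamma = gamma,
                  C = C, n_sv = nrow(m$SV), positive = positive,
                  negative = setdiff(unique(y_train), positive))
    class(model) <- "svm_model"
    # orient: positive-class training samples must score higher
    d <- svm_decision(model, X_train)
    if (mean(d[y_train == positive]) < mean(d[y_train != positive])) {
      model$alpha_y <- -model$alpha_y
      model$b <- -model$b
    }
    model
  })
  acc <- vapply(fits, function(m)
    mean(svm_classify(m, X_val)$labels == as.character(y_val)), 1)
  best <- which.max(acc)  # first max -> smallest C on ties
  model <- fits[[best]]
  model$provenance <- list(C_grid = C_grid, val_accuracy = acc)
  model
}

#' SVM decision value
#'
#' `sum_i alpha_i y_i k(x_i, z) + b` over the support vectors; this is
#' also the ROC score.
#'
#' @param model an `svm_model`.
#' @param Z matrix of row vectors (or one vector).
#' @return Numeric decision values.
#' @export
svm_decision <- function(model, Z) {
  stopifnot(inherits(model, "svm_model"))
  # a bare vector is either one sample (length d) or n samples of one
  # variable; the support-vector dimension disambiguates
  if (is.null(dim(Z))) Z <- matrix(Z, ncol = ncol(model$SV), byrow = TRUE)
  drop(crossprod(rbf_kernel(model$SV, Z, model$gamma), model$alpha_y)) +
    model$b
}

#' SVM classification
#'
#' Sign of the decision value; exactly zero goes to the positive class and
#' is flagged.
#'
#' @param model an `svm_model`.
#' @param Z matrix of row vectors (or one vector).
#' @return list with `labels`, `decision` (ROC scores) and `ties`.
#' @export
svm_classify <- function(model, Z) {
  d <- svm_decision(model, Z)
  neg <- if (!is.null(model$negative) && length(model$negative) == 1)
    model$negative else "HC"
  list(labels = ifelse(d >= 0, model$positive, neg),
       decision = d, ties = which(d == 0))
}

#' Serialize a trained classifier to JSON
#'
#' @param model a `discriminant_model` or `svm_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classifier_json <- function(model, path) {
  x <- unclass(model)
  if (inherits(model, "discriminant_model")) x$stats <- unclass(x$stats)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
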