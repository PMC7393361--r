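#' Kennard-Stone sample ranking
#'
#' Deterministic max-min selection: the first two picks are the pair of
#' samples at maximal Euclidean distance; every subsequent pick maximizes
#' its minimum distance to all already-selected samples. Ties are broken
#' toward the lowest row index (for the initial pair, the lexicographically
#' smallest index pair, smaller index first).
#'
#' @param X sample-by-feature numeric matrix.
#' @param n_select number of samples to rank, `2 <= n_select <= nrow(X)`.
#' @return Integer vector of row indices in selection order.
#' @export
kennard_stone <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_select < 2) stop("n_select must be >= 2")
  if (n_select > n) stop("n_select exceeds the number of samples")
  D <- as.matrix(stats::dist(X))
  # initial pair: max distance, ties -> smallest (i, j), i < j
  idx <- which(D == max(D), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  if (nrow(idx) == 0) idx <- matrix(c(1L, 2L), 1)  # all points identical
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  selected <- c(idx[1, 1], idx[1, 2])
  if (n_select > 2) {
    mind <- pmin(D[, selected[1]], D[, selected[2]])
    mind[selected] <- -Inf
    for (k in 3:n_select) {
      nxt <- which.max(mind)  # first max = lowest index on ties
      selected <- c(selected, nxt)
      mind <- pmin(mind, D[, nxt])
      mind[nxt] <- -Inf
    }
  }
  as.integer(selected)
}

#' Kennard-Stone 70/15/15 split
#'
#' Ranks all samples with [kennard_stone()] on their (preprocessed)
#' spectra; the first `n_train` ranks form the training set (the most
#' representative samples span the data cloud), the next `n_val` the
#' validation set and the remainder the test set. Sizes follow
#' `n_val = round(f_val * N)`, `n_test = round(f_test * N)`,
#' `n_train = N - n_val - n_test`, so N = 476 yields 334/71/71.
#'
#' @param ds a replicate-averaged [spectral_dataset()] or a numeric matrix.
#' @param f_train,f_val,f_test fractions summing to 1.
#' @return A list of class `split_result` with integer index vectors
#'   `train_idx`, `val_idx`, `test_idx` partitioning `1:N`.
#' @export
split_dataset <- function(ds, f_train = 0.70, f_val = 0.15, f_test = 0.15) {
  if (abs(f_train + f_val + f_test - 1) > 1e-9)
    stop("fractions must sum to 1")
  X <- if (inherits(ds, "spectral_dataset")) {
    if (!is.null(ds$replicate_ids) && anyDuplicated(ds$sample_ids))
      stop("dataset must be replicate-averaged (one row per sample)")
    ds$absorbance
  } else as.matrix(ds)
  n <- nrow(X)
  n_val <- round(f_val * n)
  n_test <- round(f_test * n)
  n_train <- n - n_val - n_test
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stop("split produces an empty subset (N = ", n, ")")
  ranking <- kennard_stone(X, n)
  structure(list(train_idx = sort(ranking[seq_len(n_train)]),
                 val_idx = sort(ranking[n_train + seq_len(n_val)]),
                 test_idx = sort(ranking[n_train + n_val + seq_len(n_test)]),
                 ranking = ranking),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("<split_result> train/val/test =", length(x$train_idx), "/",
      length(x$val_idx), "/", length(x$test_idx), "\n")
  invisible(x)
}

#' Write split indices to CSV for audit
#'
#' @param split a `split_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_split_csv <- function(split, path) {
  df <- data.frame(
    index = c(split$train_idx, split$val_idx, split$test_idx),
    subset = rep(c("train", "validation", "test"),
                 c(length(split$train_idx), length(split$val_idx),
                   length(split$test_idx))))
  utils::write.csv(df[order(df$index), ], path, row.names = FALSE)
  invisible(path)
}
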