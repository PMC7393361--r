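#' Confusion matrix for a binary classifier
#'
#' @param y_true true labels.
#' @param y_pred predicted labels.
#' @param positive positive-class label.
#' @return A list of class `confusion_matrix` with integer `TP`, `FN`,
#'   `FP`, `TN`.
#' @export
confusion <- function(y_true, y_pred, positive = "BC") {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!length(y_true)) stop("empty input")
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  structure(list(TP = tp, FN = fn, FP = fp, TN = tn, positive = positive),
            class = "confusion_matrix")
}

#' Diagnostic figures of merit
#'
#' The eight standard screening metrics, all as percentages computed at
#' full precision (use [round_half_up()] for display):
#' accuracy `AC = 100 (TP+TN)/total`, sensitivity `SENS = 100 TP/(TP+FN)`,
#' specificity `SPEC = 100 TN/(TN+FP)`, Youden's index
#' `YOU = SENS - (100 - SPEC)`, predictive values
#' `PPV = 100 TP/(TP+FP)` and `NPV = 100 TN/(TN+FN)`,
#' `F_score = 2 SENS SPEC / (SENS + SPEC)` and
#' `G_score = sqrt(SENS SPEC)`.
#'
#' Note: this F-score is the harmonic mean of sensitivity and
#' *specificity*, the convention used in chemometric screening reports -
#' not the precision/recall F1 of the machine-learning literature.
#' Undefined ratios (zero denominators for PPV/NPV) are reported as `NA`,
#' never as 0.
#'
#' @param cm a [confusion()] matrix.
#' @return A list of class `performance_report`.
#' @export
figures_of_merit <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$FN + cm$FP + cm$TN
  if (total == 0) stop("empty confusion matrix")
  if (cm$TP + cm$FN == 0 || cm$TN + cm$FP == 0)
    stop("need at least one positive and one negative sample")
  sens <- 100 * cm$TP / (cm$TP + cm$FN)
  spec <- 100 * cm$TN / (cm$TN + cm$FP)
  structure(list(
    AC = 100 * (cm$TP + cm$TN) / total,
    SENS = sens, SPEC = spec,
    YOU = sens - (100 - spec),
    PPV = if (cm$TP + cm$FP > 0) 100 * cm$TP / (cm$TP + cm$FP) else NA_real_,
    NPV = if (cm$TN + cm$FN > 0) 100 * cm$TN / (cm$TN + cm$FN) else NA_real_,
    F_score = if (sens + spec > 0) 2 * sens * spec / (sens + spec) else 0,
    G_score = sqrt(sens * spec),
    confusion = cm), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  v <- unlist(x[c("AC", "SENS", "SPEC", "YOU", "PPV", "NPV",
                  "F_score", "G_score")])
  cat("<performance_report>\n")
  print(round_half_up(v, 1))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (larger score = more
#' positive-like); the AUC is the Mann-Whitney rank statistic, i.e. the
#' probability that a random positive scores above a random negative,
#' ties counted 1/2 - so it is invariant under strictly increasing score
#' transforms and equals 0.5 when all scores are tied.
#'
#' @param scores numeric classifier scores.
#' @param y_true true labels.
#' @param positive positive-class label.
#' @return list with `points` (data.frame threshold/tpr/fpr) and `auc`.
#' @export
roc_curve <- function(scores, y_true, positive = "BC") {
  y <- as.character(y_true) == positive
  if (!any(y) || all(y)) stop("need both classes to build a ROC curve")
  n_pos <- sum(y); n_neg <- sum(!y)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) c(
    tpr = sum(scores >= t & y) / n_pos,
    fpr = sum(scores >= t & !y) / n_neg), c(tpr = 0, fpr = 0)))
  r <- rank(scores)  # midranks handle ties with the 1/2 convention
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(points = data.frame(threshold = thr, tpr = pts[, "tpr"],
                           fpr = pts[, "fpr"]),
       auc = auc)
}

#' Reconstruct integer confusion matrices from printed metrics
#'
#' Exhaustively searches all integer matrices with the given class sizes
#' whose figures of merit round (half away from zero, 1 decimal) to every
#' supplied metric. Useful for auditing published metric tables where only
#' percentages are printed.
#'
#' @param metrics named numeric vector with any of `AC`, `SENS`, `SPEC`,
#'   `YOU`, `PPV`, `NPV`, `F_score`, `G_score` (as printed percentages).
#' @param n_pos,n_neg numbers of positive and negative test samples.
#' @param positive positive-class label to record.
#' @return data.frame of matching `TP, FN, FP, TN` rows (possibly empty).
#' @export
reconstruct_confusion <- function(metrics, n_pos, n_neg,
                                  positive = "BC") {
  keep <- names(metrics)[!is.na(metrics)]
  out <- list()
  for (tp in 0:n_pos) for (tn in 0:n_neg) {
    cm <- structure(list(TP = tp, FN = n_pos - tp, FP = n_neg - tn,
                         TN = tn, positive = positive),
                    class = "confusion_matrix")
    fm <- tryCatch(figures_of_merit(cm), error = function(e) NULL)
    if (is.null(fm)) next
    vals <- unlist(fm[keep])
    if (all(!is.na(vals)) &&
        isTRUE(all(round_half_up(vals, 1) == metrics[keep])))
      out[[length(out) + 1]] <- c(TP = tp, FN = n_pos - tp,
                                  FP = n_neg - tn, TN = tn)
  }
  as.data.frame(do.call(rbind, out))
}

#' Published benchmark metric table for the nine model combinations
#'
#' Reported test-set figures of merit (percent) and AUCs for the
#' PCA/SPA/GA x LDA/QDA/SVM combinations on the 476-patient plasma
#' screening cohort that the synthetic generator emulates. Used for
#' metric-identity audits; AUC is only reported for the SVM-based models.
#'
#' @return data.frame with one row per model.
#' @export
reference_metric_table <- function() {
  data.frame(
    model = c("PCA-LDA", "PCA-QDA", "PCA-SVM", "SPA-LDA", "SPA-QDA",
              "SPA-SVM", "GA-LDA", "GA-QDA", "GA-SVM"),
    AC   = c(65.7, 65.7, 88.6, 68.6, 74.3, 92.9, 75.7, 72.9, 87.1),
    SENS = c(82.9, 82.9, 91.4, 80.0, 85.7, 94.3, 74.3, 71.4, 88.6),
    SPEC = c(48.6, 48.6, 85.7, 57.1, 62.9, 91.4, 77.1, 74.3, 85.7),
    YOU  = c(31.4, 31.4, 77.1, 37.1, 48.6, 85.7, 51.4, 45.7, 74.3),
    PPV  = c(61.7, 61.7, 86.5, 65.1, 69.8, 91.7, 76.5, 73.5, 86.1),
    NPV  = c(73.9, 73.9, 90.9, 74.1, 81.5, 94.1, 75.0, 72.2, 88.2),
    F_score = c(61.2, 61.2, 88.5, 66.7, 72.5, 92.8, 75.7, 72.8, 87.1),
    G_score = c(63.4, 63.4, 88.5, 67.6, 73.4, 92.8, 75.7, 72.8, 87.1),
    AUC  = c(NA, NA, 0.886, NA, NA, 0.929, NA, NA, 0.871)
  )
}
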