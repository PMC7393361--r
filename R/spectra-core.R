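#' Construct a spectral dataset
#'
#' The container used throughout the package: an absorbance matrix with one
#' row per measurement (or per sample, once replicates are averaged) and one
#' column per wavenumber. Wavenumbers may be supplied in either direction
#' but are always stored ascending, with the absorbance columns permuted to
#' match, so window and peak lookups are unambiguous.
#'
#' @param wavenumbers strictly monotone numeric vector of positions (cm^-1).
#' @param absorbance numeric matrix, `length(sample_ids)` rows by
#'   `length(wavenumbers)` columns.
#' @param sample_ids character vector, one entry per row of `absorbance`.
#' @param replicate_ids optional integer vector, one per row; `NULL` once
#'   replicates are averaged.
#' @param labels optional per-row class labels ("BC" positive, "HC"
#'   negative); all replicates of one sample must carry the same label.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(wavenumbers, absorbance, sample_ids,
                             replicate_ids = NULL, labels = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.matrix(absorbance)
  if (anyDuplicated(wavenumbers))
    stop("duplicated wavenumbers: axis must be strictly monotone")
  d <- diff(wavenumbers)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("wavenumbers must be strictly monotone")
  if (length(d) && all(d < 0)) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, rev(seq_along(wavenumbers)), drop = FALSE]
  }
  if (ncol(absorbance) != length(wavenumbers))
    stop("absorbance must have one column per wavenumber")
  sample_ids <- as.character(sample_ids)
  if (nrow(absorbance) != length(sample_ids))
    stop("absorbance must have one row per sample id")
  if (!is.null(replicate_ids)) {
    replicate_ids <- as.integer(replicate_ids)
    if (length(replicate_ids) != nrow(absorbance))
      stop("replicate_ids must have one entry per row")
    if (anyDuplicated(paste(sample_ids, replicate_ids)))
      stop("duplicate (sample, replicate) rows")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(absorbance))
      stop("labels must have one entry per row")
    per_sample <- tapply(labels, sample_ids, function(l) length(unique(l)))
    if (any(per_sample > 1))
      stop("inconsistent labels across replicates of sample(s): ",
           paste(names(per_sample)[per_sample > 1], collapse = ", "))
  }
  dimnames(absorbance) <- NULL
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 sample_ids = sample_ids, replicate_ids = replicate_ids,
                 labels = labels),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("<spectral_dataset> ", nrow(x$absorbance), " row(s) x ",
      length(x$wavenumbers), " wavenumbers [",
      min(x$wavenumbers), "-", max(x$wavenumbers), " cm^-1]",
      if (is.null(x$replicate_ids)) " (averaged)" else "", "\n", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(x$labels[!duplicated(x$sample_ids)])
    cat("  samples: ", length(unique(x$sample_ids)), " (",
        paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' Read spectra from CSV
#'
#' Two dialects are supported. `wide`: columns `sample_id,replicate,label`
#' followed by one numeric-header column per wavenumber, one row per
#' measurement. `long`: columns
#' `sample_id,replicate,label,wavenumber,absorbance`. Wavenumbers may appear
#' in descending order in the file; they are stored ascending.
#'
#' @param path CSV file path.
#' @param dialect `"wide"` (default) or `"long"`.
#' @return A [spectral_dataset()].
#' @export
read_spectra <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "replicate", "label")
  if (!all(need %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  labels <- df$label
  if (all(is.na(labels)) || all(labels == "")) labels <- NULL
  if (dialect == "wide") {
    wn_cols <- names(df)[!(names(df) %in% need)]
    wn <- suppressWarnings(as.numeric(wn_cols))
    if (anyNA(wn)) stop("non-numeric wavenumber header(s): ",
                        paste(wn_cols[is.na(wn)], collapse = ", "))
    A <- matrix(NA_real_, nrow(df), length(wn_cols))
    for (j in seq_along(wn_cols)) {
      v <- suppressWarnings(as.numeric(df[[wn_cols[j]]]))
      if (anyNA(v)) {
        bad <- which(is.na(v))[1]
        stop("non-numeric absorbance at row ", bad,
             ", wavenumber column '", wn_cols[j], "'")
      }
      A[, j] <- v
    }
    spectral_dataset(wn, A, df$sample_id,
                     replicate_ids = as.integer(df$replicate),
                     labels = labels)
  } else {
    if (!all(c("wavenumber", "absorbance") %in% names(df)))
      stop("long dialect needs 'wavenumber' and 'absorbance' columns")
    wn_all <- suppressWarnings(as.numeric(df$wavenumber))
    ab_all <- suppressWarnings(as.numeric(df$absorbance))
    if (anyNA(wn_all)) stop("non-numeric wavenumber at row ",
                            which(is.na(wn_all))[1])
    if (anyNA(ab_all)) stop("non-numeric absorbance at row ",
                            which(is.na(ab_all))[1])
    key <- paste(df$sample_id, df$replicate, sep = "\r")
    rows <- unique(key)
    wn <- sort(unique(wn_all))
    A <- matrix(NA_real_, length(rows), length(wn))
    ri <- match(key, rows)
    ci <- match(wn_all, wn)
    if (anyDuplicated(cbind(ri, ci)))
      stop("duplicated (measurement, wavenumber) entries in long file")
    A[cbind(ri, ci)] <- ab_all
    if (anyNA(A)) stop("long file does not cover the full wavenumber grid ",
                       "for every measurement")
    first <- match(rows, key)
    spectral_dataset(wn, A, df$sample_id[first],
                     replicate_ids = as.integer(df$replicate[first]),
                     labels = if (is.null(labels)) NULL else labels[first])
  }
}

#' Write spectra to wide CSV
#'
#' Inverse of [read_spectra()] for the wide dialect; numbers are written
#' with 17 significant digits so a write/read cycle reproduces the dataset
#' exactly.
#'
#' @param ds a [spectral_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path) {
  stopifnot(inherits(ds, "spectral_dataset"))
  n <- nrow(ds$absorbance)
  rep_col <- if (is.null(ds$replicate_ids)) rep(1L, n) else ds$replicate_ids
  lab_col <- if (is.null(ds$labels)) rep("", n) else ds$labels
  header <- c("sample_id", "replicate", "label",
              sprintf("%.17g", ds$wavenumbers))
  body <- cbind(ds$sample_ids, rep_col, lab_col,
                matrix(sprintf("%.17g", ds$absorbance), nrow = n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Average replicate measurements
#'
#' Collapses the dataset to one row per sample by taking the arithmetic
#' mean of that sample's replicate rows at every wavenumber; labels are
#' preserved. Idempotent on already-averaged data.
#'
#' @param ds a [spectral_dataset()].
#' @return A [spectral_dataset()] with one row per sample and
#'   `replicate_ids = NULL`.
#' @export
average_replicates <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  ids <- unique(ds$sample_ids)
  g <- match(ds$sample_ids, ids)
  A <- rowsum(ds$absorbance, g, reorder = TRUE) /
    as.vector(table(factor(g, levels = seq_along(ids))))
  labels <- NULL
  if (!is.null(ds$labels)) labels <- ds$labels[match(ids, ds$sample_ids)]
  spectral_dataset(ds$wavenumbers, A, ids, replicate_ids = NULL,
                   labels = labels)
}

#' Truncate to a wavenumber interval
#'
#' Keeps exactly the columns with `lo <= w <= hi` (closed interval), e.g.
#' the 900-1800 cm^-1 biofingerprint region.
#'
#' @param ds a [spectral_dataset()].
#' @param lo,hi interval bounds in cm^-1, `lo < hi`.
#' @return The truncated [spectral_dataset()].
#' @export
truncate_spectra <- function(ds, lo, hi) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (!(lo < hi)) stop("invalid range: lo must be < hi")
  keep <- ds$wavenumbers >= lo & ds$wavenumbers <= hi
  if (!any(keep)) stop("range [", lo, ", ", hi, "] contains no wavenumbers")
  spectral_dataset(ds$wavenumbers[keep],
                   ds$absorbance[, keep, drop = FALSE],
                   ds$sample_ids, ds$replicate_ids, ds$labels)
}

# nearest grid index to a target wavenumber
nearest_wavenumber <- function(wavenumbers, target) {
  which.min(abs(wavenumbers - target))
}
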