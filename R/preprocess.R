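#' Preprocessing configuration
#'
#' Parameters for the fixed preprocessing chain
#' truncate -> Savitzky-Golay -> AWLS baseline -> Amide I normalization.
#'
#' The Savitzky-Golay window defaults to 7 points with a 2nd-order
#' polynomial; a 15-point window is also in circulation for this kind of
#' plasma data and both are supported through `sg_window`.
#'
#' @param trunc_lo,trunc_hi biofingerprint truncation bounds (cm^-1).
#' @param sg_window odd Savitzky-Golay window length in points,
#'   `> sg_polyorder`.
#' @param sg_polyorder Savitzky-Golay polynomial order.
#' @param awls_polyorder polynomial order of the AWLS baseline.
#' @param awls_max_iter maximum AWLS reweighting iterations (>= 1).
#' @param awls_tol convergence tolerance on the max absolute change of the
#'   fitted baseline between iterations.
#' @param awls_peak_weight weight given to points above the current
#'   baseline fit (peak regions); points at or below keep weight 1.
#' @param amide_i_target Amide I normalization target (cm^-1).
#' @param amide_i_halfwidth half-width of the search window around the
#'   target within which the normalizing maximum is taken (cm^-1).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(trunc_lo = 900, trunc_hi = 1800,
                              sg_window = 7, sg_polyorder = 2,
                              awls_polyorder = 2, awls_max_iter = 50,
                              awls_tol = 1e-6, awls_peak_weight = 0.01,
                              amide_i_target = 1650,
                              amide_i_halfwidth = 10) {
  if (sg_window %% 2 != 1) stop("sg_window must be odd")
  if (sg_window <= sg_polyorder) stop("sg_window must exceed sg_polyorder")
  if (awls_max_iter < 1) stop("awls_max_iter must be >= 1")
  if (awls_tol < 0) stop("awls_tol must be non-negative")
  if (!(trunc_lo < trunc_hi)) stop("trunc_lo must be < trunc_hi")
  structure(list(trunc_lo = trunc_lo, trunc_hi = trunc_hi,
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 awls_polyorder = as.integer(awls_polyorder),
                 awls_max_iter = as.integer(awls_max_iter),
                 awls_tol = awls_tol, awls_peak_weight = awls_peak_weight,
                 amide_i_target = amide_i_target,
                 amide_i_halfwidth = amide_i_halfwidth),
            class = "preprocess_config")
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing of every spectrum. Edges are
#' handled with one-sided fits so polynomial inputs of degree up to
#' `polyorder` are reproduced exactly at every point, including the first
#' and last `(window-1)/2` channels.
#'
#' @param ds a [spectral_dataset()].
#' @param window odd window length in points.
#' @param polyorder polynomial order, `< window`.
#' @return The smoothed [spectral_dataset()].
#' @export
savitzky_golay <- function(ds, window = 7, polyorder = 2) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (window %% 2 != 1) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window > length(ds$wavenumbers))
    stop("window exceeds the number of wavenumbers")
  A <- t(apply(ds$absorbance, 1, signal::sgolayfilt,
               p = polyorder, n = window))
  spectral_dataset(ds$wavenumbers, A, ds$sample_ids, ds$replicate_ids,
                   ds$labels)
}

# One spectrum's AWLS baseline: iteratively reweighted polynomial fit in
# which points above the current fit (absorption bands) are down-weighted
# and points at/below keep full weight. Returns the fitted baseline.
awls_baseline_row <- function(y, basis, max_iter, tol, peak_weight,
                              diagnostics = FALSE) {
  w <- rep(1, length(y))
  fit_prev <- rep(0, length(y))
  sse_drop <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wb <- basis * w
    theta <- solve(crossprod(basis, wb), crossprod(wb, y))
    fit <- drop(basis %*% theta)
    if (diagnostics && it > 1) {
      # least-squares optimality: under this iteration's weights the new
      # fit can never have larger weighted SSE than the previous one
      sse_drop <- c(sse_drop,
                    sum(w * (y - fit_prev)^2) - sum(w * (y - fit)^2))
    }
    if (it > 1 && max(abs(fit - fit_prev)) < tol) {
      converged <- TRUE
      fit_prev <- fit
      break
    }
    fit_prev <- fit
    w <- ifelse(y > fit, peak_weight, 1)
  }
  list(baseline = fit_prev, converged = converged, iterations = it,
       sse_drop = sse_drop)
}

#' AWLS baseline correction
#'
#' Automatic weighted least-squares baseline removal: each spectrum's
#' baseline is an order-`polyorder` polynomial fitted by iteratively
#' reweighted least squares where points above the current fit (peaks) get
#' weight `peak_weight` and points at or below keep weight 1, iterated
#' until the fitted baseline moves less than `tol` or `max_iter` is
#' reached. Non-convergence is not an error: the last iterate is used with
#' a warning. With `max_iter = 1` this reduces to a single unweighted
#' polynomial-fit subtraction.
#'
#' @param ds a [spectral_dataset()].
#' @param polyorder baseline polynomial order.
#' @param max_iter maximum reweighting iterations.
#' @param tol convergence tolerance on the fitted baseline.
#' @param peak_weight weight for points above the fit.
#' @param diagnostics if `TRUE`, attach per-row convergence info and the
#'   per-iteration weighted-SSE improvements as attribute `"awls"`.
#' @return The baseline-corrected [spectral_dataset()].
#' @export
awls_baseline <- function(ds, polyorder = 2, max_iter = 50, tol = 1e-6,
                          peak_weight = 0.01, diagnostics = FALSE) {
  stopifnot(inherits(ds, "spectral_dataset"))
  p <- length(ds$wavenumbers)
  if (polyorder >= p) stop("polyorder must be < number of wavenumbers")
  # Chebyshev-style scaling of the abscissa keeps the normal equations
  # well conditioned at order <= 4 on any grid
  ws <- 2 * (ds$wavenumbers - min(ds$wavenumbers)) /
    (max(ds$wavenumbers) - min(ds$wavenumbers)) - 1
  basis <- outer(ws, 0:polyorder, `^`)
  A <- ds$absorbance
  info <- vector("list", nrow(A))
  for (i in seq_len(nrow(A))) {
    r <- awls_baseline_row(A[i, ], basis, max_iter, tol, peak_weight,
                           diagnostics)
    A[i, ] <- A[i, ] - r$baseline
    info[[i]] <- r[c("converged", "iterations", "sse_drop")]
  }
  if (max_iter > 1 && !all(vapply(info, `[[`, TRUE, "converged")))
    warning("AWLS did not converge for ",
            sum(!vapply(info, `[[`, TRUE, "converged")),
            " spectrum/spectra; last iterate used")
  out <- spectral_dataset(ds$wavenumbers, A, ds$sample_ids,
                          ds$replicate_ids, ds$labels)
  if (diagnostics) attr(out, "awls") <- info
  out
}

#' Amide I normalization
#'
#' Divides each spectrum by its maximum absorbance within
#' `[target - halfwidth, target + halfwidth]`. The window maximum (rather
#' than the literal grid point at `target`) is used because the Amide I
#' band centre can shift by a few wavenumbers between samples; after
#' normalization the window maximum of every row equals exactly 1.
#'
#' @param ds a [spectral_dataset()].
#' @param target band position (cm^-1), default 1650 (Amide I).
#' @param halfwidth search half-width (cm^-1).
#' @return The normalized [spectral_dataset()].
#' @export
normalize_amide_i <- function(ds, target = 1650, halfwidth = 10) {
  stopifnot(inherits(ds, "spectral_dataset"))
  win <- which(ds$wavenumbers >= target - halfwidth &
                 ds$wavenumbers <= target + halfwidth)
  if (!length(win))
    stop("normalization window [", target - halfwidth, ", ",
         target + halfwidth, "] contains no grid point")
  m <- apply(ds$absorbance[, win, drop = FALSE], 1, max)
  if (any(m <= 0)) {
    bad <- ds$sample_ids[which(m <= 0)]
    stop("non-positive Amide I window maximum for sample(s): ",
         paste(unique(bad), collapse = ", "))
  }
  spectral_dataset(ds$wavenumbers, ds$absorbance / m, ds$sample_ids,
                   ds$replicate_ids, ds$labels)
}

#' Full preprocessing chain
#'
#' Applies, in this fixed order: truncation to the biofingerprint region,
#' Savitzky-Golay smoothing, AWLS baseline correction and Amide I
#' normalization. The applied parameters are attached as attribute
#' `"provenance"`.
#'
#' @param ds a [spectral_dataset()] (typically replicate-averaged first).
#' @param cfg a [preprocess_config()].
#' @return The preprocessed [spectral_dataset()].
#' @export
preprocess <- function(ds, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  out <- truncate_spectra(ds, cfg$trunc_lo, cfg$trunc_hi)
  out <- savitzky_golay(out, cfg$sg_window, cfg$sg_polyorder)
  out <- awls_baseline(out, cfg$awls_polyorder, cfg$awls_max_iter,
                       cfg$awls_tol, cfg$awls_peak_weight)
  out <- normalize_amide_i(out, cfg$amide_i_target, cfg$amide_i_halfwidth)
  attr(out, "provenance") <- unclass(cfg)
  out
}
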