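#' Default absorption-band library for synthetic plasma spectra
#'
#' Sixteen Gaussian bands at wavenumbers typical of blood-plasma
#' biofingerprints (phosphodiesters, polysaccharides, Amide III/I,
#' nucleic-acid carbonyls, lipid C=O), with the Amide I region (1643/1661
#' cm^-1) carrying by far the largest amplitude so that Amide I
#' normalization is always well posed.
#'
#' @return data.frame with columns `centre` (cm^-1), `width` (Gaussian sd,
#'   cm^-1), `base_amplitude` (absorbance) and `class_effect` (additive
#'   absorbance shift applied to the positive class; 0 by default).
#' @export
default_band_library <- function() {
  data.frame(
    centre = c(901, 959, 980, 999, 1018, 1277, 1311, 1364,
               1402, 1464, 1489, 1582, 1626, 1643, 1661, 1742),
    width = c(10, 9, 9, 8, 9, 12, 11, 11, 10, 10, 10, 10, 12, 14, 13, 9),
    base_amplitude = c(0.12, 0.10, 0.10, 0.14, 0.16, 0.15, 0.18, 0.14,
                       0.22, 0.20, 0.12, 0.15, 0.45, 0.95, 0.60, 0.18),
    class_effect = 0
  )
}

#' Synthetic-cohort generator configuration
#'
#' Describes a plasma-like ATR-FTIR cohort: Gaussian absorption bands on a
#' regular wavenumber grid, a broad polynomial baseline with a random
#' per-sample scale, triplicate measurements with additive Gaussian noise,
#' and a class-dependent additive intensity shift at a planted subset of
#' marker bands. Defaults emulate a 476-patient screening cohort measured
#' over 600-4000 cm^-1 at 2 cm^-1 spacing, balanced classes, effect size
#' 0.05 absorbance at four markers, noise sd 0.01.
#'
#' @param n_samples number of samples (patients).
#' @param positive_fraction fraction of positive ("BC") samples, in (0,1).
#' @param grid_lo,grid_hi,grid_spacing wavenumber grid (cm^-1).
#' @param bands band library as from [default_band_library()].
#' @param marker_subset integer indices into `bands` that carry the class
#'   effect.
#' @param class_effect signed absorbance shift added to the marker bands'
#'   amplitudes for positive-class samples.
#' @param baseline_coefs polynomial coefficients (constant first) of the
#'   baseline on the grid rescaled to [-1, 1].
#' @param baseline_scale_range range of the uniform per-sample scale
#'   multiplying the baseline.
#' @param amplitude_jitter relative sd of the per-sample, per-band
#'   amplitude variability (biological spread); each band's amplitude in a
#'   given sample is scaled by `1 + N(0, amplitude_jitter)`. This is what
#'   makes the two classes overlap instead of being separable at a single
#'   channel.
#' @param noise_sd additive Gaussian noise sd per replicate (absorbance).
#' @param replicates measurements per sample.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_samples = 476, positive_fraction = 0.5,
                             grid_lo = 600, grid_hi = 4000,
                             grid_spacing = 2,
                             bands = default_band_library(),
                             marker_subset = which(bands$centre %in%
                                                     c(1018, 1311, 1464, 1582)),
                             class_effect = 0.05,
                             baseline_coefs = c(0.3, -0.1, 0.08),
                             baseline_scale_range = c(0.5, 1.5),
                             amplitude_jitter = 0.10,
                             noise_sd = 0.01, replicates = 3) {
  if (!(positive_fraction > 0 && positive_fraction < 1))
    stop("positive_fraction must be in (0, 1)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (replicates < 1) stop("replicates must be >= 1")
  if (any(bands$width <= 0)) stop("band widths must be positive")
  if (any(bands$base_amplitude < 0))
    stop("band amplitudes must be non-negative")
  if (length(marker_subset) &&
      (min(marker_subset) < 1 || max(marker_subset) > nrow(bands)))
    stop("marker_subset must index rows of `bands`")
  bands$class_effect[marker_subset] <- class_effect
  structure(list(n_samples = as.integer(n_samples),
                 positive_fraction = positive_fraction,
                 grid_lo = grid_lo, grid_hi = grid_hi,
                 grid_spacing = grid_spacing, bands = bands,
                 marker_subset = as.integer(marker_subset),
                 baseline_coefs = baseline_coefs,
                 baseline_scale_range = baseline_scale_range,
                 amplitude_jitter = amplitude_jitter,
                 noise_sd = noise_sd, replicates = as.integer(replicates)),
            class = "generator_config")
}

#' Generate a synthetic plasma-spectrum cohort
#'
#' Each sample's noiseless template is the sum of the configured Gaussian
#' bands (marker bands shifted by their `class_effect` for positive-class
#' samples) plus the polynomial baseline times a per-sample random scale;
#' each replicate adds iid Gaussian noise. Deterministic given `seed`.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed.
#' @return A list with `dataset` (a [spectral_dataset()] with replicate
#'   rows) and `truth` (labels per sample, marker wavenumbers on the grid,
#'   noiseless template matrix, the config and the seed).
#' @export
generate_spectra <- function(cfg = generator_config(), seed = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  wn <- seq(cfg$grid_lo, cfg$grid_hi, by = cfg$grid_spacing)
  p <- length(wn)
  n <- cfg$n_samples
  ws <- if (p > 1) 2 * (wn - wn[1]) / (wn[p] - wn[1]) - 1 else 0
  baseline <- drop(outer(ws, seq_along(cfg$baseline_coefs) - 1, `^`) %*%
                     cfg$baseline_coefs)
  # band profiles, one column per band, unit amplitude
  profiles <- exp(-outer(wn, cfg$bands$centre, `-`)^2 /
                    matrix(2 * cfg$bands$width^2, p, nrow(cfg$bands),
                           byrow = TRUE))
  n_bands <- nrow(cfg$bands)
  with_seed(seed, {
    n_pos <- round(n * cfg$positive_fraction)
    labels <- sample(c(rep("BC", n_pos), rep("HC", n - n_pos)))
    scales <- stats::runif(n, cfg$baseline_scale_range[1],
                           cfg$baseline_scale_range[2])
    # per-sample band amplitudes: class shift on markers for positives,
    # plus relative biological jitter
    amps <- matrix(cfg$bands$base_amplitude, n, n_bands, byrow = TRUE)
    amps[labels == "BC", ] <- amps[labels == "BC", , drop = FALSE] +
      matrix(cfg$bands$class_effect, sum(labels == "BC"), n_bands,
             byrow = TRUE)
    if (cfg$amplitude_jitter > 0)
      amps <- amps * (1 + matrix(stats::rnorm(n * n_bands,
                                              sd = cfg$amplitude_jitter),
                                 n, n_bands))
    templates <- tcrossprod(amps, profiles) + outer(scales, baseline)
    r <- cfg$replicates
    A <- templates[rep(seq_len(n), each = r), , drop = FALSE]
    if (cfg$noise_sd > 0)
      A <- A + matrix(stats::rnorm(n * r * p, sd = cfg$noise_sd), n * r, p)
    ds <- spectral_dataset(wn, A,
                           sample_ids = rep(sprintf("S%03d", seq_len(n)),
                                            each = r),
                           replicate_ids = rep(seq_len(r), n),
                           labels = rep(labels, each = r))
    marker_wn <- wn[vapply(cfg$bands$centre[cfg$marker_subset],
                           function(ct) nearest_wavenumber(wn, ct), 1L)]
    list(dataset = ds,
         truth = list(labels = labels, marker_wavenumbers = marker_wn,
                      templates = templates, baseline_scales = scales,
                      config = cfg, seed = seed))
  })
}
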