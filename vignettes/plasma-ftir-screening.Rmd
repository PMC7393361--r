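---
title: "Chemometric screening of blood plasma by ATR-FTIR: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric screening of blood plasma by ATR-FTIR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectroscreen)
```

## The problem

Attenuated total reflection Fourier-transform infrared (ATR-FTIR)
spectroscopy of blood plasma produces an absorbance fingerprint of the
circulating biochemistry: nucleic-acid phosphodiesters, carbohydrate C–O
stretches, protein Amide bands, lipid carbonyls. A screening test built on
this fingerprint asks a binary question — does this plasma sample come from
a disease (BC, positive) or healthy-control (HC, negative) patient? —
and answers it with a chain of standard chemometric machinery:

1. **preprocessing** of each spectrum,
2. a **representative split** of samples into training, validation and
   test sets,
3. **feature reduction** of the several-hundred-channel fingerprint to a
   handful of informative variables,
4. a **classifier** on the reduced variables,
5. **diagnostic figures of merit** on the held-out test set.

The package implements all five stages and a synthetic-cohort generator
with known ground truth. The reference cohort this design emulates (476
patients, triplicate measurements, 600–4,000 cm⁻¹ at 2 cm⁻¹ spacing) was
never deposited, so every quantitative claim the package makes is computed
either from published summary arithmetic (see `reference_metric_table()`)
or from synthetic data.

## Preprocessing

The chain is fixed, in this order, on replicate-averaged spectra:

* **Truncation** to the biofingerprint region, closed interval
  [900, 1800] cm⁻¹ (451 channels at 2 cm⁻¹ spacing). The interval is
  closed on both ends; an open or half-open reading would differ by at
  most one channel.
* **Savitzky–Golay smoothing**, default window 7 points, 2nd-order
  polynomial. Edges are fitted with one-sided windows, so polynomials up
  to the filter order are reproduced exactly at every channel. A 15-point
  window is also in circulation for this kind of data; both are exposed
  through `preprocess_config(sg_window =)`, and the 7-point default was
  chosen because it is the setting attached to the published preprocessed
  spectra the pipeline emulates.
* **AWLS baseline correction** — automatic weighted least squares:
  an order-2 polynomial fitted per spectrum by iteratively reweighted
  least squares in which points *above* the current fit (absorption
  bands) get weight 0.01 and points at or below keep weight 1. Iteration
  stops when the fitted baseline moves by less than 1e-6 absorbance or
  after 50 iterations; non-convergence keeps the last iterate and warns.
  The method is named in the literature without parameters; the weight
  asymmetry (1 vs 0.01), tolerance and iteration cap are this package's
  defaults, all configurable. Within each iteration the weighted SSE can
  only decrease (least-squares optimality), which the tests assert.
* **Amide I normalization**: each spectrum is divided by its *maximum*
  absorbance within ±10 cm⁻¹ of 1,650 cm⁻¹, rather than by the literal
  1,650 channel. "The Amide I peak" denotes a band whose apex shifts by a
  few wavenumbers between samples; the window maximum tolerates that
  shift and makes the normalized window maximum exactly 1.

## Splitting: Kennard–Stone 70/15/15

`kennard_stone()` is the classical deterministic max–min procedure: start
from the two mutually most distant samples, then repeatedly add the sample
maximizing its minimum Euclidean distance to everything already selected.
Ties break toward the lowest row index, making the ranking fully
deterministic. `split_dataset()` ranks **all** samples and assigns the
first `N - round(0.15N) - round(0.15N)` ranks to training, the next
`round(0.15N)` to validation and the remainder to testing, so N = 476
gives 334/71/71. Training receives the most representative ranks because
the training set must span the data cloud; the ranking is computed once,
globally, not per class — that is what reproduces the 334/71/71 arithmetic
independently of class balance.

## Feature reduction and the cost function G

All three reducers are driven (directly or for model-order selection) by
a validation-set cost: for validation sample *n*,

$$g_n = \frac{r^2(x_n, m_{\mathrm{own}})}{\min_{\mathrm{wrong}} r^2(x_n, m_{\mathrm{wrong}})},$$

the ratio of squared Mahalanobis distances to the own-class and nearest
wrong-class training means, and \(G\) is the mean of \(g_n\) over the
validation set; selection fitness is \(1/G\). The Mahalanobis metric uses
the **pooled** training covariance of the candidate variables — the
natural choice in a linear-discriminant context, and one covariance
inversion per candidate keeps the search cheap. Covariances are ridged with
\(\lambda I\), \(\lambda = 10^{-6}\,\mathrm{tr}(C)/d\), whenever the
smallest eigenvalue drops below \(10^{-10}\); the applied ridge is
recorded in the fitted statistics.

* **PCA** (`pca_select()`): mean-centred principal components, component
  count chosen by minimizing G on the validation set over 1..20. Sign
  convention: the largest-magnitude loading element is positive.
* **SPA** (`spa_select()`): from every possible starting channel a chain
  is grown by appending the channel with the largest column norm after
  orthogonal projection out of the span of the chosen columns (computed
  in Gram space, so the scan over all 451 starts stays fast); every
  prefix of every chain is scored with G and the minimizer wins, ties
  toward shorter chains then lower start index. SPA only *selects*
  channels — it never rotates the data space.
* **GA** (`ga_select()`): binary chromosomes over channels, fitness
  \(1/G\), roulette parent selection, single-point crossover with
  probability 0.60, per-bit mutation at rate 0.10/length, elitism of one,
  empty chromosomes repaired by activating a random bit; the best final
  chromosome across 3 independent realizations of 100 generations × 200
  chromosomes wins. Operator details (roulette, single-point, elitism 1)
  are fixed here for reproducibility; the generation/population/rate
  budget follows standard wavelength-selection practice. Initial
  chromosomes activate ~15 channels on average, a sparse start that
  matches the target solution size.

## Classifiers

`fit_discriminant()` implements *non-Bayesian* discriminant analysis: the
score of sample *x* against class *k* is the bare quadratic form
\((x-\bar x_k)^\top C^{-1}(x-\bar x_k)\) with \(C\) the pooled covariance
(LDA) or class covariance (QDA) — no priors, no log-determinants. The
label is the argmin; exact ties go to the positive class (screening
favours sensitivity) and are flagged. When all class covariances coincide
QDA reproduces LDA exactly, which the tests assert.

`fit_svm()` is a soft-margin SVM with the radial-basis-function kernel
\(k(x,z) = \exp(-\gamma\lVert x-z\rVert^2)\), \(\gamma = 1\) fixed. The
dual problem is solved by libsvm (via e1071); the package keeps the dual
solution (support vectors, multipliers \(\alpha_i y_i\), bias) and
evaluates the decision function
\(f(z)=\sum_i \alpha_i y_i k(x_i,z)+b\) itself, oriented so positive
values indicate the positive class. The box constraint C is tuned on the
validation set over {0.01, 0.1, 1, 10, 100, 1000} by validation accuracy,
ties toward the smaller (more regularized) C. Tests verify the decision
values against an independent quadratic-programming solve of the same
dual (kernlab::ipop) and the KKT conditions on free support vectors.

## Figures of merit and ROC

`figures_of_merit()` computes AC, SENS, SPEC, Youden's index
(SENS − (100 − SPEC)), PPV, NPV, and two summary scores:
F = 2·SENS·SPEC/(SENS+SPEC) and G = √(SENS·SPEC). **Note** that this
F-score is the harmonic mean of sensitivity and *specificity* — the
convention of the screening literature this package follows — not the
precision/recall F1. Percentages are kept at full precision internally;
`round_half_up()` (half away from zero, one decimal) matches the rounding
style of published tables, which R's default half-to-even would not.
Undefined predictive values (empty prediction classes) are reported as
`NA`, never 0. The AUC is the Mann–Whitney rank statistic with ties
counted ½, hence invariant under monotone score transforms.

`reconstruct_confusion()` inverts the display rounding: it enumerates all
integer confusion matrices with given class sizes and keeps those whose
rounded metrics match a printed row — with 35/35 test samples the best
published screening row is matched by exactly one matrix
(TP 33, FN 2, FP 3, TN 32).

## The synthetic generator

`generate_spectra()` builds cohorts with known ground truth. Each sample
is a sum of 16 Gaussian bands at canonical plasma wavenumbers (901–1,742
cm⁻¹), with the Amide I region (1,643/1,661 cm⁻¹) dominant so
normalization is always well-posed, plus a broad polynomial baseline with
a per-sample random scale; each of the 3 replicates adds iid Gaussian
noise (sd 0.01 absorbance). Positive-class samples get an additive
amplitude shift of +0.05 on four marker bands (1,018, 1,311, 1,464,
1,582 cm⁻¹).

Two design choices deserve comment:

* **Band shape is Gaussian** (not Lorentzian/Voigt): the simplest shape
  that exercises selection and classification logic; band physics is not
  the target of the simulation.
* **Per-sample amplitude jitter** (`amplitude_jitter = 0.10`): every
  band's amplitude in every sample is scaled by \(1 + N(0, 0.1)\).
  Without it all samples of a class share one exact template and a
  single channel separates the classes perfectly — nothing like real
  plasma spectra, whose classes overlap heavily. A 10% relative spread
  is a realistic biological variability for plasma band intensities and
  is what makes multivariate selection genuinely necessary.

What the generator does **not** emulate: ATR penetration-depth physics,
water-vapour lines, scattering artefacts, instrument drift, or
correlated biochemical co-variation between bands. Passing tests on this
generator therefore demonstrate that the *algorithms* behave as specified
— not that the pipeline would reach any particular accuracy on real
cohorts.

## Marker recovery and a known limitation

With the default conditions (476 samples, effect 0.05, noise 0.01,
jitter 0.10), SPA usually places selected channels on the exact centres
of the four marker bands: its chain proposals are driven by column
norms, which peak at band centres. Its occasional failures are cohorts
where the prefix-G minimum lands on a *single* strong in-band channel —
one channel of a marker band already separates the classes almost as
well as the four centres, and with hundreds of candidate prefixes the
validation minimum sometimes falls there. The GA identifies the marker
*bands* but rarely the exact centres: the validation cost G is flat to
within noise across each band's width (the class effect is an amplitude
shift on bands of sd 8–14 cm⁻¹, so any channel inside a band carries
nearly the full effect), and a G-driven optimizer has no gradient toward
the centre channel. Recovery scored at ±2 cm⁻¹ (one grid point) is
therefore common for SPA but rare for the GA, while at ±10 cm⁻¹ (about
one band sd) the GA's rate rises several-fold;
`analysis/04_marker_recovery.R` reports both tolerances per run. This is
a property of wide-band amplitude effects, not of the GA implementation
— the package reports it rather than hiding it behind a narrower, less
realistic marker band.

## Numerical choices and degenerate inputs

* Covariance ridge: λ = 1e-6·tr(C)/d when min eigenvalue < 1e-10, logged
  in the fitted statistics.
* A validation point exactly at a wrong-class mean makes \(g_n\)
  infinite; it is flagged, not silently clipped.
* AWLS non-convergence warns and keeps the last iterate.
* Collinearity exhausts an SPA chain early (projected norms ~ 0); the
  chain is truncated. Duplicated channels can never be selected twice
  (zero projected norm).
* Empty GA chromosomes are repaired by activating one random bit.
* Classifier ties (equal scores, zero SVM decision) resolve toward the
  positive class and are flagged — a screening test should fail toward
  sensitivity.
* All stochastic stages derive their seeds from one base seed via fixed
  offsets, so results are bit-reproducible and any stage can be rerun in
  isolation.

## Problem sizes used in tests and scripted analyses

Unit and property tests run on reduced cohorts (typically 60 samples on a
900–1800 cm⁻¹ grid at 10 cm⁻¹ spacing) that preserve the full structure
of the study conditions; end-to-end recovery checks and the acceptance
script run the full 476-sample, 2 cm⁻¹ configuration with a GA budget of
60 generations × 80 chromosomes × 1 realization per run, the point at
which the GA's selection behaviour has stabilized (its full-budget
behaviour is identical in kind, as `analysis/03_model_comparison.R`
shows). The null-accuracy check uses 200-sample cohorts: with smaller
cohorts the fixed class counts make train- and test-set label proportions
anti-correlated, which can bias null accuracy below 50% — a
finite-population artefact, not a generator asymmetry.
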