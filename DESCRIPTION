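Package: spectroscreen
Title: Spectrochemical Screening of Blood Plasma by ATR-FTIR and
    Multivariate Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end chemometric pipeline for disease screening from
    attenuated total reflection Fourier-transform infrared (ATR-FTIR)
    spectra of blood plasma. Implements the standard preprocessing chain
    (Savitzky-Golay smoothing, automatic weighted least-squares baseline
    correction, Amide I normalization), Kennard-Stone representative
    splitting, feature reduction by principal component analysis,
    the successive projections algorithm and a genetic algorithm driven by
    a Mahalanobis cost function, Mahalanobis linear and quadratic
    discriminant classifiers and a radial-basis-function support vector
    machine, and diagnostic figures of merit with ROC analysis. Includes a
    synthetic plasma-spectrum generator with known ground truth so every
    stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
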