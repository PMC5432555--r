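Package: bispecref
Title: Reference-Induced Distortion of EEG Bispectral Measures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how the choice of EEG reference (vertex Cz,
    digitally linked mastoids, average reference, and the Reference
    Electrode Standardization Technique, REST) distorts bispectral
    measures of non-linear coupling: bicoherence, cross-bicoherence and
    the antisymmetric cross-bicoherence.  Provides an analytic
    three-concentric-shell spherical head model with idealized 10-20 /
    10-10 / 10-5 electrode layouts, a forward-modelled simulator of
    quadratically phase-coupled dipole sources, segmented-FFT bispectral
    estimators, a relative-error evaluation harness against the
    infinity-reference gold standard, and permutation-based group
    statistics with false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
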