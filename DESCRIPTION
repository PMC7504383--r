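Package: fluospec
Title: Predicting Chlorophyll Fluorescence Parameters from Leaf Hyperspectral Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for leaf-level vegetation spectroscopy and
    pulse-amplitude-modulation (PAM) chlorophyll fluorescence. Computes the
    standard quenching-analysis parameters (Fv/Fm, PhiPSII, qP, qN, NPQ, qL,
    ETR and relatives) from raw fluorescence yields, predicts them from
    350-2500 nm leaf reflectance with a from-scratch NIPALS partial least
    squares regression (permutation-ensemble validation, PRESS-based component
    selection, VIP and standardized-coefficient diagnostics), screens spectra
    for common acquisition artifacts, and phenotypes ozone-treatment groups
    from full spectral signatures via PERMANOVA, principal coordinates
    analysis, and PLS discriminant analysis scored by Cohen's kappa. A
    synthetic-data generator emulating the coupled spectra/fluorescence/
    treatment structure of an ozone FACE experiment makes the whole chain
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
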