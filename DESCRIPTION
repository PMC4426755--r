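Package: tspray
Title: Chemometric Classification of Tissue-Spray Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and chemometric analysis of tissue-spray ionization
    mass spectrometry (TSI-MS) fingerprints for two-class tissue
    discrimination (cancer vs. adjacent normal). Provides a calibrated
    synthetic cohort generator, peak-list input/output (CSV, MGF, mzML),
    spectral binning onto fixed m/z grids with base-peak normalisation,
    partial least squares linear discriminant analysis (NIPALS PLS-LDA),
    Monte Carlo sampling cross-validation, competitive adaptive reweighted
    sampling (CARS) variable selection, and univariate peak statistics
    (class means, Student's/Welch's t, replicate relative standard
    deviations).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
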