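Package: tscqeeg
Title: Quantitative EEG Dysmaturity Analysis for Infants with Tuberous
    Sclerosis Complex
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the association between early EEG background
    dysmaturity and neurodevelopmental outcome in infants with tuberous
    sclerosis complex (TSC). Provides a synthetic neonatal EEG generator with
    controllable maturity characteristics (discontinuity, slow-delta content,
    interhemispheric asynchrony), four quantitative EEG feature families
    (relative band power, range-EEG asymmetry, multiscale sample entropy,
    Hurst exponent by detrended fluctuation analysis), linear discriminant
    classification with stratified three-fold testing, and the clinical
    outcome statistics used in early-biomarker cohort studies (ADOS-2 risk
    categorisation, 2x2 diagnostic metrics, odds ratios, logistic and linear
    models, Mann-Whitney tests). Includes EDF input/output and a seeded
    end-to-end pipeline so every stage is reproducible without access to
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
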