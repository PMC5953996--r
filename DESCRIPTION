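Package: dynamicMFR
Title: Myocardial Blood Flow and Flow Reserve from Dynamic SPECT and PET
    Time-Activity Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kinetic quantification of myocardial blood flow (MBF) and
    myocardial flow reserve (MFR) from frame-binned dynamic rest/stress
    time-activity curves. Implements the net-retention model for dynamic
    Tc-99m-sestamibi CZT-SPECT with flow-dependent extraction correction by
    inversion of the Renkin-Crone relation, and a one-tissue-compartment
    model for O-15-water PET with perfusable tissue fraction and arterial
    blood volume terms. Includes a fully specified synthetic cohort
    generator (gamma-variate arterial input functions, trapping and washout
    tissue kinetics, spillover, partial volume, count-statistics noise) with
    known ground-truth flows and fractional flow reserve (FFR), plus the
    diagnostic-concordance layer: threshold classification, 2x2 contingency
    metrics, Cohen's kappa, ROC/AUC with Youden cutoff selection,
    Bland-Altman limits of agreement and Pearson correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
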