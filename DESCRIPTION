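Package: ramantdm
Title: Resonance Raman Therapeutic Drug Monitoring of Piperacillin in Urine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for deep-UV resonance Raman therapeutic drug
    monitoring of the beta-lactam antibiotic piperacillin in human urine.
    Implements the spectral conditioning chain (wavenumber calibration,
    Savitzky-Golay smoothing, extended multiplicative signal correction,
    SNIP baseline removal, vector and maxima normalization), NIPALS partial
    least squares calibration with cross-validated component selection,
    a closed-form correction-factor statistic quantifying concentration loss
    from clinical sample-preparation steps (freezing, filtration,
    centrifugation), marker-band quantification with ICH limits of detection
    against alternative urine reference matrices, and donor-sex
    classification (PCA + LDA/SVM with threshold-averaged ROC). A seeded
    synthetic urine-spectrum generator provides test data with the
    statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    signal,
    minpack.lm,
    MASS,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
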