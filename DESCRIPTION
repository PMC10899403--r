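Package: restpower
Title: Resting-State EEG Band Power, Asymmetry and Diagnostic Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resting-state EEG biomarker analysis of major depressive
    disorder: a synthetic two-group cohort generator with configurable regional
    band effects, ocular and excursion artifacts and clinical-score coupling; a
    preprocessing chain (zero-phase band-pass and notch filtering, downsampling,
    ICA-based ocular artifact removal, 2-s epoching, amplitude-based epoch
    rejection, average re-referencing); six-band relative spectral power over
    ten 10-20 regions of interest with right-minus-left hemispheric asymmetry
    scores; FDR-corrected group contrasts with effect sizes; and a
    cross-validated logistic diagnostic model with ROC analysis and
    Youden-index cut-offs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    tidyr,
    jsonlite
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
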