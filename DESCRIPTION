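Package: ecgkit
Title: Cross-Dataset ECG Harmonization and Model-Audit Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spectral harmonization of 12-lead electrocardiograms for
    cross-dataset deep-learning work, together with the audit machinery used
    to evaluate such models. The harmonization pipeline applies a conditional
    1 Hz high-pass filter (triggered by sub-1 Hz log-power excess), detects
    50/60 Hz powerline peaks and their harmonics with a 2-standard-deviation
    local rule, flattens them against a LOESS spectral baseline, and rescales
    amplitudes to a reference profile. Audit tools cover multilabel AUROC and
    AUPRC with 70 percent subsample confidence intervals, the DeLong test,
    balanced sensitivity-specificity threshold selection, equalized-odds
    disparity bootstraps across age and sex groups, random-forest membership
    inference attacks with t-SNE separation diagnostics, and LIME-style
    segment attribution for multichannel 1-D signals. A synthetic ECG and
    prediction-set generator with exact contamination oracles makes every
    component testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    Rtsne,
    cluster,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
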