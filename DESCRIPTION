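Package: mstquant
Title: Quantification of Fecal Contamination from qPCR and Culture Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for measuring and explaining fecal
    contamination in domestic environments. Implements validation of
    microbial source tracking qPCR assays with ROC-derived integer Cq
    cutoffs selected by the Youden index; multilevel Bayesian calibration
    curves with slopes and intercepts varying by instrument run and
    extraction batch, with posterior uncertainty propagated into per-sample
    log10 concentration estimates; sample-specific process limits of
    detection for culture and molecular targets; colony-count arithmetic
    with too-numerous-to-count censoring; maximum-likelihood inference for
    censored normal concentration distributions with truncated-normal
    imputation; and univariable Bayesian censored linear and logistic
    risk-factor regressions with compound-varying intercepts. A synthetic
    data generator with known ground truth emulates the structure of a
    household fecal-contamination survey so every stage can be exercised
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fitdistrplus,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
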