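Package: tailorcut
Title: Tailored Fit-Index Cutoffs for Latent-Variable Models via Simulation and ROC Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Generates tailored cutoffs for confirmatory factor analysis (CFA)
    fit indices by Monte Carlo simulation. Users define a correctly specified
    (H0) and a misspecified (H1) population model matched to their empirical
    setting; the package simulates replicate datasets from both (multivariate
    normal or non-normal via Fleishman polynomials and the Vale-Maurelli
    intermediate-correlation construction), fits the analysis model by normal
    theory maximum likelihood with an optional Satorra-Bentler-type robust
    scaling correction, and records chi-square, CFI, RMSEA and SRMR. Fit
    indices are then ranked by the area under the ROC curve formed from their
    H0/H1 distributions, screened against an AUC threshold, and Youden-optimal
    cutoffs are reported together with accuracy and type I/II error rates,
    yielding an accept/reject decision for an empirical model. Population-level
    misspecification effect sizes (population discrepancy and RMSEA) and
    robustness checks over alternative misspecification forms are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
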