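Package: shapCSA
Title: SHAP-Guided Contribution Selection for Binary EHR Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Feature selection and interpretation for small case-control
    cohorts described by binarized electronic-health-record problem lists.
    Implements a contribution selection algorithm (CSA): backward elimination
    driven by Shapley-value feature attributions of a Gaussian-kernel support
    vector machine, evaluated by repeated stratified k-fold cross-validation
    with bootstrap confidence intervals. Includes an exact Shapley enumerator
    and a Kernel SHAP weighted-least-squares estimator, cohort summary
    statistics (Welch's t-test, two-sided Fisher's exact test by
    hypergeometric enumeration), a synthetic problem-list cohort generator
    with planted discriminative features, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
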