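Package: lcmsprep
Title: Normalization and Missing-Value Handling for Label-Free LC-MS
    Peptide Abundance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Preprocessing toolkit for label-free LC-MS peptide-by-sample
    abundance matrices. Implements global centering, lowess MA-plot
    normalization against a reference sample, fixed-effects ANOVA bias
    models with sum-to-zero constraints, and SVD-based eigentrend removal
    from model residuals with permutation-based trend selection and
    residual variance re-inflation. Missing values are handled through a
    joint likelihood for left-censored and missing-completely-at-random
    cells, with Fisher-information peptide filtering, model-based
    truncated-normal imputation, naive imputation baselines, and
    right-tail p-value adjustment. Includes a peptide-level simulator
    with ground-truth bookkeeping and drivers for confidence-interval
    coverage, normalization/imputation ordering, and null p-value
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
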