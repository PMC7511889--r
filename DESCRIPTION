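Package: braincca
Title: Sparse Canonical Correlation Analysis for Brain-Behavior Association
    with Permutation Inference and Reliability Resampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links a block of behavioral and questionnaire measures (including
    formula-defined social-optimism-bias scores computed from raw likelihood
    ratings) to a block of regional cortical-thickness values via sparse
    canonical correlation analysis based on the L1-penalized matrix
    decomposition, with successive-mode deflation, permutation significance
    testing, a reliability battery (leave-one-out influence, split-half
    weight transfer, redundancy-reliability scores, sample-size/overfitting
    checks), covariate-adjusted post hoc correlations, and a synthetic-data
    generator that plants sparse cross-block latent modes with known loadings
    and canonical correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
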