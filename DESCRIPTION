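Package: tracemtl
Title: Trace-Norm Multitask Regression for Drug Sensitivity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint prediction of drug response across many drugs from cancer
    cell line molecular features using trace-norm (nuclear-norm) regularized
    multitask linear regression, solved by an ADMM algorithm with
    singular-value soft-thresholding and warm-started regularization paths.
    Includes single-task elastic net and nearest-drug-response baselines,
    inductive and transductive nested cross-validation with paired
    signed-rank model comparison, a permutation-based label-noise test for
    drug response profiles, weight-matrix interpretation tools (Ward
    clustering of drug models, adjusted Rand index, hypergeometric gene-set
    enrichment), and a synthetic low-rank data generator for offline
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
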