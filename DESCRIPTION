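Package: chirtransfer
Title: Knowledge-Transfer Modelling of Enantioselectivity for Chiral
    Carboxylic Acid Catalyst Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven knowledge transfer for predicting the
    enantioselectivity of chiral-carboxylic-acid (CCA) co-catalysed C-H
    alkylations. A base regressor (linear support vector regression by
    default) is trained on physical-organic descriptor encodings of a
    data-rich source reaction; a delta-learning model trained on a handful
    of target-reaction measurements captures the structure-performance
    perturbation between the two reactions; the corrected predictor ranks
    a combinatorial library of candidate CCAs by predicted enantiomeric
    excess. Includes conversion between enantiomeric excess and
    transition-state free-energy differences, k-fold and leave-one-out
    evaluation, a naive pooled-training baseline, virtual screening with
    distribution binning, and a synthetic-data generator with a known
    latent structure-performance relationship for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    caret,
    randomForest,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
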