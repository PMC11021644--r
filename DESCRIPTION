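Package: neopredict
Title: Feature-Based Prediction of Neoepitope Immunogenicity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes peptide-level physicochemical descriptors,
    mutation-quality and tumor-microenvironment covariates for
    tumor neoepitope candidates, trains a class-balanced random
    forest subsampling ensemble under leakage-aware fivefold
    cross-validation (patients and motif-sharing immunogenic
    peptides never span folds), and evaluates predictions with
    ROC/partial-AUC, DeLong comparisons, sensitivity-specificity
    intersection thresholding and per-patient top-k capture.
    Includes quartile-based survival stratification by predicted
    neoepitope load and a synthetic multi-patient screen generator
    with planted signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ranger,
    survival,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'peptide-features.R'
    'context-features.R'
    'dataset.R'
    'partitioning.R'
    'model.R'
    'evaluation.R'
    'survival.R'
    'synthetic.R'
    'pipeline.R'
    'neopredict-package.R'
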