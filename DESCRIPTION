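Package: gwasdnn
Title: Enhancing GWAS Signals with a Deep Neural Network over LD and
    Functional Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates genome-wide association study (GWAS) summary
    statistics, linkage-disequilibrium (LD) features computed from a
    genotype reference panel, and functional annotations into a
    33-feature per-variant representation, and trains a 14-layer fully
    connected neural network -- with binary labels taken from a larger
    study of the same trait -- to predict each variant's probability of
    true association. Predicted-significant variants and loci absent
    from the input study are reported as "enhanced" findings, evaluated
    at variant and locus level (TPR, F1, ROC, PRC), and a trained model
    can be applied with frozen weights to other traits. Includes
    logistic-regression and gradient-boosted-tree baselines and a
    synthetic-data generator (block-LD panels, paired studies of
    differing power, enriched annotations) with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    withr,
    IRanges,
    vcfR,
    xgboost,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
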