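Package: gdlnet
Title: Genome Deep Learning for Variant-Based Cancer-Type Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the genome deep learning (GDL) approach to phenotype
    classification from somatic point-mutation profiles. Per-sample VCF files
    are encoded as binary presence/absence vectors against a frequency-ranked
    Mutation Collection of recurrent variant sites; a fully connected softmax
    network is trained by back-propagated gradient descent with exponential
    learning-rate decay, L2 weight regularization and exponentially weighted
    moving-average shadow parameters used at inference. Includes the full
    evaluation battery (accuracy/sensitivity/specificity, ROC/AUC, confusion
    matrices, top-N accuracy, shared-dimension analysis), a synthetic cohort
    simulator with planted per-class signature sites for end-to-end testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
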