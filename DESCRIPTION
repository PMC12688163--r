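Package: hrdclass
Title: Multi-Modal Semi-Supervised Classification of Homologous
    Recombination Deficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects homologous recombination deficiency (HRD) in breast
    tumours by integrating features from total copy number, allele-specific
    copy number and somatic SNV/indel data. Computes genomic scar scores
    (LOH, TAI, LST and their scarHRD sum), copy-number summary scores and
    channelized signature exposures (SBS96, ID83, allele-specific CN48),
    screens and prunes features, trains semi-supervised self-training
    random-forest classifiers on BRCA1/2-derived labels plus unknown-status
    samples, calibrates a maximum-F1 decision threshold by leave-one-out
    cross-validation, and evaluates predictions with ROC/PR areas,
    confusion-matrix metrics and Fisher association tests. Includes a
    synthetic cohort generator so the whole pipeline is testable without
    access to controlled tumour data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    Biostrings,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
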