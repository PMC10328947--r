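Package: EndoResist
Title: Molecular Profiling of Anti-Proliferative Response to Aromatase
    Inhibitors in ER+ Breast Cancer
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for profiling good versus poor
    anti-proliferative responders to neoadjuvant aromatase inhibition in
    ER+HER2- breast cancer. Classifies responders from paired Ki67
    measurements, stratifies poor responders by ESR1 expression, calls
    intrinsic subtypes via a composition-matched random-subset calibration
    of nearest-centroid classification, scores expression signatures
    (single-sample GSEA, preranked GSEA, HOXB13/IL17BR ratio), performs
    negative-binomial differential expression with Benjamini-Hochberg
    correction, and compares somatic mutations and copy-number alterations
    between response groups. Ships a synthetic-cohort generator with ground
    truth so every stage is testable without access-controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    fgsea,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
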