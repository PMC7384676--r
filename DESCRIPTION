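Package: uneecon
Title: Joint Inference of Missense Variant Effects and Gene-Level
    Constraint from Rare-Variant Depletion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the strength of negative selection acting on potential
    missense mutations and on whole genes from their depletion in population
    sequencing data. A context-dependent neutral mutation model (7-mer
    mutability, sequencing depth, local mutation rate, exome recalibration)
    predicts the occurrence probability of every candidate mutation under
    neutrality; a deep mixed-effects model combines a feedforward
    fixed-effect network over variant features with a Gaussian gene-level
    random effect, marginalized by Gauss-Hermite quadrature, to estimate the
    relative occurrence probability under selection. Per-variant scores
    (posterior expected reduction in occurrence probability) and per-gene
    constraint scores are computed from the fitted model, together with a
    linear-surrogate feature-contribution analysis, a synthetic-data
    generator mirroring the full generative process, and evaluation
    utilities (balanced ROC/AUC, percentile enrichment odds ratios,
    length-matched gene negatives, median splits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    pracma,
    jsonlite,
    yaml,
    withr,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
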