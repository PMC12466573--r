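Package: chipregulon
Title: Transcription-Factor Regulon Inference from Integrated ChIP-Seq and
    RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Regulon", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to define the direct regulon of a bacterial transcription
    factor by integrating ChIP-seq binding evidence with RNA-seq differential
    expression, as applied to global regulators such as AdpA in high-GC
    Streptomyces genomes. Implements summit-centred peak post-processing,
    EM-based motif discovery over summit fragments, position weight matrix
    scanning with exact p-values from a dynamic-programming null
    distribution, strand-aware promoter-window assignment with operon-aware
    attribution, a fold-change-threshold negative-binomial test for
    differential expression, direct-regulon construction, and per-cluster
    summaries of expression changes across secondary-metabolite biosynthetic
    gene clusters. A synthetic-data generator with recorded ground truth
    (planted motifs, peaks, and negative-binomial counts) supports end-to-end
    validation without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
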