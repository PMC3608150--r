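Package: dgetag
Title: Digital Gene Expression Profiling with CATG-Anchored Tags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for restriction-site anchored digital gene expression (DGE)
    tag profiling. Extracts 21-bp NlaIII (CATG-anchored) tags from short reads,
    applies the standard clean-tag filters, maps tags to a virtual tag database
    built from gene models with at most one mismatch, normalizes counts to tags
    per million (TPM), screens differentially expressed genes with the
    Audic-Claverie conditional count test under Benjamini-Hochberg false
    discovery rate control, classifies hybrid gene expression as additive or
    non-additive relative to the mid-parent value, and produces library-level
    summaries: tag category accounting, abundance and fold-change ratio
    distributions, sequencing saturation curves, expression overlap partitions,
    hierarchical clustering of differentially expressed genes, and
    hypergeometric term enrichment. A self-contained simulator generates toy
    genomes, gene models, and error-bearing tag reads with known expression
    truth so that every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
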