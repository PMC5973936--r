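Package: circDynamics
Title: Detection, Quantification and Dynamic Screening of Circular RNAs
    from Stranded RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for circular RNA (circRNA) discovery and
    dynamics from stranded total-RNA sequencing. Simulates stranded
    paired-end libraries containing exon-derived circular transcripts and
    an RNase R digestion step, detects back-spliced junctions by anchor
    splitting with GT-AG enforcement, quantifies circular and linear
    abundances (junction reads per 1e8 mapped reads, flanking-exon linear
    estimates, FPKM), screens for high-confidence and dynamically
    regulated circRNAs across two library types and three timepoints
    with a fold-change consensus rule, characterizes genomic features,
    and predicts miRNA sponge interactions by seed matching and a
    duplex pairing score intersected with CLIP support.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
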