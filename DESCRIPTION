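Package: mcatlas
Title: Metacell Atlases, Regulatory Region Assignment and Motif
    Enrichment for Developmental Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds high-granularity single-cell expression atlases
    (metacells) from UMI count matrices via balanced k-nearest-neighbor
    cell graphs and bootstrap co-clustering, computes normalized
    fold-change expression profiles and marker tables, assigns ATAC-seq
    peaks to genes by summit-to-TSS distance rules, curates non-redundant
    transcription-factor motif libraries and tests cell-type-specific
    regulatory regions for motif enrichment against GC- and length-matched
    genomic backgrounds, and compares cell types across species through
    orthology groups.  Ships a synthetic-data generator with planted
    ground truth (cell types, marker programs, genome, peaks, motif
    insertions, a paired species) so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    rtracklayer
Config/testthat/edition: 3
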