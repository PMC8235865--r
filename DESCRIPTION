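Package: eveTrace
Title: Reconstruction of Endogenous Viral Element Integration Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs endogenous viral element (EVE) integration events
    from viral-versus-host alignment hits. Provides readers for BLAST
    tabular hits, curated EVE tables, per-base depth tables, minimal VCF
    and small-RNA alignment records; a filter cascade and single-linkage
    region builder for candidate loci; collinear chaining of EVE fragments
    by matched viral/host gap signatures with overlap/identity clustering
    into integration events, duplicate flagging and evidence-gated
    adjacency merging; cohort-level conservation profiling (sample QC,
    depth-threshold presence matrices, core-conservation and heterogeneity
    statistics, 2-D embedding); per-EVE SNP/InDel density with coverage
    breadth masking; windowed piRNA strand-ratio tracks used as orientation
    evidence; and a seeded genome integration/fragmentation simulator with
    complete ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    jsonlite,
    cluster,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
biocViews: Genetics, SequenceMatching, Coverage, Alignment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
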