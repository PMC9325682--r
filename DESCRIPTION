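Package: dysmap
Title: Single-Cell Chromatin, Transcriptome and TCR Mapping of T Cell Dysfunction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for mapping T cell dysfunction programs from
    single-cell chromatin accessibility, transcriptome and T cell receptor (TCR)
    data. Implements per-cell ATAC fragment quality control (unique-fragment and
    TSS-enrichment filters), two-round iterative LSI clustering of binarized tile
    and peak matrices (TF-IDF, truncated SVD, shared-nearest-neighbor graph
    clustering with minimum-cluster-size-constrained resolution selection),
    pseudobulk Poisson peak calling with iterative overlap removal, gene activity
    scores with bidirectional exponential distance decay and neighbor-boundary
    filtering, GC- and accessibility-matched background motif deviation z-scores,
    supervised pseudotime along an ordered cluster backbone, scRNA-seq quality
    filtering, clustering and signed co-expression module detection, entropy-based
    clonal expansion/migration/transition indices from paired-chain clonotypes,
    cross-modality label transfer with prediction scores, and gene-signature
    survival stratification (Kaplan-Meier, log-rank). A synthetic-data generator
    with recorded ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    irlba,
    igraph,
    FNN,
    data.table,
    survival,
    Rsamtools,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
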