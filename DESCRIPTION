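Package: polyphase
Title: Subgenome Phasing, Scaffolding and Composition Analysis for Complex Polyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for characterising the subgenome structure of complex
    (allo)polyploid genomes: assignment of chromosomes to ancestral
    subgenomes by differential k-mer enrichment and iterative clustering,
    ploidy and chromosome-number estimation from single-copy marker
    multiplicities, synteny-based contig anchoring with unique-link
    filtering and AGP construction (including fused-reference surrogates),
    competitive read assignment with integer chromosome-composition
    inference, and LTR retrotransposon insertion-age dating.  A synthetic
    polyploid genome generator with full ground truth (ancestries,
    haplotypes, repeat insertions, planted markers, reads) makes every
    stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    Matrix,
    Rcpp,
    S4Vectors,
    cluster,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
SystemRequirements: minimap2 (only for align_contigs()/anchor_contigs())
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
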