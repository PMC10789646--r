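Package: xlinkquant
Title: Quantitative Pipeline for Photo-Cross-Linking Interactome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of MaxQuant-style label-free proteomics tables for
    photo-cross-linking (+/-UV) interactome experiments: contaminant and decoy
    filtering, shared-peptide protein grouping, riBAQ normalization, fold
    enrichment and t-test based classification of candidate interactors into
    exclusive/common/enriched categories. Also provides a one-site isothermal
    titration calorimetry (ITC) binding model (forward simulation and nonlinear
    least-squares fitting with derived thermodynamic parameters) and genomic
    peak colocalization summaries (pairwise overlap fractions, three-set Venn
    classification, TSS-anchored signal matrices and binned-signal
    correlations). Seeded synthetic-data generators emulate the statistical
    structure of each input so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    igraph,
    withr,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
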