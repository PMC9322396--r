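Package: hrpredict
Title: Full-Length Homology-Based Prediction of NB-LRR Resistance Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates plant NB-LRR (NLR) resistance gene models directly in
    genome assemblies with a two-pass homology procedure: a protein
    motif/domain-based search (PDS) over an automatically predicted proteome
    seeds full-length NB-LRR queries, short NB-domain motifs discovered by
    expectation-maximisation rescue weakly scoring candidates, and a
    splice-aware protein-to-genome alignment re-models every locus genome-wide.
    Includes the method's span and overlap filters, CNL/TNL/RNL architecture
    classification, pseudogene flagging, gene-model set comparison, and a
    synthetic-genome generator with known truth so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
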