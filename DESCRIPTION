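Package: gliascan
Title: Celiac-Disease Epitope Census of Gamma-Gliadin Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for surveying celiac-disease (CD) T-cell epitopes in the
    gamma-gliadin transcriptome of allohexaploid bread wheat. Clusters
    near-identical gluten transcripts into contigs, assigns contigs to their
    genome of origin (Gli-A1/Gli-B1/Gli-D1) by distance and neighbor-joining
    analysis against diploid reference sequences, scans deduced proteins for
    9-mer CD-epitope cores, annotates tissue-transglutaminase (TG2)
    deamidation targets and trypsin/chymotrypsin cleavage sites, and
    aggregates per-locus epitope censuses weighted by transcript depth. A
    seeded synthetic-data generator emulates the gamma-gliadin multigene
    family so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
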