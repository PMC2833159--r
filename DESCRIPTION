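Package: bilatmir
Title: Prediction of Evolutionarily Conserved miRNA Target Genes in
    Bilaterian Animals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-step screen for microRNA (miRNA) target-gene pairs
    conserved across distantly related bilaterian species. Conserved miRNA
    families are extracted by seed matching and global sequence identity;
    candidate target sites in 3'-UTRs are found by minimising the free
    energy of the intermolecular miRNA:mRNA duplex under a complete
    seed-match constraint; candidates are filtered on four duplex binding
    features (mismatches on either strand, G-U wobble pairs overall and in
    the seed) whose thresholds are chosen by an Enrichment-times-Coverage
    grid search against experimentally verified pairs; and surviving pairs
    are required to recur in orthologous genes of at least four species.
    Includes enrichment/coverage accounting, a species-specific-miRNA
    negative control with a Welch t-test, and a seeded synthetic corpus
    generator with planted target sites for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
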