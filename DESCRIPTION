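Package: paleomt
Title: Ancient Mitochondrial DNA Simulation, Variant Calling, and
    Heteroplasmy Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for benchmarking variant detection in ancient
    mitochondrial DNA (mtDNA). Simulates single-end aDNA sequencing reads
    with terminal cytosine-deamination damage, present-day contamination,
    two-haplotype heteroplasmy mixtures and nuclear-insertion (NumtS-like)
    decoys, with full ground truth; maps reads to a circular mitochondrial
    reference while excluding ambiguously placed reads; estimates damage
    profiles and rescales base qualities; calls variants with allele-depth,
    allele-fraction and likelihood evidence; applies a multilevel filter
    grid to build consensus sequences and heteroplasmy profiles; and scores
    call sets against a truth set with a whole-genome confusion matrix and
    nine derived statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR
LinkingTo: Rcpp
Config/testthat/edition: 3
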