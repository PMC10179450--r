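Package: mitorecomb
Title: Repeat-Mediated Recombination and Structural Feature Analysis of
    Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the multipartite structure of plant
    mitochondrial genomes from long reads. Builds flank-swapped junction
    references around large direct repeats and counts junction-spanning
    long reads to quantify repeat-mediated recombination; enumerates the
    circular isomers consistent with a repeat-bearing assembly graph; and
    provides the standard descriptive analyses of organellar genomes:
    microsatellite (SSR) detection with MISA-style thresholds, dispersed
    repeat detection (forward, reverse, palindromic and complementary
    pairs) with bounded Hamming distance, relative synonymous codon usage
    (RSCU) from GenBank annotations, and detection of mitochondrial
    plastid DNA (MTPT) by homology search. A seeded synthetic-data
    generator simulates a repeat-bearing circular mitogenome, its isomers
    and noisy long reads so that the whole pipeline is testable without
    external data.
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
    readr,
    rlang,
    withr,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    Biostrings,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
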