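Package: tntscan
Title: Locate Tnt1 Retrotransposon Insertion Sites from Paired-End
    Whole-Genome Sequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for locating LTR-retrotransposon (Tnt1)
    insertion sites in whole-genome paired-end sequencing data. Reads are
    quality-filtered, classified against the element's 90 bp terminal
    sequences into the five canonical pair types, junction-spanning hybrid
    reads are split into element and genomic portions, the genomic mates of
    element-touching pairs are assembled into unitigs with a built-in de
    Bruijn assembler, and all junction evidence is mapped to a reference
    genome with a k-mer seeded local aligner and clustered into insertion
    loci with a three-support high-confidence rule and zygosity calls from
    junction-spanning genomic pairs. Companion statistics cover Mendelian
    3:1 segregation chi-square tests, fold-coverage estimation, and
    deduplication/overlap of flanking-sequence-tag sets. A seeded simulator
    plants insertions with known positions and zygosity and generates
    paired-end reads so the whole pipeline can be validated against ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
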