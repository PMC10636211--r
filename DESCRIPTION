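Package: evescan
Title: Discovery and Population Analysis of Non-Retroviral Endogenous Viral Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for detecting non-retroviral
    endogenous viral elements (EVEs) in host genome assemblies and
    characterising them across resequenced populations. Implements a
    six-frame translated homology search with Karlin-Altschul E-values,
    merging and stringency filtering of hits into a vetted locus
    catalogue with reciprocal-search validation and flank-extended ORF
    prediction, per-individual presence/absence genotyping from read
    depth and breadth of coverage, polymorphism-level estimation
    benchmarked against fast- and slow-evolving single-copy orthologs
    classified by p-distance, FPKM transcript quantification, small-RNA
    size profiling with piRNA-signature calling, hypergeometric
    enrichment testing, and a synthetic-data generator that produces
    every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    vctrs,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    Biostrings,
    IRanges,
    Rsamtools,
    GenomicAlignments,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
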