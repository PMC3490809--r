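Package: spptools
Title: Single-Position Polymorphism Detection from Overlapping Tiling
    Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects single-position polymorphisms (SPPs) from genomic DNA
    hybridizations to overlapping 2 bp tiling oligonucleotide arrays.
    Provides chip-layout tiling with anti-genomic background probes,
    RMA-style background correction and quantile normalization,
    GC-stratified informative-probe masking, position-weighted SFPdev/SPPdev
    deviation statistics with a permutation ratio test and FDR adjustment,
    a moderated D-statistic positional caller with SAM-style delta
    calling, a diversity-panel bimodal genotyper with A/B/C/D/I/- marker
    summarization and haplotype collapse, validation against SNP truth
    sets with a duplicate-locus screen, and a synthetic hybridization
    simulator so the whole pipeline is testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    limma,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
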