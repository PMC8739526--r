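Package: editscan
Title: Strand-Aware A-to-I RNA Editing Detection and Differential Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects A-to-I RNA editing sites from per-sample variant call
    tables (VCF) using strand-consistent A-to-G / T-to-C mismatch selection
    against gene models, applies confident-site read-support and rate filters,
    annotates sites to gene regions (promoter, UTRs, exon, intron, distal) and
    RepeatMasker repeat elements (SINE/LTR/LINE and SINE subfamilies B1/B2/B4),
    classifies sites as differentially edited between paired control and
    ADAR1-depleted libraries, aggregates calls to repeat-element level
    (high/low-editing repeats), and intersects results across biological
    replicates. Includes a seeded synthetic-data generator that emulates the
    statistical structure of paired-condition editing studies so every stage
    can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
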