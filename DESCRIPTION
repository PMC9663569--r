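Package: loopstats
Title: Loop-Level Statistics Linking 3D Chromatin Loops to Gene Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for connecting factor-dependent chromatin loops
    (HiChIP/Hi-C interaction calls) to gene regulation: loop overlap and
    engulfment scoring against a reference loop set, transcriptional
    insulation scores with shuffled-loop null distributions, permutation
    and bootstrap enrichment tests for genomic intervals and accessibility
    signal, per-gene differential-loop linking scores and their correlation
    with expression change, hypergeometric gene-set enrichment, and an
    ordinary least-squares model of expression change built from binned
    occupancy, accessibility-difference and loop-count predictors. A
    synthetic-data generator produces complete input bundles (genome,
    stranded genes, nested two-factor loop sets, binding sites, wild-type
    and knockout signal tracks, count-based expression) with planted effect
    sizes so that every statistic can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
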