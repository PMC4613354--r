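Package: strandbias
Title: Replicating Strand Composition Bias Analysis for Bacterial Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies replicating strand composition bias in circular
    bacterial chromosomes and relates it to genomic features across a cohort.
    Partitions a chromosome into its two replichores from the replication
    origin and terminus, classifies genes as leading- or lagging-strand,
    computes the composition-bias score (|G-C| + |T-A| over chromosome
    length on the composite leading strand), per-gene GC/TA skew dispersion
    indices (gcRF, taRF) that proxy rearrangement frequency, COG functional
    subcategory percentages, strong/weak-biased group count ratios and their
    subcategory averages (AVDT), SCOG/WCOG selection, and KEGG
    replication-and-repair pathway proportions. Cohort-level statistics
    include Spearman correlation batteries, Welch t-tests for
    obligate-intracellular genomes, phylum summaries, and a principal
    component regression that attributes regression R-squared back to the
    original features. A synthetic-genome simulator with controllable
    per-replichore base-composition deltas, leading-strand gene density,
    COG label coupling and segment inversions provides a ground-truth test
    bed so the whole analysis runs end to end without external databases.
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
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
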