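Package: twindmr
Title: Differential DNA Methylation and Correlation-Network Analysis for
    Discordant Monozygotic Twin Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An epigenome-wide association toolkit for discordant
    monozygotic twin designs built on MeDIP-seq window counts. Provides a
    synthetic twin-cohort study generator (negative-binomial window counts
    with twin-pair baselines, planted differentially methylated regions and
    latent trait-correlated window modules), trait discordance
    classification and sample QC, 1 kb genomic window construction with
    RPKM normalisation, a per-window two-group negative-binomial exact
    test with Benjamini-Hochberg FDR, seed-and-extend calling of
    differentially methylated regions (DMRs), CpG-density and gene-proximity
    annotation, cross-comparison DMR overlap analysis, and a weighted
    correlation network stage (unsigned topological overlap, module
    detection, eigengenes, module-trait correlation) for relating
    methylation modules to physical-activity, walkability and adiposity
    traits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    generics,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
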