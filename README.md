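# twindmr

Differential DNA methylation and correlation-network analysis for
discordant monozygotic (MZ) twin cohorts, built on MeDIP-seq window
counts.

Identical twins who differ on a lifestyle exposure — weekly
moderate-to-vigorous physical activity (MVPA), neighbourhood
walkability, or body mass index — form a genetically controlled design:
epigenetic differences between co-twins cannot be explained by genotype.
`twindmr` implements the complete analysis for such a study, for
epigenomics researchers and methods developers who want a tested,
reproducible desk-scale pipeline:

* **Cohort handling** — trait-table ingestion, the three discordance
  rules (one twin ≥ 150 MVPA min/week and the co-twin < 150;
  car-dependent/somewhat-walkable vs very-walkable/walker's-paradise
  neighbourhood categories; BMI difference ≥ 5 kg/m²), and mapping-rate
  QC that removes failing samples together with their co-twins. Sexes
  are analysed strictly separately.
* **Window statistics** — a 1 kb genomic window grid, midpoint read
  counting, RPKM normalisation, and a per-window two-group
  negative-binomial exact test: counts are scaled to a common library
  size, group-summed, and the total `T = s_A + s_B` is split-enumerated;
  the two-sided p-value is `sum{ w(a) : w(a) <= w(s_A) } / sum w(a)`
  with `w(a) = f_A(a) f_B(T-a)` the NB-sum split weights
  (`Var = mu + phi mu^2`, pooled method-of-moments dispersion).
  Benjamini–Hochberg FDR across windows.
* **DMR calling** — seed-and-extend: windows with `p < 1e-4` seed a
  differentially methylated region, neighbours with `p < 0.1` within
  1 kb are absorbed to a fixed point, bridged seeds merge. Threshold
  tables, CpG density, length, gene association (±10 kb of the gene
  body), cluster flags, three-way Venn and relaxed-threshold "extended"
  overlaps between comparisons, and a DMR-feature PCA with an arm
  silhouette score.
* **Correlation networks** — a from-scratch weighted-network stage over
  the top windows by mean RPKM: unsigned adjacency `|cor|^beta`
  (beta 6 female / 9 male), topological overlap, average-linkage module
  detection with a membership (kME) cleanup, SVD module eigengenes,
  eigengene merging at dissimilarity 0.25, and module–trait Pearson
  correlations with Student-t p-values, filtered at `p < 0.001`.
* **Synthetic studies** — a fully seeded generator producing a toy
  reference genome with controlled CpG density, a twin cohort with
  configurable discordance fractions, twin-pair-correlated
  negative-binomial window counts, planted multi-window DMRs, and
  latent trait-correlated window modules — so the whole pipeline is
  testable end to end without any external data.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` displays.

## Worked example

```r
library(twindmr)

study <- simulate_study(sim_config(seed = 1))   # 5,000 windows, 8 MZ pairs/sex
rep   <- run_comparison(study, "pa", "M")       # male physical-activity contrast
rep
#> <comparison_report> M pa: 4 vs 4 samples
#>   9 DMRs at p < 0.0001 (0 multiple-window); dispersion 0.272
#>   recovery: 5/7 planted (boundaries ok 5), 0 false

head(tidy(rep$dmrs), 3)
#> # A tibble: 3 x 9
#>   chrom  start    end length n_windows n_significant_windows      min_p log2fc
#>   <chr>  <dbl>  <dbl>  <dbl>     <int>                 <int>      <dbl>  <dbl>
#> 1 chr1  340000 342000   2000         2                     1 0.00000249  -2.88
#> 2 chr1  606000 609000   3000         3                     1 0.0000823   -2.44
#> 3 chr1  985000 990000   5000         5                     1 0.0000571    2.29
```

Reading the output: with the default study, 4 of the 8 male pairs are
PA-discordant, giving a 4 vs 4 unpaired contrast. The estimated common
dispersion (0.272) is in the neighbourhood of the generating value
(0.2). Nine regions pass the `p < 1e-4` seed; 5 of the 7 planted
PA-responsive DMRs are recovered with both boundaries within one window,
and none of the calls falls outside planted signal (`0 false`). Each DMR
row gives its span, member windows, seed windows, minimum p, the log2
fold change of its most significant window (high arm over low arm;
negative means lower coverage in the high-MVPA twin), and CpG density.

Continue with `run_network(study, "M")` for the module–trait stage,
`pca_dmr_features()` for the arm-separation PCA, `venn_counts()` /
`extended_overlap()` for cross-comparison overlap, or run everything at
once with `run_study(study)`. `write_study()` / `read_study()` persist a
study as FASTA + BED + TSV/JSON. A thin command-line wrapper lives in
`inst/scripts/twindmr.R`.

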