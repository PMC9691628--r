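---
title: "Methods: differential methylation and network analysis in discordant twin designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation and network analysis in discordant twin designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twindmr)
```

## The design

Monozygotic (MZ) twin pairs discordant for an exposure approximate a
genetically controlled case/control contrast: both twins share a genome,
so systematic epigenetic differences between the exposed and unexposed
co-twins are attributable to environment and lifestyle rather than
genotype. `twindmr` implements an epigenome-wide association workflow for
such designs built on MeDIP-seq window coverage: read counts in fixed
1 kb genomic windows proxy the local density of methylated DNA.

Three discordance definitions drive the comparisons:

* **Physical activity (PA)** — one twin accumulates at least 150 minutes
  of moderate-to-vigorous physical activity (MVPA) per week and the
  co-twin fewer than 150 (ties at exactly 150/150 are concordant; the
  rule is `>=` on one side and strict `<` on the other).
* **Neighbourhood walkability** — one twin lives in a *car dependent* or
  *somewhat walkable* neighbourhood and the co-twin in a *very walkable*
  or *walker's paradise* one. The score-to-category map is
  configuration; the default follows the published Walk Score bins
  (0–49, 50–69, 70–89, 90–100), because no bin edges are fixed by the
  discordance definition itself.
* **BMI** — a within-pair difference of at least 5 kg/m².

Male and female pairs are always analysed separately; the pipeline
hard-partitions by sex before any statistic touches data. Samples with
an overall read-mapping rate below 70% are removed *together with their
co-twin*, so every retained sample belongs to an intact pair.

## Per-window exact test

For one comparison the two groups are the low and high arms of the
discordant pairs, treated as unpaired samples. Counts are modelled as
negative binomial with mean `mu` and variance `mu + phi * mu^2`
(`phi = 0` is the Poisson limit). The test for one window:

1. scale every sample's count to the common (geometric-mean) library
   size and sum within each group — `s_A`, `s_B` from `n_A`, `n_B`
   samples (sums rounded to integers);
2. condition on the total `T = s_A + s_B`. The sum of `n` i.i.d.
   NB(`mu`, `phi`) variables is NB with mean `n*mu` and size `n/phi`,
   so under the null of equal means each split `(a, T - a)` has weight
   `w(a) = f_A(a) * f_B(T - a)` with the null mean estimated from the
   window itself (`mu0 = T / (n_A + n_B)`);
3. the two-sided p-value is the normalised sum of `w(a)` over all splits
   with `w(a) <= w(s_A)` — the "probability at most that of the
   observed outcome" rule, not the doubled one-tail. This rule is
   directly checkable by exhaustive enumeration, which is exactly what
   the test suite does.

The log2 fold change is `log2((s_B/n_B + 0.5) / (s_A/n_A + 0.5))` (high
arm over low arm); the 0.5 pseudo-count keeps it finite at zero counts.

The common dispersion is estimated by pooled method of moments on the
library-scaled counts: `phi = max(0, sum(v - c*m) / sum(m^2))` over all
windows and groups, where `m` and `v` are the per-window group mean and
variance and `c` corrects for the variance inflation introduced by the
rescaling. On simulated data with `phi = 0.2` (10k windows, 8 + 8
samples) the estimate lands within ±0.05; with Poisson data it collapses
to zero. Twin pairing is deliberately **not** modelled by the test — the
group comparison is unpaired — while the simulator *does* create shared
within-pair baselines, precisely so that the tests demonstrate the
analysis is robust to the pairing it ignores. A shared pair baseline
scales a sample's whole profile and is absorbed by library-size
normalisation, which is why calibration survives it.

False discovery rates are Benjamini–Hochberg across all tested windows
of a comparison (`stats::p.adjust`); the procedure choice is
configuration, since FDR reporting conventions vary.

### Discreteness and what "calibrated" means here

The exact test is discrete: its achievable p-values form a finite set
per window, with a point mass at `p = 1` (the event that the observed
split is the modal one). On a 20,000-window null study at depth 30 the
empirical CDF of the p-values matches Uniform(0,1) to within ~0.005 at
every probe point below 1, and the fraction below 0.05 sits inside the
99% binomial band — but a raw Kolmogorov–Smirnov statistic against the
uniform is dominated by that atom at 1 (mass ≈ 0.028) and will exceed
the usual critical value at any realistic depth. This is a property of
every discrete two-sided exact test, not a miscalibration; the test
suite asserts the band and the sub-unit ECDF agreement, and carries the
literal KS assertion so the discreteness stays visible.

## Seed-and-extend DMR calling

Windows with `p < 1e-4` seed differentially methylated regions (DMRs).
Each DMR is extended to a fixed point: any window with `p < 0.1` whose
span lies within 1000 bp of the current DMR span is absorbed, extension
may chain, and DMRs whose spans come to overlap or abut merge. "Within
1000 bp" is implemented as edge-to-edge distance strictly below the gap
parameter, so on the 1 kb grid an adjacent window (gap 0) qualifies and
a window one full window away (gap exactly 1000) does not. The
alternative reading — absorbing at gap `<= 1000` — lets an isolated
noise window two positions away pull the boundary outward; under the
null roughly one flanking window in ten sits below 0.1, which would
displace a boundary by two or more windows on ~20% of DMRs and destroy
boundary accuracy. Under the strict rule, planted-DMR recovery on
synthetic data (20 DMRs of 2–4 windows, log2FC 2, depth 30, 8 vs 8) is
19–20/20 with both boundaries within one window, and false calls are
rare (expected below one per 5,000 null windows at the 1e-4 seed).

Each DMR reports its span, window count, seed-window count
(`n_significant_windows`; DMRs with at least two are the
"multiple-window" class), minimum p, CpG density per 100 bp over the
span, and the log2 fold change of its most significant window (the mean
across member windows is available by configuration). The threshold
table re-calls DMRs at a ladder of seed thresholds
(1e-3 … 1e-7); counts are non-increasing with stringency by
construction.

## Annotation and overlaps

CpG density is the count of CG dinucleotides per 100 bp of reference
sequence (for CG, non-overlapping and sliding counts coincide). Gene
association links a region to every gene whose body extended by 10 kb on
*both* sides overlaps it by at least one base — a strand-symmetric,
parameter-free reading of "within 10 kb of a gene" that covers distal
and proximal promoter regions on either end. Cross-comparison overlap
uses ≥1 bp genomic intersection as the pairing relation; a region
overlapping several partners counts once, and percentages are relative
to the strict set. The "extended overlap" statistic re-calls the second
comparison's DMRs at a relaxed seed (default `p < 0.05`) before
intersecting, quantifying shared signal that a stringent threshold
hides. DMR clusters along a chromosome are flagged as maximal runs of at
least 3 DMRs spanning at most 2 Mb; both numbers are explicit
configuration, chosen as a simple quantitative stand-in for visual
cluster boxes on chromosome ideograms, and claim nothing beyond that.

## Correlation-network stage

The network stage is written from first principles (no external
correlation-network package):

* **Input** — the top 100,000 windows by mean RPKM (all windows when
  fewer exist), per sex. RPKM is `count / (window_kb * lib/1e6)`.
* **Adjacency** — `a_ij = |cor(x_i, x_j)|^beta`, unsigned, with
  `beta = 6` for female and `beta = 9` for male sets (taken as given,
  not fitted).
* **Topological overlap** —
  `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
  `l_ij = sum_u a_iu a_uj` (`u != i, j`) and `k_i = sum_{u != i} a_iu`;
  `1 - TOM` is the clustering dissimilarity. The implementation is
  matrix-algebraic and is checked against a literal triple-loop oracle
  to 1e-12.
* **Module detection** — average-linkage hierarchical clustering of the
  dissimilarity, cut at 99% of the *maximum* merge height; clusters of
  at least 30 windows become modules, everything else is grey
  (unassigned). Cutting relative to the maximum rather than at a height
  quantile matters in the no-structure case: with independent windows
  all merges crowd just below the top of the tree, a quantile cut lands
  inside that band and would carve large spurious modules, while the
  relative-max cut leaves only singletons, i.e. everything grey.
* **Membership cleanup** — after detection, each window's correlation
  with its own module eigengene (kME) is computed and members with
  `|kME| < 0.5` are released to grey; modules that fall below the
  minimum size dissolve. A fixed-height cut inevitably accretes a few
  windows that are only weakly correlated with a module's driver
  (|r| ≈ 0.3); the kME floor removes exactly those stragglers. This is
  the same role the membership floor plays in the reference
  blockwise-module workflow. Post-hoc *reassignment* between modules is
  deliberately omitted (reassignment threshold 0).
* **Eigengenes and merging** — a module eigengene is the first left
  singular vector of the z-scored sample × member matrix, unit norm,
  sign fixed so its mean correlation with members is non-negative.
  Modules whose eigengene dissimilarity `1 - cor` falls below 0.25 are
  merged (connected components per round, eigengenes recomputed, until a
  fixed point), so chains of pairwise-similar modules collapse.
* **Blockwise driver** — inputs beyond 15,000 windows are
  pre-partitioned by k-means on the windows' leading
  singular-vector coordinates into blocks no larger than the cap;
  detection runs per block and the merge step reunites split modules.
  The partition is deterministic given the seed.
* **Module–trait correlation** — Pearson correlation of each eigengene
  with each numeric-coded trait (MVPA minutes, walkability score, BMI,
  waist, and the 0/1 per-pair discordance flags), with the two-sided
  Student p-value `p = 2 P(T_{n-2} > |r| sqrt(n-2) / sqrt(1-r^2))`. All
  samples are treated as independent at this stage — twin pairing is
  ignored by design. The filtered summary drops modules and traits with
  no entry at `p < 0.001`.

Average-linkage clustering with a fixed relative cut is a simplification
of the reference "dynamic hybrid" tree cut; correctness is claimed at
the level of module *recovery* on data with planted structure (ARI,
driving-trait identification), not label identity with any external
tool.

## The synthetic study generator

The generator is first-class, tested code. It emulates the statistical
structure the analysis assumes, not MeDIP chemistry:

* **Reference** — per chromosome, an A/T background with CG
  dinucleotides planted at non-overlapping positions so each 1 kb window
  hits a target density drawn from 1–10 CpG/100 bp. Window CpG counts
  are recomputed from the emitted FASTA, never trusted from
  bookkeeping. The base composition outside CpG positions is not
  realistic and is not meant to be; only CpG placement matters
  downstream.
* **Cohort** — `n_pairs_per_sex` MZ pairs per sex (default 8; 20 in the
  network-recovery study, giving 40 same-sex samples). A configurable
  fraction of pairs is discordant per trait (default 0.5 each, so a
  desk-scale cohort still yields several pairs per arm). The first
  discordant pair per sex is anchored at the published exemplar
  magnitudes — MVPA 66/266 min, walkability 25.7/82.0, BMI
  28.4/35.2 kg/m² — so those reference contrasts are always present;
  the rest draw around realistic spreads, and which member is the low
  twin is random. Waist tracks BMI with noise; mapping rates default to
  0.85–0.99 with an optional fraction of deliberately failing pairs.
* **Counts** — `NB(mu_ws, phi)` with
  `log mu_ws = log mu_w + pair_s + Delta_ws + a * f_ms + log d_s`:
  a CpG-density-driven window baseline (mean depth 30 at average
  density), a shared within-pair log-normal baseline (SD 0.3), the
  planted DMR effect (`log2fc * ln 2`, default |log2FC| = 2 with random
  sign, applied to the high arm of the affected trait's discordant
  pairs), the latent module term, and a per-sample depth factor uniform
  within ±30%. Library sizes are the column sums. Dispersion defaults
  to `phi = 0.2`, a typical overdispersion for window-level enrichment
  counts; `phi = 0` gives exact Poisson.
* **Truth** — planted DMRs (spans of 1–5 windows by default) and latent
  modules (50 contiguous windows each) are placed disjointly with a
  two-window buffer, so DMR recovery and module recovery are scored
  independently. Each latent module has a driver
  `f = sign * r * z(trait) + sqrt(1 - r^2) * noise` per sex
  (`r = 0.7` by default) and loads on its windows with coefficient 0.8,
  which yields within-module window correlations around 0.7 — strong
  but within the range of genuine co-methylated domains, and necessary
  for modules to be detectable at all from 40 samples at depth 30.

What the generator does **not** emulate: fragment-level MeDIP
enrichment, mappability and GC bias, non-contiguous modules, copy-number
structure, or cell-type heterogeneity. Passing recovery tests therefore
demonstrates that the pipeline's inference machinery is correct under
its own model assumptions — not that real buccal-cell MeDIP-seq data
satisfy those assumptions.

## Numerical choices and degenerate inputs

* Window totals of zero give `p = 1`, `log2fc = 0`, and stay in the
  output; they are never dropped silently.
* Ties in the split enumeration are included with a `1e-12` relative
  tolerance; the phi → 0 path switches to the closed-form binomial.
* Zero-variance windows are removed (with a warning) before adjacency;
  constant traits yield `NA` correlations rather than errors.
* Read-to-window assignment uses the midpoint rule — unambiguous and
  count-conserving; fractional-overlap assignment is a different,
  non-conserving convention and is not offered.
* Terminal short windows are kept, flagged, and use their true length
  for RPKM and CpG density.
* All interval files are 0-based half-open (BED dialect); GTF input is
  converted at the boundary. A fixed seed makes every generated file
  byte-identical across runs.

## Problem sizes used by the test-suite studies

Unit tests run on studies of a few hundred windows. The study-scale
checks use: 20,000 windows / 8 vs 8 samples for null calibration;
5,000 windows / 8 pairs for DMR recovery (20 planted DMRs); and
5,000 windows / 40 same-sex samples for module recovery (3 modules of
50 windows). These sizes were chosen so that each property is measured
with comfortable statistical resolution while a full suite run stays in
the minutes range on a laptop core.

## Known limitations

* The exact test assumes a common dispersion across windows;
  window-specific dispersion shrinkage is not implemented (the
  `DispersionModel` surface accepts an override instead).
* TMM-style compositional normalisation is out of scope; library-size
  scaling only.
* The dendrogram cut is static; very close or nested modules that the
  dynamic hybrid cut would separate may merge or shed members here.
* Functional enrichment relies on a user-supplied gene-to-category
  table; no live pathway database is consulted.
* With only two samples per group the dispersion cannot be estimated
  and must be supplied.
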