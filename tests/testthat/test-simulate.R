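# Synthetic study generator: reference, cohort, truth, counts.

test_that("config validation enforces the generator invariants", {
  expect_error(sim_config(chrom_length_bp = 1500, window_size_bp = 1000),
               "multiple")
  expect_error(sim_config(dispersion = -0.1), "dispersion")
  expect_error(sim_config(module_trait_r = 1.2), "module_trait_r")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("reference CpG counts are exactly recomputable from the FASTA", {
  cfg <- sim_config(n_pairs_per_sex = 2, n_chromosomes = 2,
                    chrom_length_bp = 3e4, seed = 5)
  ref <- simulate_reference(cfg)
  # independent sliding rescan of the emitted sequence
  for (i in sample(nrow(ref$windows), 8)) {
    w <- ref$windows[i, ]
    chars <- strsplit(as.character(ref$reference[[w$chrom]]), "")[[1]]
    n <- sum(chars[(w$start + 1):(w$end - 1)] == "C" &
               chars[(w$start + 2):w$end] == "G")
    expect_equal(w$cpg, n)
  }
  # densities span the 1-10 CpG/100bp range
  expect_gte(min(ref$windows$cpg_bin), 1)
  expect_lte(max(ref$windows$cpg_bin), 10)
  expect_gt(length(unique(ref$windows$cpg_bin)), 5)
})

test_that("cohort honours discordance fractions and exemplar magnitudes", {
  cfg <- sim_config(n_pairs_per_sex = 10, seed = 3)
  cohort <- simulate_cohort(cfg)
  expect_equal(nrow(cohort), 40L)
  flags <- classify_discordance(cohort)
  # half the pairs discordant per trait (default fractions 0.5)
  expect_equal(sum(flags$pa_discordant), 10L)
  expect_equal(sum(flags$walkability_discordant), 10L)
  expect_equal(sum(flags$bmi_discordant), 10L)
  # printed exemplar pairs are present in each sex
  for (sx in c("F", "M")) {
    m <- cohort$mvpa_min_week[cohort$sex == sx]
    expect_true(all(c(66, 266) %in% m))
    w <- cohort$walkability_score[cohort$sex == sx]
    expect_true(all(c(25.7, 82.0) %in% w))
    b <- cohort$bmi[cohort$sex == sx]
    expect_true(all(c(28.4, 35.2) %in% b))
  }
  # fraction 1 -> every pair discordant
  all_disc <- simulate_cohort(sim_config(
    n_pairs_per_sex = 6,
    fraction_discordant = c(pa = 1, walkability = 1, bmi = 1)))
  fl <- classify_discordance(all_disc)
  expect_true(all(fl$pa_discordant))
  expect_true(all(fl$walkability_discordant))
  expect_true(all(fl$bmi_discordant))
})

test_that("fixing the seed fixes every generated byte", {
  cfg <- tiny_config(seed = 17)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$counts, s2$counts)
  expect_identical(as.character(s1$reference), as.character(s2$reference))
  expect_identical(s1$truth, s2$truth)
  # a different seed changes the data
  s3 <- simulate_study(tiny_config(seed = 18))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("planted features are disjoint and aligned to window boundaries", {
  cfg <- tiny_config(seed = 29, n_planted_dmrs = 6, n_latent_modules = 2)
  study <- simulate_study(cfg)
  tr <- study$truth
  dmr_windows <- unlist(Map(seq, tr$planted_dmrs$window_start,
                            tr$planted_dmrs$window_end))
  expect_false(any(duplicated(c(dmr_windows, tr$module_membership$window))))
  expect_true(all(tr$planted_dmrs$start %% cfg$window_size_bp == 0))
  expect_true(all(tr$planted_dmrs$end %% cfg$window_size_bp == 0))
  # module ids partition their windows disjointly
  expect_false(any(duplicated(tr$module_membership$window)))
})

test_that("the Poisson limit shows variance approximately equal to the mean", {
  cfg <- sim_config(n_pairs_per_sex = 30, n_chromosomes = 1,
                    chrom_length_bp = 5e4, dispersion = 0, pair_effect_sd = 0,
                    lib_size_range = 0, n_planted_dmrs = 0,
                    n_latent_modules = 0, seed = 37)
  study <- simulate_study(cfg)
  m <- rowMeans(study$counts)
  v <- apply(study$counts, 1, var)
  # variance/mean ratio concentrates around 1 across windows
  expect_equal(mean(v / m), 1, tolerance = 0.05)
  # and clearly below what dispersion 0.2 would give (1 + 0.2 * mu)
  expect_lt(mean(v / m), 1 + 0.1 * mean(m))
})

test_that("planted log2fc = 2 gives a four-fold arm ratio at depth", {
  cfg <- sim_config(n_pairs_per_sex = 20, n_chromosomes = 1,
                    chrom_length_bp = 1e5, mean_depth = 60, dispersion = 0.05,
                    pair_effect_sd = 0, lib_size_range = 0,
                    n_planted_dmrs = 5, dmr_span_windows = c(2, 3),
                    dmr_log2fc = 2, dmr_traits = "pa", n_latent_modules = 0,
                    fraction_discordant = c(pa = 1, walkability = 0, bmi = 0),
                    seed = 41)
  study <- simulate_study(cfg)
  grp <- comparison_groups(study$cohort, "pa", "M")
  low <- rowMeans(study$counts[, grp$id[grp$arm == "low"]])
  high <- rowMeans(study$counts[, grp$id[grp$arm == "high"]])
  for (d in seq_len(nrow(study$truth$planted_dmrs))) {
    rec <- study$truth$planted_dmrs[d, ]
    sel <- rec$window_start:rec$window_end
    ratio <- mean(high[sel]) / mean(low[sel])
    expected <- 2^rec$log2fc
    expect_equal(ratio, expected, tolerance = 0.35)
  }
})

test_that("twin-pair baselines induce within-pair coverage correlation", {
  # the shared pair baseline scales a sample's whole profile, so it shows
  # up in total coverage: co-twin log library sizes correlate across
  # pairs, re-paired samples do not
  cfg <- sim_config(n_pairs_per_sex = 12, n_chromosomes = 1,
                    chrom_length_bp = 3e5, pair_effect_sd = 0.5,
                    lib_size_range = 0, n_planted_dmrs = 0,
                    n_latent_modules = 0, seed = 43)
  study <- simulate_study(cfg)
  tot <- log(study$lib_sizes)
  a <- tot[paste0(unique(study$cohort$pair_id), "a")]
  b <- tot[paste0(unique(study$cohort$pair_id), "b")]
  within <- cor(a, b)
  set.seed(1)
  between <- mean(replicate(100, cor(a, sample(b))))
  expect_gt(within, 0.5)
  expect_gt(within, between + 0.3)
  # with no pair effect the within-pair correlation vanishes
  cfg0 <- sim_config(n_pairs_per_sex = 12, n_chromosomes = 1,
                     chrom_length_bp = 3e5, pair_effect_sd = 0,
                     lib_size_range = 0.3, n_planted_dmrs = 0,
                     n_latent_modules = 0, seed = 43)
  s0 <- simulate_study(cfg0)
  t0 <- log(s0$lib_sizes)
  a0 <- t0[paste0(unique(s0$cohort$pair_id), "a")]
  b0 <- t0[paste0(unique(s0$cohort$pair_id), "b")]
  expect_lt(abs(cor(a0, b0)), 0.5)
})
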