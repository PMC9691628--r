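# Seed-and-extend DMR calling on constructed p-value fixtures and random
# property checks.

grid5 <- make_windows(c(chr1 = 5000))

fixture_results <- function(p, log2fc = rep(1, length(p))) {
  structure(tibble::tibble(window = seq_along(p), p_value = p,
                           q_value = bh_fdr(p), log2fc = log2fc,
                           mean_a = 10, mean_b = 20),
            class = c("window_test", "tbl_df", "tbl", "data.frame"))
}

test_that("extension absorbs adjacent sub-0.1 windows around a seed", {
  res <- fixture_results(c(0.5, 0.08, 2e-5, 0.09, 0.2))
  dmrs <- call_dmrs(res, grid5)
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$start, 1000)
  expect_equal(dmrs$end, 4000)
  expect_equal(dmrs$n_windows, 3L)
  expect_equal(dmrs$n_significant_windows, 1L)
  expect_equal(dmrs$min_p, 2e-5)
})

test_that("an isolated seed yields a single-window DMR", {
  res <- fixture_results(c(0.5, 0.3, 2e-5, 0.9, 0.2))
  dmrs <- call_dmrs(res, grid5)
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$length, 1000)
  expect_equal(dmrs$n_windows, 1L)
  expect_equal(dmrs$n_significant_windows, 1L)
})

test_that("two seeds bridged by an extension window merge into one DMR", {
  res <- fixture_results(c(2e-5, 0.05, 2e-5, 0.9, 0.9))
  dmrs <- call_dmrs(res, grid5)
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$n_windows, 3L)
  expect_equal(dmrs$n_significant_windows, 2L)
  expect_equal(dmrs$start, 0)
  expect_equal(dmrs$end, 3000)
})

test_that("DMR log2fc is reported from the most significant window", {
  res <- fixture_results(c(0.5, 0.08, 2e-5, 0.09, 0.2),
                         log2fc = c(0, 1, 2.5, 1, 0))
  expect_equal(call_dmrs(res, grid5)$log2fc, 2.5)
  expect_equal(call_dmrs(res, grid5, fc_summary = "mean")$log2fc,
               mean(c(1, 2.5, 1)))
})

test_that("extension never crosses chromosomes and the fixed point is clean", {
  grid <- make_windows(c(chr1 = 3000, chr2 = 3000))
  res <- fixture_results(c(0.5, 0.05, 2e-5, 0.05, 0.5, 0.5))
  dmrs <- call_dmrs(res, grid)
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$chrom, "chr1")
  # window 4 is the first window of chr2 (p = 0.05): never absorbed
  expect_equal(dmrs$end, 3000)
  # partition property on random fixtures: every seed is inside exactly
  # one DMR and no outside sub-0.1 window touches a DMR span
  set.seed(77)
  grid20 <- make_windows(c(chr1 = 20000))
  for (i in 1:20) {
    p <- runif(20)
    p[sample(20, 3)] <- 10^runif(3, -8, -5)
    res <- fixture_results(p)
    dmrs <- call_dmrs(res, grid20)
    seeds <- which(p < 1e-4)
    covered <- vapply(seeds, function(s) {
      sum(dmrs$start <= grid20$start[s] & dmrs$end >= grid20$end[s])
    }, numeric(1))
    expect_true(all(covered == 1))
    for (d in seq_len(nrow(dmrs))) {
      outside <- which(p < 0.1 &
                         (grid20$end <= dmrs$start[d] |
                            grid20$start >= dmrs$end[d]))
      gaps <- pmax(dmrs$start[d] - grid20$end[outside],
                   grid20$start[outside] - dmrs$end[d])
      expect_true(all(gaps >= 1000))
    }
  }
})

test_that("calling is invariant to window processing order", {
  set.seed(12)
  grid20 <- make_windows(c(chr1 = 10000, chr2 = 10000))
  p <- runif(20)
  p[c(3, 4, 15)] <- c(2e-5, 0.03, 1e-6)
  res <- fixture_results(p)
  shuffled <- res[sample(20), ]
  expect_equal(tidy(call_dmrs(res, grid20)),
               tidy(call_dmrs(shuffled, grid20)))
})

test_that("multi-window classification splits DMRs by seed count", {
  res <- fixture_results(c(2e-5, 0.05, 2e-5, 0.9, 2e-5))
  dmrs <- call_dmrs(res, grid5)
  cm <- classify_multi_window(dmrs)
  expect_equal(cm$all_window, 2L)
  expect_equal(cm$multiple_window, 1L)
  empty <- call_dmrs(fixture_results(rep(0.5, 5)), grid5)
  expect_equal(nrow(empty), 0L)
  expect_equal(classify_multi_window(empty),
               tibble::tibble(all_window = 0L, multiple_window = 0L))
})

test_that("threshold table is monotone and hits the p_seed = 1 limit", {
  set.seed(19)
  grid50 <- make_windows(c(chr1 = 50000))
  p <- runif(50)
  p[sample(50, 6)] <- 10^runif(6, -9, -3.5)
  res <- fixture_results(p)
  tt <- dmr_threshold_table(res, grid50)
  expect_equal(tt$p_seed, sort(c(1e-3, 1e-4, 1e-5, 1e-6, 1e-7),
                               decreasing = TRUE))
  expect_true(all(diff(tt$all_window) <= 0))
  expect_true(all(diff(tt$multiple_window) <= 0))
  # p_seed = 1: every window seeds, DMR count = number of maximal runs,
  # which on a single gap-free chromosome is 1
  all_in <- dmr_threshold_table(res, grid50, thresholds = 1, p_extend = 1)
  expect_equal(all_in$all_window, 1L)
  expect_equal(all_in$multiple_window, 1L)
})
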