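test_that("CpG density counts CG dinucleotides per 100 bp", {
  ref <- Biostrings::DNAStringSet(c(
    chrA = paste(rep("AC", 200), collapse = ""),        # no CG anywhere
    chrB = paste(rep("CG", 200), collapse = "")         # CG everywhere
  ))
  regions <- tibble::tibble(chrom = c("chrA", "chrB"), start = 0, end = 400)
  res <- cpg_density(regions, ref)
  expect_equal(res$cpg_count, c(0L, 200L))
  expect_equal(res$cpg_per_100bp, c(0, 50))
  # 100 bp of "CG" repeated 50x -> 50 per 100 bp, overlap-free count
  res2 <- cpg_density(tibble::tibble(chrom = "chrB", start = 0, end = 100), ref)
  expect_equal(res2$cpg_count, 50L)
  expect_error(cpg_density(tibble::tibble(chrom = "chrA", start = 0, end = 401),
                           ref), "bounds")
})

test_that("CpG density equals a brute-force sliding rescan on random sequence", {
  set.seed(4)
  seq_chars <- sample(c("A", "C", "G", "T"), 2000, replace = TRUE)
  ref <- Biostrings::DNAStringSet(c(chrR = paste(seq_chars, collapse = "")))
  for (i in 1:10) {
    s <- sample(0:1500, 1)
    e <- s + sample(100:400, 1)
    got <- cpg_density(tibble::tibble(chrom = "chrR", start = s, end = e), ref)
    # independent sliding scan over the character vector
    n <- sum(seq_chars[(s + 1):(e - 1)] == "C" &
               seq_chars[(s + 2):e] == "G")
    expect_equal(got$cpg_count, n)
  }
})

test_that("gene association uses a symmetric 10 kb body flank", {
  genes <- tibble::tibble(gene_id = "GENE1", symbol = "G1", chrom = "chr1",
                          start = 50000, end = 60000, strand = "+")
  # region 5 kb upstream: associated
  up5 <- associate_genes(tibble::tibble(chrom = "chr1", start = 44000,
                                        end = 45000), genes)
  expect_equal(up5$gene_id, "GENE1")
  # region ending 10,001 bp before the gene: not associated
  far <- associate_genes(tibble::tibble(chrom = "chr1", start = 38999,
                                        end = 39999), genes)
  expect_true(is.na(far$gene_id))
  # boundary: exactly 10 kb away still touches the flank
  edge <- associate_genes(tibble::tibble(chrom = "chr1", start = 39001,
                                         end = 40001), genes)
  expect_equal(edge$gene_id, "GENE1")
})

test_that("gene association matches the all-pairs oracle and ignores strand/order", {
  set.seed(15)
  genes <- tibble::tibble(
    gene_id = sprintf("G%02d", 1:15), symbol = sprintf("S%02d", 1:15),
    chrom = sample(c("chr1", "chr2"), 15, replace = TRUE),
    start = sample(seq(0, 180000, 1000), 15),
    strand = sample(c("+", "-"), 15, replace = TRUE)
  )
  genes$end <- genes$start + sample(2000:8000, 15)
  regions <- random_dmr_set(8, max_bp = 2e5)
  flank <- 10000
  got <- associate_genes(regions, genes, flank) |>
    dplyr::filter(!is.na(gene_id))
  oracle <- NULL
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(genes))) {
      if (regions$chrom[i] == genes$chrom[j] &&
          regions$start[i] < genes$end[j] + flank &&
          regions$end[i] > genes$start[j] - flank) {
        oracle <- rbind(oracle, data.frame(region = i,
                                           gene_id = genes$gene_id[j]))
      }
    }
  }
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(paste(got$region, got$gene_id),
               paste(oracle$region, oracle$gene_id))
  # gene-set order invariance
  perm <- sample(15)
  got2 <- associate_genes(regions, genes[perm, ], flank) |>
    dplyr::filter(!is.na(gene_id)) |>
    dplyr::arrange(region, gene_id)
  expect_equal(got2$gene_id, dplyr::arrange(got, region, gene_id)$gene_id)
})

test_that("DMR clusters are maximal runs fitting in the span window", {
  dmrs <- tibble::tibble(
    chrom = "chr1",
    start = c(1e6, 1.4e6, 1.8e6, 9e6),
    end = c(1e6, 1.4e6, 1.8e6, 9e6) + 2000
  )
  out <- flag_dmr_clusters(dmrs, window_mb = 1, min_count = 3)
  expect_equal(out$cluster, c(1L, 1L, 1L, NA))
  # all far apart -> no clusters
  spread <- tibble::tibble(chrom = "chr1", start = c(1, 30, 60) * 1e6,
                           end = c(1, 30, 60) * 1e6 + 1000)
  expect_true(all(is.na(flag_dmr_clusters(spread)$cluster)))
  # random sets match an exhaustive run scan
  set.seed(23)
  for (i in 1:10) {
    d <- random_dmr_set(12, chroms = "chr1", max_bp = 2e7) |>
      dplyr::arrange(start)
    got <- flag_dmr_clusters(d, window_mb = 2, min_count = 3)
    in_run <- rep(FALSE, nrow(d))
    for (a in seq_len(nrow(d))) {
      for (b in a:nrow(d)) {
        if (d$end[b] - d$start[a] <= 2e6 && b - a + 1 >= 3) in_run[a:b] <- TRUE
      }
    }
    expect_equal(!is.na(got$cluster), in_run)
  }
})

test_that("category assignment tallies against the user table", {
  links <- tibble::tibble(gene_id = c("A", "B", "B", "C", "D", NA))
  tab <- tibble::tibble(gene_id = c("A", "B", "C"),
                        category = c("signaling", "transport", "signaling"))
  got <- assign_categories(links, tab)
  expect_equal(got$n[got$category == "signaling"], 2L)
  expect_equal(got$n[got$category == "transport"], 2L)
  expect_equal(got$n[got$category == "unknown"], 1L)
  # conservation: counts sum to the number of annotated gene links
  expect_equal(sum(got$n), 5L)
  # empty table -> all unknown
  empty <- assign_categories(links, tibble::tibble(gene_id = character(),
                                                   category = character()))
  expect_equal(empty$category, "unknown")
  expect_equal(empty$n, 5L)
  # conflicting duplicate rows rejected
  bad <- tibble::tibble(gene_id = c("A", "A"), category = c("x", "y"))
  expect_error(assign_categories(links, bad), "conflicting")
})
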