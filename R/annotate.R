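#' CpG density of genomic regions
#'
#' Counts CG dinucleotides in each region of a reference and reports the
#' density per 100 bp, together with an integer-binned value
#' (`round(density)`) convenient for histogramming. Dinucleotides are
#' counted without overlap, which for the CG motif coincides with the
#' sliding count.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param reference A [Biostrings::DNAStringSet] keyed by chromosome name.
#' @return `regions` with added columns `cpg_count`, `cpg_per_100bp`,
#'   `cpg_bin`.
#' @export
cpg_density <- function(regions, reference) {
  if (!all(regions$chrom %in% names(reference))) {
    abort("region chromosome(s) missing from the reference")
  }
  lens <- setNames(Biostrings::width(reference), names(reference))
  if (any(regions$start < 0 | regions$end > lens[regions$chrom])) {
    abort("region(s) outside the reference sequence bounds")
  }
  n <- vapply(seq_len(nrow(regions)), function(i) {
    seq_i <- Biostrings::subseq(reference[[regions$chrom[i]]],
                                start = regions$start[i] + 1L,
                                end = regions$end[i])
    Biostrings::countPattern("CG", seq_i)
  }, numeric(1))
  regions |>
    mutate(cpg_count = as.integer(n),
           cpg_per_100bp = 100 * n / (.data$end - .data$start),
           cpg_bin = as.integer(round(.data$cpg_per_100bp)))
}

#' Associate regions with nearby genes
#'
#' A region is linked to every gene whose body, expanded by `flank` bp on
#' both sides, overlaps it by at least one base. The two-sided flank
#' (default 10 kb) captures distal and proximal promoter regions
#' regardless of strand. Regions without any gene within reach are
#' retained with an `NA` gene link.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param genes Gene models: `gene_id`, `symbol`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @param flank Flank size in bp added to both gene ends.
#' @return A tibble with one row per (region, gene) link: the region
#'   columns plus `region` (row index in `regions`), `gene_id`, `symbol`.
#' @export
associate_genes <- function(regions, genes, flank = 10000) {
  reg <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  gen <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$start + 1L - flank, 1L), genes$end + flank))
  hits <- GenomicRanges::findOverlaps(reg, gen, minoverlap = 1L)
  links <- tibble(
    region = S4Vectors::queryHits(hits),
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    symbol = genes$symbol[S4Vectors::subjectHits(hits)]
  )
  regions |>
    mutate(region = row_number()) |>
    left_join(links, by = "region") |>
    relocate("region")
}

#' Flag clusters of DMRs along a chromosome
#'
#' Marks maximal runs of at least `min_count` consecutive DMRs whose
#' combined span fits within `window_mb` megabases, a simple quantitative
#' stand-in for visually boxed DMR clusters on chromosome plots. The
#' criteria are explicit configuration, not an estimate of any published
#' threshold.
#'
#' @param dmrs A `dmr_set` (or tibble with `chrom`, `start`, `end`).
#' @param window_mb Maximum clustered span in Mb (default 2).
#' @param min_count Minimum DMRs per cluster (default 3).
#' @return `dmrs` with an integer `cluster` column (NA outside clusters),
#'   numbered per genome in positional order.
#' @export
flag_dmr_clusters <- function(dmrs, window_mb = 2, min_count = 3) {
  span_bp <- window_mb * 1e6
  out <- dmrs |>
    as_tibble() |>
    arrange(.data$chrom, .data$start) |>
    mutate(cluster = NA_integer_)
  next_id <- 1L
  for (ch in unique(out$chrom)) {
    idx <- which(out$chrom == ch)
    s <- out$start[idx]
    e <- out$end[idx]
    k <- length(idx)
    in_run <- rep(FALSE, k)
    for (i in seq_len(k)) {
      # furthest j such that dmrs i..j fit within span_bp
      j <- max(which(e[i:k] - s[i] <= span_bp)) + i - 1L
      if (j - i + 1L >= min_count) in_run[i:j] <- TRUE
    }
    if (any(in_run)) {
      runs <- rle(in_run)
      pos <- cumsum(c(1L, head(runs$lengths, -1L)))
      for (r in seq_along(runs$values)) {
        if (runs$values[r]) {
          sel <- idx[pos[r]:(pos[r] + runs$lengths[r] - 1L)]
          out$cluster[sel] <- next_id
          next_id <- next_id + 1L
        }
      }
    }
  }
  out
}

#' Tally gene functional categories
#'
#' Joins gene links against a user-supplied gene-to-category table and
#' tallies the categories; genes missing from the table count as
#' `"unknown"`. The table must be unambiguous: duplicated gene rows with
#' conflicting categories are rejected.
#'
#' @param gene_links Tibble with a `gene_id` column (e.g. from
#'   [associate_genes()]; `NA` gene ids are ignored).
#' @param category_table Tibble with columns `gene_id` and `category`.
#' @return A tibble `category`, `n`, sorted by decreasing count.
#' @export
assign_categories <- function(gene_links, category_table) {
  if (nrow(category_table)) {
    dup <- category_table |>
      distinct(.data$gene_id, .data$category) |>
      count(.data$gene_id) |>
      filter(.data$n > 1L)
    if (nrow(dup)) {
      abort(paste0("conflicting categories for gene(s): ",
                   paste(dup$gene_id, collapse = ", ")))
    }
    category_table <- distinct(category_table, .data$gene_id, .data$category)
  }
  gene_links |>
    filter(!is.na(.data$gene_id)) |>
    left_join(category_table, by = "gene_id") |>
    mutate(category = coalesce(.data$category, "unknown")) |>
    count(.data$category, sort = TRUE)
}
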