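#' Build a fixed-width genomic window grid
#'
#' Tiles each chromosome with non-overlapping windows of `width` bp
#' (default 1000). The final window of a chromosome is truncated when the
#' length is not a multiple of the width; truncated windows are retained
#' and flagged. Coordinates are 0-based half-open throughout.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths, or a
#'   data frame with columns `chrom` and `length`.
#' @param width Window width in bp.
#' @return A tibble with columns `window` (1-based global index), `chrom`,
#'   `start`, `end`, `width`, `short` (logical, truncated terminal
#'   window).
#' @examples
#' make_windows(c(chr1 = 3500), width = 1000)
#' @export
make_windows <- function(chrom_sizes, width = 1000) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  }
  if (length(chrom_sizes) == 0L) abort("empty chromosome set")
  if (width <= 0) abort("`width` must be positive")
  grid <- imap(chrom_sizes, function(len, chrom) {
    starts <- seq(0, len - 1, by = width)
    tibble(chrom = chrom, start = starts, end = pmin(starts + width, len))
  }) |> list_rbind()
  grid |>
    mutate(window = row_number(),
           width = .data$end - .data$start,
           short = .data$width < !!width) |>
    select("window", "chrom", "start", "end", "width", "short")
}

#' Count reads into grid windows by midpoint
#'
#' Each read interval is assigned to exactly one window: the window
#' containing its midpoint `floor((start + end) / 2)`. Reads whose
#' midpoint falls beyond the chromosome end (or on an unknown chromosome)
#' are dropped with a message. The rule conserves counts: every retained
#' read contributes to exactly one window.
#'
#' @param reads Tibble of read intervals with columns `chrom`, `start`,
#'   `end` (0-based half-open) and optionally `sample`; without a `sample`
#'   column all reads form one sample called `"S1"`.
#' @param grid Window grid from [make_windows()].
#' @return A list with `counts` (integer matrix, windows x samples, row
#'   names the window index) and `lib_sizes` (named vector of total input
#'   reads per sample, including dropped ones).
#' @export
count_reads <- function(reads, grid) {
  if (!"sample" %in% names(reads)) reads$sample <- "S1"
  samples <- sort(unique(reads$sample))
  lib_sizes <- vapply(samples, function(s) sum(reads$sample == s), numeric(1))
  counts <- matrix(0L, nrow = nrow(grid), ncol = length(samples),
                   dimnames = list(grid$window, samples))
  if (nrow(reads) > 0L) {
    mid <- (reads$start + reads$end) %/% 2
    chrom_ends <- grid |> group_by(.data$chrom) |> summarise(len = max(.data$end))
    ends <- setNames(chrom_ends$len, chrom_ends$chrom)
    ok <- reads$chrom %in% names(ends) & mid < ends[reads$chrom] & mid >= 0
    if (any(!ok)) {
      inform(sprintf("dropping %d read(s) outside the grid", sum(!ok)))
    }
    reads <- reads[ok, ]
    mid <- mid[ok]
    # window index: per-chromosome offset + floor(mid / width); robust to
    # truncated terminal windows because those are the last per chromosome
    first_idx <- grid |> group_by(.data$chrom) |>
      summarise(first = min(.data$window), width = max(.data$width))
    off <- setNames(first_idx$first, first_idx$chrom)
    w <- setNames(first_idx$width, first_idx$chrom)
    idx <- off[reads$chrom] + mid %/% w[reads$chrom]
    tab <- tibble(idx = as.integer(idx), sample = reads$sample) |>
      count(.data$idx, .data$sample)
    counts[cbind(tab$idx, match(tab$sample, samples))] <- tab$n
  }
  list(counts = counts, lib_sizes = lib_sizes)
}

#' RPKM-normalise a window count matrix
#'
#' Reads per kilobase of window per million mapped reads:
#' `count / (width_kb * lib_size / 1e6)`. Windows shorter than the grid
#' width (truncated terminal windows) use their actual length.
#'
#' @param counts Windows x samples count matrix.
#' @param lib_sizes Per-sample library sizes (named like the columns or in
#'   column order); defaults to the column sums of `counts`.
#' @param widths Per-window lengths in bp (defaults to `grid$width` when a
#'   `grid` tibble is supplied instead).
#' @return A numeric matrix of the same shape as `counts`.
#' @examples
#' rpkm_normalize(matrix(10), lib_sizes = 1e7, widths = 1000)  # 1.0
#' @export
rpkm_normalize <- function(counts, lib_sizes = colSums(counts), widths = 1000) {
  if (any(lib_sizes <= 0)) abort("library sizes must be positive")
  if (length(widths) == 1L) widths <- rep(widths, nrow(counts))
  if (length(widths) != nrow(counts)) {
    abort("`widths` must have one entry per window")
  }
  sweep(counts / (widths / 1000), 2, lib_sizes / 1e6, "/")
}

#' Select the top windows by mean RPKM
#'
#' Ranks windows by their mean RPKM across samples and returns the top
#' `n`; ties are broken by genomic order (smaller window index first).
#' When fewer than `n` windows are available, all are returned with a
#' warning.
#'
#' @param rpkm Windows x samples RPKM matrix with window indices as row
#'   names.
#' @param n Number of windows to keep (default 100,000).
#' @return Integer vector of selected window indices, in genomic order.
#' @export
select_top_windows <- function(rpkm, n = 100000) {
  if (n < 1) abort("`n` must be at least 1")
  means <- rowMeans(rpkm)
  idx <- as.integer(rownames(rpkm) %||% seq_len(nrow(rpkm)))
  if (n >= length(means)) {
    if (n > length(means)) {
      warn(sprintf("requested %d windows but only %d available", n,
                   length(means)))
    }
    return(sort(idx))
  }
  ord <- order(-means, idx)
  sort(idx[ord[seq_len(n)]])
}
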