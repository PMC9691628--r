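# Cross-comparison DMR overlap analysis. The overlap relation throughout
# is >= 1 bp of genomic intersection; a region overlapping several
# partners still counts once.

dmr_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

#' Count DMRs of one set overlapping another
#'
#' A member of `set_a` is counted when it shares at least one base with
#' any member of `set_b`; the percentage is relative to `|set_a|`
#' (`NA` when `set_a` is empty).
#'
#' @param set_a,set_b DMR tibbles with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return A tibble with `n_a`, `n_overlap`, `percent`.
#' @export
overlap_count <- function(set_a, set_b) {
  if (nrow(set_a) == 0L) {
    return(tibble(n_a = 0L, n_overlap = 0L, percent = NA_real_))
  }
  if (nrow(set_b) == 0L) {
    return(tibble(n_a = nrow(set_a), n_overlap = 0L, percent = 0))
  }
  # suppress the seqlevel-mismatch warning: disjoint chromosome sets are
  # a legitimate zero-overlap case here
  n <- sum(suppressWarnings(
    GenomicRanges::countOverlaps(dmr_granges(set_a), dmr_granges(set_b),
                                 minoverlap = 1L)) > 0L)
  tibble(n_a = nrow(set_a), n_overlap = n,
         percent = percent_of(n, nrow(set_a)))
}

#' Three-way DMR Venn region counts
#'
#' Assigns every DMR from the three comparison sets a membership pattern:
#' its own set plus any other set it overlaps by at least one base. Region
#' counts are the numbers of DMRs per pattern, so they sum to the total
#' number of DMRs and each set's marginal equals its cardinality.
#'
#' @param sets Named list of exactly three DMR tibbles (`chrom`, `start`,
#'   `end`).
#' @return A tibble with one row per non-empty pattern: logical membership
#'   columns named after `sets`, a `pattern` label, and `n`.
#' @export
venn_counts <- function(sets) {
  if (length(sets) != 3L || is.null(names(sets))) {
    abort("`sets` must be a named list of three DMR tables")
  }
  nm <- names(sets)
  grs <- map(sets, dmr_granges)
  assign_pattern <- function(i) {
    set <- sets[[i]]
    if (nrow(set) == 0L) return(NULL)
    memb <- matrix(FALSE, nrow(set), 3L, dimnames = list(NULL, nm))
    memb[, i] <- TRUE
    for (j in setdiff(seq_len(3L), i)) {
      if (nrow(sets[[j]]) > 0L) {
        memb[, j] <- suppressWarnings(
          GenomicRanges::countOverlaps(grs[[i]], grs[[j]],
                                       minoverlap = 1L)) > 0L
      }
    }
    as_tibble(memb)
  }
  pats <- map(seq_len(3L), assign_pattern) |> list_rbind()
  if (is.null(pats) || nrow(pats) == 0L) {
    return(tibble(!!nm[1] := logical(), !!nm[2] := logical(),
                  !!nm[3] := logical(), pattern = character(), n = integer()))
  }
  pats |>
    count(across(all_of(nm))) |>
    mutate(pattern = pmap_chr(across(all_of(nm)),
                              ~ paste(nm[c(...)], collapse = "&"))) |>
    relocate("pattern", .before = "n")
}

#' Extended overlap against a relaxed-threshold DMR set
#'
#' Takes a strict-threshold DMR set from comparison A and measures its
#' overlap with comparison B's DMRs re-called at a relaxed seed threshold
#' (default `p < 0.05`), quantifying shared signal that a stringent
#' threshold hides.
#'
#' @param set_a_strict Strict DMR set from comparison A.
#' @param results_b Full [test_windows()] results for comparison B.
#' @param grid Window grid.
#' @param p_relaxed Relaxed seed threshold for re-calling B's DMRs.
#' @param p_extend,gap_bp Extension parameters passed to [call_dmrs()];
#'   `p_extend` is raised to `p_relaxed` when necessary.
#' @return A tibble with `n_a`, `n_overlap`, `percent`, `p_relaxed`.
#' @export
extended_overlap <- function(set_a_strict, results_b, grid, p_relaxed = 0.05,
                             p_extend = 0.1, gap_bp = 1000) {
  relaxed <- call_dmrs(results_b, grid, p_seed = p_relaxed,
                       p_extend = max(p_extend, p_relaxed), gap_bp = gap_bp)
  overlap_count(set_a_strict, relaxed) |>
    mutate(p_relaxed = p_relaxed)
}
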