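#' Call differentially methylated regions by seed-and-extend
#'
#' Windows with `p_value < p_seed` (default 1e-4) seed DMRs. Each DMR is
#' then extended to a fixed point: any window with `p_value < p_extend`
#' (default 0.1) whose span lies within `gap_bp` of the current DMR span
#' (edge-to-edge distance strictly below `gap_bp`; adjacent windows
#' qualify at gap 0) is absorbed, and DMRs whose spans come to overlap or
#' abut are merged. Extension never crosses a chromosome boundary. The
#' result is order-independent: after convergence no window outside a DMR
#' with `p_value < p_extend` lies within `gap_bp` of its span.
#'
#' @param results A [test_windows()] result (or any tibble with `window`,
#'   `p_value`, `log2fc` columns).
#' @param grid Window grid from [make_windows()], optionally carrying a
#'   `cpg` column (CpG dinucleotide count per window) for density
#'   annotation.
#' @param p_seed Seed threshold; a DMR contains at least one window below
#'   it.
#' @param p_extend Extension threshold; must be `>= p_seed`.
#' @param gap_bp Maximum edge separation considered "nearby" during
#'   extension (exclusive bound).
#' @param fc_summary How the per-DMR `log2fc` is summarised: from the
#'   minimum-p window (default) or the mean over member windows.
#' @return A tibble of class `dmr_set`: `chrom`, `start`, `end`, `length`,
#'   `n_windows`, `n_significant_windows`, `min_p`, `log2fc`, and
#'   `cpg_per_100bp` when the grid has CpG counts. Calling parameters are
#'   attached as attribute `"params"`.
#' @export
call_dmrs <- function(results, grid, p_seed = 1e-4, p_extend = 0.1,
                      gap_bp = 1000, fc_summary = c("min_p", "mean")) {
  fc_summary <- match.arg(fc_summary)
  if (p_seed <= 0 || p_seed > 1 || p_extend <= 0 || p_extend > 1) {
    abort("thresholds must lie in (0, 1]")
  }
  if (p_extend < p_seed) abort("`p_extend` must be >= `p_seed`")
  dat <- grid |>
    inner_join(as_tibble(results)[c("window", "p_value", "log2fc")],
               by = "window") |>
    arrange(.data$chrom, .data$start)
  if (nrow(dat) != nrow(grid)) {
    abort("`results` must cover every window of the grid")
  }
  out <- dat |>
    group_by(.data$chrom) |>
    group_map(~ seed_extend_chrom(.x, .y$chrom, p_seed, p_extend, gap_bp,
                                  fc_summary)) |>
    list_rbind()
  if (is.null(out) || nrow(out) == 0L) {
    out <- empty_dmr_set("cpg" %in% names(grid))
  }
  out <- out |> arrange(.data$chrom, .data$start)
  attr(out, "params") <- list(p_seed = p_seed, p_extend = p_extend,
                              gap_bp = gap_bp, fc_summary = fc_summary)
  class(out) <- c("dmr_set", class(out))
  out
}

# Fixed-point seed-and-extend on one chromosome's sorted windows.
seed_extend_chrom <- function(dat, chrom, p_seed, p_extend, gap_bp,
                              fc_summary) {
  p <- dat$p_value
  is_seed <- p < p_seed
  is_ext <- p < p_extend
  if (!any(is_seed)) return(NULL)
  start <- dat$start
  end <- dat$end
  # intervals are [lo, hi] index ranges; spans cover all windows between
  ivs <- lapply(which(is_seed), function(i) c(i, i))
  repeat {
    changed <- FALSE
    ivs <- lapply(ivs, function(iv) {
      repeat {
        grew <- FALSE
        lo <- iv[1]; hi <- iv[2]
        left <- which(is_ext & seq_along(p) < lo & end > start[lo] - gap_bp)
        if (length(left)) { iv[1] <- min(left); grew <- TRUE }
        right <- which(is_ext & seq_along(p) > hi & start < end[hi] + gap_bp)
        if (length(right)) { iv[2] <- max(right); grew <- TRUE }
        if (!grew) break
        changed <<- TRUE
      }
      iv
    })
    # merge intervals whose spans overlap or abut; the grid tiles the
    # chromosome, so index-adjacency is span-abutment
    ivs <- ivs[order(vapply(ivs, `[`, numeric(1), 1))]
    merged <- list(ivs[[1]])
    for (iv in ivs[-1]) {
      last <- merged[[length(merged)]]
      if (iv[1] <= last[2] + 1L) {
        if (iv[2] > last[2]) changed <- TRUE
        merged[[length(merged)]] <- c(last[1], max(last[2], iv[2]))
      } else {
        merged <- c(merged, list(iv))
      }
    }
    ivs <- merged
    if (!changed) break
  }
  map(ivs, function(iv) {
    sel <- iv[1]:iv[2]
    pmin_i <- sel[which.min(p[sel])]
    fc <- if (fc_summary == "min_p") dat$log2fc[pmin_i] else
      mean(dat$log2fc[sel])
    span_start <- start[iv[1]]
    span_end <- end[iv[2]]
    rec <- tibble(
      chrom = chrom,
      start = span_start,
      end = span_end,
      length = span_end - span_start,
      n_windows = length(sel),
      n_significant_windows = sum(is_seed[sel]),
      min_p = p[pmin_i],
      log2fc = fc
    )
    if ("cpg" %in% names(dat)) {
      rec$cpg_per_100bp <- 100 * sum(dat$cpg[sel]) / rec$length
    }
    rec
  }) |> list_rbind()
}

empty_dmr_set <- function(has_cpg) {
  out <- tibble(
    chrom = character(), start = numeric(), end = numeric(),
    length = numeric(), n_windows = integer(),
    n_significant_windows = integer(), min_p = numeric(), log2fc = numeric()
  )
  if (has_cpg) out$cpg_per_100bp <- numeric()
  out
}

#' Count all-window and multiple-window DMRs
#'
#' The "multiple window" class contains DMRs with at least two
#' seed-significant windows; "all window" counts every DMR.
#'
#' @param dmrs A `dmr_set` from [call_dmrs()].
#' @return A tibble with columns `all_window` and `multiple_window`.
#' @export
classify_multi_window <- function(dmrs) {
  tibble(
    all_window = nrow(dmrs),
    multiple_window = if (nrow(dmrs)) sum(dmrs$n_significant_windows >= 2L)
    else 0L
  )
}

#' DMR counts across seed-threshold stringencies
#'
#' Re-runs the seed-and-extend caller at each seed threshold and tabulates
#' all-window and multiple-window DMR counts, the layout used to compare
#' DMR discovery across p-value cutoffs.
#'
#' @inheritParams call_dmrs
#' @param thresholds Seed p-value cutoffs.
#' @return A tibble with columns `p_seed`, `all_window`, `multiple_window`.
#' @export
dmr_threshold_table <- function(results, grid,
                                thresholds = c(1e-3, 1e-4, 1e-5, 1e-6, 1e-7),
                                p_extend = 0.1, gap_bp = 1000) {
  map(sort(thresholds, decreasing = TRUE), function(th) {
    dmrs <- call_dmrs(results, grid, p_seed = th,
                      p_extend = max(p_extend, th), gap_bp = gap_bp)
    bind_cols(tibble(p_seed = th), classify_multi_window(dmrs))
  }) |> list_rbind()
}
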