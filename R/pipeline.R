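#' Run one discordance comparison end to end
#'
#' Executes the full per-comparison analysis for one sex: mapping QC
#' (removing low-mapping samples with their co-twins), construction of
#' the low/high discordance arms, per-window negative-binomial exact
#' tests, seed-and-extend DMR calling, gene association, and the DMR
#' threshold table. The sexes are always analysed separately; no
#' mixed-sex test can be produced. When the study carries a planted truth
#' set, recovery metrics are attached.
#'
#' @param study A `twin_study` from [simulate_study()] (or an equivalent
#'   list with `cohort`, `counts`, `lib_sizes`, `windows`, `genes`,
#'   optionally `truth`).
#' @param comparison `"pa"`, `"walkability"` or `"bmi"`.
#' @param sex `"M"` or `"F"`.
#' @param p_seed,p_extend,gap_bp DMR calling parameters, see
#'   [call_dmrs()].
#' @param dispersion Optional dispersion override for [test_windows()].
#' @param flank Gene association flank in bp.
#' @param thresholds Seed thresholds of the DMR threshold table.
#' @return A `comparison_report`: list with `comparison`, `sex`, `groups`,
#'   `results`, `dmrs`, `gene_links`, `threshold_table`, `recovery`
#'   (NULL without truth), `params`.
#' @export
run_comparison <- function(study, comparison = c("pa", "walkability", "bmi"),
                           sex = c("M", "F"), p_seed = 1e-4, p_extend = 0.1,
                           gap_bp = 1000, dispersion = NULL, flank = 10000,
                           thresholds = c(1e-3, 1e-4, 1e-5, 1e-6, 1e-7)) {
  comparison <- match.arg(comparison)
  sex <- match.arg(sex)
  traits <- apply_mapping_qc(study$cohort)
  grp <- comparison_groups(traits, comparison, sex)
  counts <- study$counts[, grp$id, drop = FALSE]
  groups <- factor(grp$arm, levels = c("low", "high"))
  res <- test_windows(counts, groups, lib_sizes = study$lib_sizes[grp$id],
                      dispersion = dispersion)
  dmrs <- call_dmrs(res, study$windows, p_seed = p_seed,
                    p_extend = p_extend, gap_bp = gap_bp)
  gene_links <- if (nrow(dmrs)) {
    associate_genes(as_tibble(dmrs)[c("chrom", "start", "end")],
                    study$genes, flank = flank)
  } else tibble()
  tt <- dmr_threshold_table(res, study$windows, thresholds = thresholds,
                            p_extend = p_extend, gap_bp = gap_bp)
  recovery <- NULL
  if (!is.null(study$truth) && nrow(study$truth$planted_dmrs)) {
    recovery <- score_dmr_recovery(dmrs, study$truth, comparison,
                                   study$config$window_size_bp,
                                   grid = study$windows)
  }
  structure(list(
    comparison = comparison, sex = sex, groups = grp, results = res,
    dmrs = dmrs, gene_links = gene_links, threshold_table = tt,
    recovery = recovery,
    params = list(p_seed = p_seed, p_extend = p_extend, gap_bp = gap_bp,
                  flank = flank,
                  dispersion = attr(res, "dispersion"))
  ), class = "comparison_report")
}

#' Score called DMRs against a planted truth set
#'
#' A planted DMR of the tested trait counts as recovered when a called
#' DMR overlaps it by at least one base, and as boundary-accurate when
#' additionally both edges of that call lie within one window of the
#' truth. Called DMRs overlapping no planted feature at all (neither a
#' planted DMR of any trait nor a latent module window) are counted as
#' false positives.
#'
#' @param dmrs Called `dmr_set`.
#' @param truth Truth list from [simulate_truth()].
#' @param comparison Trait of the comparison being scored.
#' @param window_bp Window width used for the one-window boundary slack.
#' @param grid Optional window grid, used to exempt latent-module windows
#'   (real trait-linked signal) from the false-positive count.
#' @return A one-row tibble: `n_planted`, `n_recovered`, `n_boundary_ok`,
#'   `recovery_rate`, `boundary_rate`, `n_false`.
#' @export
score_dmr_recovery <- function(dmrs, truth, comparison, window_bp = 1000,
                               grid = NULL) {
  planted <- truth$planted_dmrs |> filter(.data$trait == comparison)
  called <- as_tibble(dmrs)
  hit <- function(p) {
    ov <- called$chrom == p$chrom & called$start < p$end & called$end > p$start
    if (!any(ov)) return(c(FALSE, FALSE))
    ok <- any(abs(called$start[ov] - p$start) <= window_bp &
                abs(called$end[ov] - p$end) <= window_bp)
    c(TRUE, ok)
  }
  scores <- vapply(seq_len(nrow(planted)),
                   function(i) hit(planted[i, ]), logical(2))
  n_rec <- if (nrow(planted)) sum(scores[1, ]) else 0L
  n_ok <- if (nrow(planted)) sum(scores[2, ]) else 0L
  # calls not explained by any planted signal (DMRs of any trait, or
  # latent module windows, which carry real trait-linked differences)
  explained <- rep(FALSE, nrow(called))
  all_planted <- truth$planted_dmrs
  for (i in seq_len(nrow(all_planted))) {
    p <- all_planted[i, ]
    explained <- explained |
      (called$chrom == p$chrom & called$start < p$end & called$end > p$start)
  }
  if (nrow(truth$module_membership) && !is.null(grid)) {
    mw <- grid[match(truth$module_membership$window, grid$window), ]
    explained <- explained | vapply(seq_len(nrow(called)), function(i) {
      any(mw$chrom == called$chrom[i] & mw$start < called$end[i] &
            mw$end > called$start[i])
    }, logical(1))
  }
  tibble(
    n_planted = nrow(planted),
    n_recovered = n_rec,
    n_boundary_ok = n_ok,
    recovery_rate = if (nrow(planted)) n_rec / nrow(planted) else NA_real_,
    boundary_rate = if (nrow(planted)) n_ok / nrow(planted) else NA_real_,
    n_false = sum(!explained)
  )
}

#' Run the correlation-network stage for one sex
#'
#' Selects the top windows by mean RPKM, detects modules on the unsigned
#' topological overlap (power 6 for female, 9 for male samples by
#' default), computes module eigengenes and correlates them with the
#' numeric-coded traits (MVPA, walkability score, BMI, waist, plus the
#' per-trait discordance flags). All samples are treated as independent;
#' twin pairing is ignored at this stage.
#'
#' @param study A `twin_study`.
#' @param sex `"M"` or `"F"`.
#' @param config A [network_config()]; when `NULL`, defaults with the
#'   per-sex power.
#' @param p_filter Threshold of the filtered module-trait summary.
#' @return A `network_report`: list with `sex`, `fit` (a `wcna_fit`),
#'   `module_trait` (a `module_trait_cor`), `top_windows`, `traits`,
#'   `recovery` (module-to-truth matching, NULL without truth).
#' @export
run_network <- function(study, sex = c("M", "F"), config = NULL,
                        p_filter = 0.001) {
  sex <- match.arg(sex)
  config <- config %||% network_config(power = default_network_power(sex))
  traits <- apply_mapping_qc(study$cohort) |> filter(.data$sex == !!sex)
  if (nrow(traits) < 4L) abort("need at least 4 samples for the network stage")
  rpkm <- rpkm_normalize(study$counts[, traits$id, drop = FALSE],
                         lib_sizes = study$lib_sizes[traits$id],
                         widths = study$windows$width)
  sel <- select_top_windows(rpkm, n = config$top_n)
  profiles <- t(rpkm[as.character(sel), , drop = FALSE])
  fit <- wcna_modules(profiles, config, seed = study$config$seed)
  trait_mat <- network_trait_table(traits)
  mt <- module_trait_cor(fit$eigengenes, trait_mat, p_filter = p_filter)
  recovery <- NULL
  if (!is.null(study$truth) && nrow(study$truth$trait_links)) {
    recovery <- score_module_recovery(fit$assignment, study$truth)
  }
  structure(list(sex = sex, fit = fit, module_trait = mt, top_windows = sel,
                 traits = trait_mat, recovery = recovery, config = config),
            class = "network_report")
}

# Numeric trait codes used in module-trait correlation: measured traits
# plus 0/1 discordance flags shared by both members of a pair.
network_trait_table <- function(traits) {
  flags <- classify_discordance(traits)
  traits |>
    left_join(flags |> select("pair_id", ends_with("_discordant")),
              by = "pair_id") |>
    transmute(
      mvpa_min_week = .data$mvpa_min_week,
      walkability_score = .data$walkability_score,
      bmi = .data$bmi,
      waist_cm = .data$waist_cm,
      pa_discordant = as.numeric(.data$pa_discordant),
      walkability_discordant = as.numeric(.data$walkability_discordant),
      bmi_discordant = as.numeric(.data$bmi_discordant)
    ) |> as.data.frame()
}

# Match each planted module to its best-overlapping detected module
# (Jaccard index over window sets).
score_module_recovery <- function(assignment, truth) {
  mods <- setdiff(unique(assignment$module), "grey")
  map(unique(truth$module_membership$module_id), function(mid) {
    planted <- as.character(
      truth$module_membership$window[truth$module_membership$module_id == mid])
    jac <- vapply(mods, function(m) {
      det <- assignment$window[assignment$module == m]
      length(intersect(planted, det)) / length(union(planted, det))
    }, numeric(1))
    best <- if (length(jac)) which.max(jac) else NA_integer_
    tibble(module_id = mid,
           detected = if (length(jac)) mods[best] else NA_character_,
           jaccard = if (length(jac)) jac[best] else 0)
  }) |> list_rbind()
}

#' Principal component analysis of samples over DMR methylation
#'
#' Summarises each sample by its mean RPKM over the member windows of
#' every DMR, mean-centres the DMR features and reports the sample
#' coordinates on the first two principal components together with the
#' variance explained and the silhouette score of the two discordance
#' arms on the PC1-PC2 plane (positive silhouette = separated arms).
#'
#' @param study A `twin_study`.
#' @param dmrs A `dmr_set` (at least one DMR).
#' @param groups Arm table from [comparison_groups()] (or a
#'   `comparison_report`'s `groups` element).
#' @return A `dmr_pca` object: list with `scores` (tibble `id`, `arm`,
#'   `PC1`, `PC2`), `var_explained` (fractions), `silhouette`.
#' @export
pca_dmr_features <- function(study, dmrs, groups) {
  if (nrow(dmrs) < 1L) abort("need at least one DMR")
  if (nrow(groups) < 2L) abort("need at least two samples")
  rpkm <- rpkm_normalize(study$counts[, groups$id, drop = FALSE],
                         lib_sizes = study$lib_sizes[groups$id],
                         widths = study$windows$width)
  feat <- vapply(seq_len(nrow(dmrs)), function(i) {
    sel <- study$windows$chrom == dmrs$chrom[i] &
      study$windows$start >= dmrs$start[i] & study$windows$end <= dmrs$end[i]
    colMeans(rpkm[sel, , drop = FALSE])
  }, numeric(nrow(groups)))
  pc <- prcomp(feat, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble(
    id = groups$id,
    arm = groups$arm,
    PC1 = pc$x[, 1],
    PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else NA_real_
  )
  sil <- silhouette_two_groups(
    cbind(scores$PC1, if (ncol(pc$x) >= 2) scores$PC2 else 0), scores$arm)
  structure(list(scores = scores,
                 var_explained = ve[seq_len(min(2, length(ve)))],
                 silhouette = sil),
            class = "dmr_pca")
}

# Mean silhouette width for a two-group labelling under Euclidean
# distance; degenerate (all-identical) inputs give 0.
silhouette_two_groups <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- mean(d[i, own])
    b <- mean(d[i, !own])
    if (!is.finite(a) || !is.finite(b) || max(a, b) == 0) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Run every comparison and the network stage on a study
#'
#' Orchestrates the full analysis: all three discordance comparisons for
#' both sexes (skipping, with a message, any comparison without
#' discordant pairs) followed by the per-sex network stage. A manifest
#' tibble records every produced component with its key parameters and
#' the study seed, so a run can be reproduced from the manifest alone.
#'
#' @param study A `twin_study`.
#' @param comparisons Traits to compare.
#' @param sexes Sexes to analyse.
#' @param run_networks Whether to run the correlation-network stage.
#' @param ... Passed to [run_comparison()].
#' @return A `study_report`: list with `comparisons` (named
#'   `comparison_report`s, e.g. `"M_pa"`), `networks` (named
#'   `network_report`s), `manifest`.
#' @export
run_study <- function(study, comparisons = c("pa", "walkability", "bmi"),
                      sexes = c("M", "F"), run_networks = TRUE, ...) {
  reports <- list()
  manifest <- list()
  for (sx in sexes) {
    for (cmp in comparisons) {
      key <- paste(sx, cmp, sep = "_")
      rep <- tryCatch(run_comparison(study, cmp, sx, ...),
                      error = function(e) {
                        inform(paste0("skipping ", key, ": ",
                                      conditionMessage(e)))
                        NULL
                      })
      if (!is.null(rep)) {
        reports[[key]] <- rep
        manifest[[key]] <- tibble(
          component = key, kind = "comparison",
          n_samples = nrow(rep$groups), n_dmrs = nrow(rep$dmrs),
          params = list(rep$params), seed = study$config$seed)
      }
    }
  }
  networks <- list()
  if (run_networks) {
    for (sx in sexes) {
      nrep <- tryCatch(run_network(study, sx), error = function(e) {
        inform(paste0("skipping network ", sx, ": ", conditionMessage(e)))
        NULL
      })
      if (!is.null(nrep)) {
        networks[[sx]] <- nrep
        manifest[[paste0("network_", sx)]] <- tibble(
          component = paste0("network_", sx), kind = "network",
          n_samples = nrow(nrep$fit$eigengenes),
          n_dmrs = NA_integer_,
          params = list(unclass(nrep$config)), seed = study$config$seed)
      }
    }
  }
  structure(list(comparisons = reports, networks = networks,
                 manifest = list_rbind(manifest)),
            class = "study_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cm <- classify_multi_window(x$dmrs)
  cat(sprintf("<comparison_report> %s %s: %d vs %d samples\n", x$sex,
              x$comparison, sum(x$groups$arm == "low"),
              sum(x$groups$arm == "high")))
  cat(sprintf("  %d DMRs at p < %g (%d multiple-window); dispersion %.3g\n",
              cm$all_window, x$params$p_seed, cm$multiple_window,
              x$params$dispersion))
  if (!is.null(x$recovery)) {
    cat(sprintf("  recovery: %d/%d planted (boundaries ok %d), %d false\n",
                x$recovery$n_recovered, x$recovery$n_planted,
                x$recovery$n_boundary_ok, x$recovery$n_false))
  }
  invisible(x)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d comparison(s), %d network(s)\n",
              length(x$comparisons), length(x$networks)))
  for (r in x$comparisons) print(r)
  invisible(x)
}
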