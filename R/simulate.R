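# Synthetic twin-cohort MeDIP-seq study generator. Every stage draws from
# a child seed of `config$seed`, so a config fixes each output exactly.

#' Generate a synthetic reference genome with controlled CpG density
#'
#' Builds one random sequence per chromosome on an A/T background with CG
#' dinucleotides planted at non-overlapping positions, so that each 1 kb
#' window attains a target CpG density drawn uniformly from 1-10 CpG per
#' 100 bp. Per-window CpG counts are recomputed from the written sequence
#' (not taken from the planting bookkeeping), so the returned grid is
#' exactly consistent with the FASTA.
#'
#' @param config A [sim_config()].
#' @return A list with `reference` (a [Biostrings::DNAStringSet]) and
#'   `windows` (the window grid of [make_windows()] plus `cpg`,
#'   `cpg_per_100bp` and `cpg_bin` columns).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$window_size_bp
  L <- config$chrom_length_bp
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  seqs <- with_seed(child_seed(config$seed, 1L), {
    lapply(chroms, function(ch) {
      chars <- sample(c("A", "T"), L, replace = TRUE)
      starts <- seq(0, L - 1, by = w)
      density <- sample(1:10, length(starts), replace = TRUE)
      for (i in seq_along(starts)) {
        n_cpg <- round(density[i] * w / 100)
        # odd offsets keep planted CGs non-overlapping and prevent
        # accidental CG formation against the A/T background
        pos <- starts[i] + sample(seq(1L, w - 1L, by = 2L), n_cpg)
        chars[pos] <- "C"
        chars[pos + 1L] <- "G"
      }
      paste(chars, collapse = "")
    })
  })
  reference <- Biostrings::DNAStringSet(setNames(unlist(seqs), chroms))
  grid <- make_windows(setNames(rep(L, length(chroms)), chroms), width = w)
  grid <- cpg_density(grid, reference) |> rename(cpg = "cpg_count")
  list(reference = reference, windows = grid)
}

#' Generate a toy gene annotation
#'
#' Scatters gene models (2-8 kb) over the synthetic genome, roughly one
#' gene per 12 windows, with random strands. Useful for exercising
#' gene-proximity annotation.
#'
#' @param config A [sim_config()].
#' @return A tibble `gene_id`, `symbol`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @export
simulate_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$chrom_length_bp
  n_per_chrom <- max(1L, (L %/% config$window_size_bp) %/% 12L)
  with_seed(child_seed(config$seed, 2L), {
    genes <- map(paste0("chr", seq_len(config$n_chromosomes)), function(ch) {
      len <- round(runif(n_per_chrom, 2000, 8000))
      start <- sort(sample.int(max(L - max(len), 1L), n_per_chrom))
      tibble(chrom = ch, start = start, end = pmin(start + len, L),
             strand = sample(c("+", "-"), n_per_chrom, replace = TRUE))
    }) |> list_rbind()
    genes |>
      mutate(gene_id = sprintf("GENE%04d", row_number()),
             symbol = sprintf("G%d", row_number())) |>
      select("gene_id", "symbol", "chrom", "start", "end", "strand")
  })
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw within-pair (low, high) trait values for one trait, with the first
# discordant pair anchored at the published exemplar magnitudes.
draw_pair_values <- function(n, disc, exemplar, draw_disc, draw_conc) {
  lo <- numeric(n)
  hi <- numeric(n)
  for (i in seq_len(n)) {
    v <- if (disc[i]) draw_disc() else draw_conc()
    lo[i] <- v[1]
    hi[i] <- v[2]
  }
  first <- which(disc)[1]
  if (!is.na(first)) {
    lo[first] <- exemplar[1]
    hi[first] <- exemplar[2]
  }
  cbind(lo, hi)
}

#' Generate a synthetic twin cohort trait table
#'
#' Produces `n_pairs_per_sex` monozygotic pairs per sex with MVPA
#' (min/week), neighbourhood walkability score (0-100), BMI (kg/m^2),
#' waist circumference and mapping rate. For each trait a configurable
#' fraction of pairs is made discordant under the study definitions
#' (150 MVPA min/week split; car-oriented vs walkable category split;
#' >= 5 kg/m^2 BMI difference), and the first discordant pair per sex is
#' anchored at the published exemplar magnitudes (MVPA 66/266,
#' walkability 25.7/82.0, BMI 28.4/35.2) so those reference contrasts are
#' always present. Which member of a pair is the low one is randomised.
#'
#' @param config A [sim_config()].
#' @return Participant tibble: `id`, `pair_id`, `sex`, `mvpa_min_week`,
#'   `walkability_score`, `bmi`, `waist_cm`, `mapping_rate`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_pairs_per_sex
  frac <- config$fraction_discordant
  with_seed(child_seed(config$seed, 3L), {
    one_sex <- function(sex) {
      pick <- function(f) {
        k <- round(f * n)
        is_disc <- rep(FALSE, n)
        if (k > 0) is_disc[sample.int(n, k)] <- TRUE
        is_disc
      }
      pa_disc <- pick(frac[["pa"]])
      wk_disc <- pick(frac[["walkability"]])
      bm_disc <- pick(frac[["bmi"]])
      pa <- draw_pair_values(
        n, pa_disc, c(66, 266),
        draw_disc = function() c(clamp(rnorm(1, 66, 25), 0, 149),
                                 clamp(rnorm(1, 266, 50), 150, 600)),
        draw_conc = function() if (runif(1) < 0.5) runif(2, 5, 145)
        else runif(2, 155, 420))
      wk <- draw_pair_values(
        n, wk_disc, c(25.7, 82.0),
        draw_disc = function() c(runif(1, 5, 65), runif(1, 72, 98)),
        draw_conc = function() if (runif(1) < 0.5) runif(2, 5, 65)
        else runif(2, 72, 98))
      bm <- draw_pair_values(
        n, bm_disc, c(28.4, 35.2),
        draw_disc = function() {
          lo <- clamp(rnorm(1, 28.4, 2), 20, 33)
          c(lo, lo + runif(1, 5, 8.5))
        },
        draw_conc = function() {
          m <- clamp(rnorm(1, 27, 3), 19, 38)
          d <- runif(1, 0, 4.5)
          c(m - d / 2, m + d / 2)
        })
      swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
      member <- function(vals, first) {
        ifelse(swap == first, vals[, 1], vals[, 2])
      }
      pair_id <- sprintf("%s%02d", sex, seq_len(n))
      per_member <- function(suffix, first) {
        tibble(
          id = paste0(pair_id, suffix),
          pair_id = pair_id,
          sex = sex,
          mvpa_min_week = member(pa, first),
          walkability_score = member(wk, first),
          bmi = member(bm, first)
        )
      }
      cohort <- bind_rows(per_member("a", TRUE), per_member("b", FALSE))
      cohort$waist_cm <- round(2.3 * cohort$bmi + 25 + rnorm(nrow(cohort), 0, 4), 1)
      cohort$mapping_rate <- round(runif(nrow(cohort), 0.85, 0.99), 3)
      n_low <- round(config$low_mapping_fraction * n)
      if (n_low > 0) {
        low_pairs <- pair_id[sample.int(n, n_low)]
        victim <- paste0(low_pairs, sample(c("a", "b"), n_low, replace = TRUE))
        cohort$mapping_rate[cohort$id %in% victim] <-
          round(runif(sum(cohort$id %in% victim), 0.40, 0.69), 3)
      }
      cohort
    }
    bind_rows(one_sex("F"), one_sex("M")) |>
      arrange(.data$pair_id, .data$id)
  })
}

#' Generate the planted truth of a synthetic study
#'
#' Chooses non-overlapping genomic placements for the planted DMRs and the
#' latent trait-correlated window modules (with a two-window buffer
#' between any two features, so DMR recovery and module recovery are
#' scoreable independently), assigns each DMR a signed log2 fold change
#' and an affected trait, and links each module to a trait with a random
#' sign.
#'
#' @param config A [sim_config()].
#' @param windows Window grid from [simulate_reference()].
#' @return A list with `planted_dmrs` (tibble `dmr_id`, `chrom`, `start`,
#'   `end`, `window_start`, `window_end`, `log2fc`, `trait`),
#'   `module_membership` (tibble `window`, `module_id`) and `trait_links`
#'   (tibble `module_id`, `trait`, `sign`).
#' @export
simulate_truth <- function(config, windows) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 4L), {
    occupied <- rep(FALSE, nrow(windows))
    chrom_of <- windows$chrom
    place <- function(span) {
      for (try in 1:10000) {
        i <- sample.int(nrow(windows) - span + 1L, 1L)
        sel <- i:(i + span - 1L)
        buffered <- max(1L, i - 2L):min(nrow(windows), i + span + 1L)
        if (chrom_of[i] == chrom_of[i + span - 1L] && !any(occupied[buffered])) {
          occupied[sel] <<- TRUE
          return(i)
        }
      }
      abort("could not place all planted features; genome too small")
    }
    dmrs <- NULL
    if (config$n_planted_dmrs > 0) {
      spans <- sample(seq(config$dmr_span_windows[1],
                          config$dmr_span_windows[2]),
                      config$n_planted_dmrs, replace = TRUE)
      dmrs <- map(seq_len(config$n_planted_dmrs), function(d) {
        i <- place(spans[d])
        tibble(
          dmr_id = sprintf("DMR%03d", d),
          chrom = chrom_of[i],
          start = windows$start[i],
          end = windows$end[i + spans[d] - 1L],
          window_start = i,
          window_end = i + spans[d] - 1L,
          log2fc = sample(c(-1, 1), 1) * config$dmr_log2fc,
          trait = config$dmr_traits[(d - 1L) %% length(config$dmr_traits) + 1L]
        )
      }) |> list_rbind()
    }
    membership <- NULL
    links <- NULL
    if (config$n_latent_modules > 0) {
      links <- tibble(
        module_id = sprintf("M%02d", seq_len(config$n_latent_modules)),
        trait = config$module_traits[
          (seq_len(config$n_latent_modules) - 1L) %%
            length(config$module_traits) + 1L],
        sign = sample(c(-1, 1), config$n_latent_modules, replace = TRUE)
      )
      membership <- map(seq_len(config$n_latent_modules), function(m) {
        i <- place(config$module_size_windows)
        tibble(window = i:(i + config$module_size_windows - 1L),
               module_id = links$module_id[m])
      }) |> list_rbind()
    }
    list(
      planted_dmrs = dmrs %||% tibble(
        dmr_id = character(), chrom = character(), start = integer(),
        end = integer(), window_start = integer(), window_end = integer(),
        log2fc = numeric(), trait = character()),
      module_membership = membership %||% tibble(window = integer(),
                                                 module_id = character()),
      trait_links = links %||% tibble(module_id = character(),
                                      trait = character(), sign = numeric())
    )
  })
}

#' Generate the window count matrix of a synthetic study
#'
#' Draws negative-binomial read counts per window and sample. The log
#' mean for sample `s` in window `w` is the sum of a CpG-density-driven
#' window baseline, the shared twin-pair baseline, the planted DMR effect
#' (`log2fc * ln 2` in the high discordance arm of the affected trait's
#' discordant pairs), the latent module term (`loading * f_ms` with a
#' per-sex driver `f` correlated with the linked trait at the target
#' level), and a uniform +/- `lib_size_range` sequencing-depth factor.
#' Library sizes are the column sums (every read falls in a window).
#'
#' @param config A [sim_config()].
#' @param cohort Participant table from [simulate_cohort()].
#' @param truth Truth set from [simulate_truth()].
#' @param windows Window grid with `cpg` column.
#' @return A list with `counts` (integer matrix, windows x samples),
#'   `lib_sizes`, and `module_drivers` (samples x modules matrix of the
#'   latent factors, for diagnostics).
#' @export
simulate_counts <- function(config, cohort, truth, windows) {
  stopifnot(inherits(config, "sim_config"))
  ns <- nrow(cohort)
  nw <- nrow(windows)
  mu_w <- config$mean_depth * (0.5 + windows$cpg) / (0.5 + mean(windows$cpg))
  if (any(mu_w < 0)) abort("negative window means")
  flags <- classify_discordance(cohort)
  with_seed(child_seed(config$seed, 5L), {
    pair_eff <- rnorm(length(unique(cohort$pair_id)), 0, config$pair_effect_sd)
    names(pair_eff) <- unique(cohort$pair_id)
    depth_mult <- runif(ns, 1 - config$lib_size_range, 1 + config$lib_size_range)
    # log-mean matrix: window baseline + per-sample offsets
    log_mu <- matrix(log(mu_w), nw, ns) +
      matrix(pair_eff[cohort$pair_id] + log(depth_mult), nw, ns, byrow = TRUE)
    # planted DMR effects in the high arm of the affected trait
    if (nrow(truth$planted_dmrs)) {
      high_ids <- list(
        pa = flags$pa_high_id[flags$pa_discordant],
        walkability = flags$walkability_high_id[flags$walkability_discordant],
        bmi = flags$bmi_high_id[flags$bmi_discordant]
      )
      for (d in seq_len(nrow(truth$planted_dmrs))) {
        rec <- truth$planted_dmrs[d, ]
        cols <- which(cohort$id %in% high_ids[[rec$trait]])
        rows <- rec$window_start:rec$window_end
        log_mu[rows, cols] <- log_mu[rows, cols] + rec$log2fc * log(2)
      }
    }
    # latent module drivers, correlated with their trait within each sex
    drivers <- matrix(0, ns, nrow(truth$trait_links),
                      dimnames = list(cohort$id, truth$trait_links$module_id))
    if (nrow(truth$trait_links)) {
      for (m in seq_len(nrow(truth$trait_links))) {
        link <- truth$trait_links[m, ]
        f <- numeric(ns)
        for (sx in unique(cohort$sex)) {
          idx <- which(cohort$sex == sx)
          z <- as.numeric(scale(cohort[[link$trait]][idx]))
          f[idx] <- link$sign * config$module_trait_r * z +
            sqrt(1 - config$module_trait_r^2) * rnorm(length(idx))
        }
        drivers[, m] <- f
        rows <- truth$module_membership$window[
          truth$module_membership$module_id == link$module_id]
        log_mu[rows, ] <- log_mu[rows, ] +
          config$module_loading * matrix(f, length(rows), ns, byrow = TRUE)
      }
    }
    mu <- exp(log_mu)
    counts <- if (config$dispersion == 0) {
      matrix(rpois(nw * ns, mu), nw, ns)
    } else {
      matrix(rnbinom(nw * ns, size = 1 / config$dispersion, mu = mu), nw, ns)
    }
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(windows$window, cohort$id)
    list(counts = counts, lib_sizes = colSums(counts),
         module_drivers = drivers)
  })
}

#' Generate a complete synthetic twin methylation study
#'
#' Runs the full generator: reference genome and CpG-annotated window
#' grid, toy gene annotation, twin cohort trait table, planted truth
#' (DMRs and latent modules) and the window count matrix.
#'
#' @param config A [sim_config()].
#' @return A `twin_study` object: list with elements `config`,
#'   `reference`, `windows`, `genes`, `cohort`, `truth`, `counts`,
#'   `lib_sizes`, `module_drivers`.
#' @examples
#' study <- simulate_study(sim_config(n_pairs_per_sex = 4,
#'                                    n_chromosomes = 1,
#'                                    chrom_length_bp = 2e5,
#'                                    n_planted_dmrs = 2,
#'                                    n_latent_modules = 0))
#' dim(study$counts)
#' @export
simulate_study <- function(config = sim_config()) {
  ref <- simulate_reference(config)
  genes <- simulate_genes(config)
  cohort <- simulate_cohort(config)
  truth <- simulate_truth(config, ref$windows)
  cnt <- simulate_counts(config, cohort, truth, ref$windows)
  structure(list(
    config = config,
    reference = ref$reference,
    windows = ref$windows,
    genes = genes,
    cohort = cohort,
    truth = truth,
    counts = cnt$counts,
    lib_sizes = cnt$lib_sizes,
    module_drivers = cnt$module_drivers
  ), class = "twin_study")
}

#' @export
print.twin_study <- function(x, ...) {
  cat("<twin_study>\n")
  print(x$config)
  cat(sprintf("  %d samples x %d windows; %d planted DMRs, %d latent modules\n",
              ncol(x$counts), nrow(x$counts), nrow(x$truth$planted_dmrs),
              nrow(x$truth$trait_links)))
  invisible(x)
}
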