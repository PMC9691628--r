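#' Simulation configuration for a synthetic twin methylation study
#'
#' Defines the full parameterisation of the synthetic study generator:
#' cohort size, genome geometry, negative-binomial count model, planted
#' differentially methylated regions (DMRs) and latent trait-correlated
#' window modules. Counts for sample \eqn{s} and window \eqn{w} are drawn
#' from a negative binomial with mean
#' \eqn{\mu_w \exp(\mathrm{pair}_s + \Delta_{ws} + a f_{ms})} and
#' variance \eqn{\mu + \phi \mu^2}; \eqn{\phi = 0} is the Poisson limit.
#'
#' @param n_pairs_per_sex Number of monozygotic twin pairs per sex.
#' @param n_chromosomes Number of synthetic chromosomes.
#' @param chrom_length_bp Length of each chromosome in bp; must be a
#'   multiple of `window_size_bp`.
#' @param window_size_bp Width of the genomic windows (bp). The analysis
#'   grid defaults to 1000 bp windows.
#' @param mean_depth Expected read count per window at average CpG density.
#' @param dispersion Negative-binomial dispersion \eqn{\phi \ge 0}
#'   (`Var = mu + phi * mu^2`); 0 gives Poisson counts.
#' @param pair_effect_sd Standard deviation of the shared within-pair
#'   log-baseline. This creates twin-pair correlation that the downstream
#'   unpaired window test deliberately does not model.
#' @param lib_size_range Half-width of the uniform relative variation in
#'   per-sample sequencing depth (0.3 means library sizes vary +/- 30%).
#' @param n_planted_dmrs Number of planted DMRs.
#' @param dmr_span_windows Integer range (length 2) of planted DMR spans in
#'   windows.
#' @param dmr_log2fc Absolute log2 fold change (high over low discordance
#'   arm) planted in DMR windows; the sign is randomised per DMR.
#' @param dmr_traits Character vector of traits the planted DMRs respond
#'   to, cycled over DMRs; subset of `c("pa", "walkability", "bmi")`.
#' @param n_latent_modules Number of latent trait-correlated window modules.
#' @param module_size_windows Windows per latent module.
#' @param module_trait_r Target Pearson correlation between each module's
#'   latent driver and its linked trait, in `[0, 1]`.
#' @param module_loading Multiplicative log-scale loading of module windows
#'   on the latent driver; controls within-module window correlation.
#' @param module_traits Trait columns the latent modules are linked to,
#'   cycled over modules.
#' @param fraction_discordant Named numeric vector with elements `pa`,
#'   `walkability` and `bmi`: the fraction of pairs made discordant for
#'   each trait.
#' @param low_mapping_fraction Fraction of pairs in which one member is
#'   given a sub-70% mapping rate (to exercise sample QC).
#' @param seed Integer RNG seed; fixes every output of the generator.
#'
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(n_pairs_per_sex = 4, n_chromosomes = 2,
#'                   chrom_length_bp = 50000)
#' cfg$window_size_bp
#' @export
sim_config <- function(n_pairs_per_sex = 8,
                       n_chromosomes = 4,
                       chrom_length_bp = 1.25e6,
                       window_size_bp = 1000,
                       mean_depth = 30,
                       dispersion = 0.2,
                       pair_effect_sd = 0.3,
                       lib_size_range = 0.3,
                       n_planted_dmrs = 20,
                       dmr_span_windows = c(1L, 5L),
                       dmr_log2fc = 2,
                       dmr_traits = c("pa", "walkability", "bmi"),
                       n_latent_modules = 3,
                       module_size_windows = 50,
                       module_trait_r = 0.7,
                       module_loading = 0.8,
                       module_traits = c("mvpa_min_week", "walkability_score", "bmi"),
                       fraction_discordant = c(pa = 0.5, walkability = 0.5, bmi = 0.5),
                       low_mapping_fraction = 0,
                       seed = 1L) {
  assert_scalar_number(n_pairs_per_sex, "n_pairs_per_sex", min = 1)
  assert_scalar_number(n_chromosomes, "n_chromosomes", min = 1)
  assert_scalar_number(window_size_bp, "window_size_bp", min = 1)
  assert_scalar_number(chrom_length_bp, "chrom_length_bp", min = window_size_bp)
  if (chrom_length_bp %% window_size_bp != 0) {
    abort("`chrom_length_bp` must be a multiple of `window_size_bp`")
  }
  assert_scalar_number(mean_depth, "mean_depth", min = 0)
  assert_scalar_number(dispersion, "dispersion", min = 0)
  assert_scalar_number(pair_effect_sd, "pair_effect_sd", min = 0)
  assert_scalar_number(lib_size_range, "lib_size_range", min = 0, max = 0.99)
  assert_scalar_number(n_planted_dmrs, "n_planted_dmrs", min = 0)
  if (length(dmr_span_windows) != 2L || any(dmr_span_windows < 1) ||
      dmr_span_windows[1] > dmr_span_windows[2]) {
    abort("`dmr_span_windows` must be an increasing integer range of length 2")
  }
  assert_scalar_number(dmr_log2fc, "dmr_log2fc")
  dmr_traits <- match.arg(dmr_traits, c("pa", "walkability", "bmi"),
                          several.ok = TRUE)
  assert_scalar_number(n_latent_modules, "n_latent_modules", min = 0)
  assert_scalar_number(module_size_windows, "module_size_windows", min = 2)
  assert_scalar_number(module_trait_r, "module_trait_r", min = 0, max = 1)
  assert_scalar_number(module_loading, "module_loading", min = 0)
  stopifnot(all(c("pa", "walkability", "bmi") %in% names(fraction_discordant)))
  if (any(fraction_discordant < 0 | fraction_discordant > 1)) {
    abort("`fraction_discordant` entries must lie in [0, 1]")
  }
  assert_scalar_number(low_mapping_fraction, "low_mapping_fraction",
                       min = 0, max = 1)
  assert_scalar_number(seed, "seed")

  structure(list(
    n_pairs_per_sex = as.integer(n_pairs_per_sex),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp),
    window_size_bp = as.integer(window_size_bp),
    mean_depth = mean_depth,
    dispersion = dispersion,
    pair_effect_sd = pair_effect_sd,
    lib_size_range = lib_size_range,
    n_planted_dmrs = as.integer(n_planted_dmrs),
    dmr_span_windows = as.integer(dmr_span_windows),
    dmr_log2fc = dmr_log2fc,
    dmr_traits = dmr_traits,
    n_latent_modules = as.integer(n_latent_modules),
    module_size_windows = as.integer(module_size_windows),
    module_trait_r = module_trait_r,
    module_loading = module_loading,
    module_traits = module_traits,
    fraction_discordant = fraction_discordant[c("pa", "walkability", "bmi")],
    low_mapping_fraction = low_mapping_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cohort : %d MZ pairs per sex\n", x$n_pairs_per_sex))
  cat(sprintf("  genome : %d chromosome(s) x %s bp, %d bp windows (%d windows)\n",
              x$n_chromosomes, format(x$chrom_length_bp, big.mark = ","),
              x$window_size_bp,
              x$n_chromosomes * (x$chrom_length_bp %/% x$window_size_bp)))
  cat(sprintf("  counts : NB mean depth %.1f, dispersion %.3g, pair SD %.2f\n",
              x$mean_depth, x$dispersion, x$pair_effect_sd))
  cat(sprintf("  truth  : %d planted DMRs (|log2FC| %.2g), %d latent modules (r %.2f)\n",
              x$n_planted_dmrs, x$dmr_log2fc, x$n_latent_modules,
              x$module_trait_r))
  cat(sprintf("  seed   : %d\n", x$seed))
  invisible(x)
}

#' Weighted correlation network configuration
#'
#' Parameters of the correlation-network stage. Defaults follow the usual
#' settings for unsigned topological-overlap module detection on
#' methylation window profiles: soft-threshold power 6 for female and 9
#' for male samples, minimum module size 30, eigengene merge cut height
#' 0.25 and a 15,000-window block cap.
#'
#' @param power Soft-threshold exponent \eqn{\beta \ge 1} applied to
#'   `|cor|`. See [default_network_power()] for the per-sex defaults.
#' @param min_module_size Smallest window count admitted as a module;
#'   smaller clusters fall into the grey (unassigned) bucket.
#' @param merge_cut_height Eigengene dissimilarity (`1 - cor`) below which
#'   modules are merged, in (0, 1).
#' @param max_block_size Maximum windows handled in one block; larger
#'   inputs are pre-partitioned and module detection runs per block.
#' @param top_n Number of top-mean-RPKM windows admitted to the network.
#' @param cut_fraction Fraction of the maximum dendrogram merge height at
#'   which the average-linkage tree is cut during module detection.
#' @param min_kme Module-membership floor: windows whose correlation with
#'   their own module eigengene falls below this value are released to
#'   grey after detection (0 disables the cleanup).
#'
#' @return A `network_config` list.
#' @export
network_config <- function(power = 6,
                           min_module_size = 30,
                           merge_cut_height = 0.25,
                           max_block_size = 15000,
                           top_n = 100000,
                           cut_fraction = 0.99,
                           min_kme = 0.5) {
  assert_scalar_number(power, "power", min = 1)
  assert_scalar_number(min_module_size, "min_module_size", min = 2)
  assert_scalar_number(merge_cut_height, "merge_cut_height")
  if (merge_cut_height <= 0 || merge_cut_height >= 1) {
    abort("`merge_cut_height` must lie strictly between 0 and 1")
  }
  assert_scalar_number(max_block_size, "max_block_size", min = 2)
  assert_scalar_number(top_n, "top_n", min = 1)
  assert_scalar_number(cut_fraction, "cut_fraction", min = 0, max = 1)
  assert_scalar_number(min_kme, "min_kme", min = 0, max = 1)
  structure(list(
    power = power,
    min_module_size = as.integer(min_module_size),
    merge_cut_height = merge_cut_height,
    max_block_size = as.integer(max_block_size),
    top_n = as.integer(top_n),
    cut_fraction = cut_fraction,
    min_kme = min_kme
  ), class = "network_config")
}

#' Default soft-threshold power by sex
#'
#' The network stage uses power 6 for female and 9 for male sample sets.
#'
#' @param sex `"F"` or `"M"`.
#' @return A single number.
#' @export
default_network_power <- function(sex) {
  sex <- match.arg(sex, c("F", "M"))
  if (sex == "F") 6 else 9
}

#' Read a simulation configuration from a YAML file
#'
#' Any key of [sim_config()] may appear; missing keys take the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading YAML configs requires the 'yaml' package")
  }
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$fraction_discordant)) {
    vals$fraction_discordant <- unlist(vals$fraction_discordant)
  }
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, vals)
}
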