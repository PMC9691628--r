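# broom-style tidy()/glance() methods for the package's result objects.

#' @describeIn call_dmrs Tidy a DMR set into a plain tibble.
#' @param x A `dmr_set`.
#' @param ... Unused.
#' @method tidy dmr_set
#' @export
tidy.dmr_set <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "dmr_set")
  attr(out, "params") <- NULL
  as_tibble(out)
}

#' @describeIn call_dmrs One-row summary: DMR counts and calling
#'   parameters.
#' @method glance dmr_set
#' @export
glance.dmr_set <- function(x, ...) {
  params <- attr(x, "params")
  bind_cols(
    classify_multi_window(x),
    tibble(min_p = if (nrow(x)) min(x$min_p) else NA_real_,
           p_seed = params$p_seed, p_extend = params$p_extend,
           gap_bp = params$gap_bp)
  )
}

#' @describeIn test_windows Per-window results as a plain tibble.
#' @param x A `window_test`.
#' @param ... Unused.
#' @method tidy window_test
#' @export
tidy.window_test <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "window_test")
  as_tibble(out)
}

#' @describeIn test_windows One-row test summary (windows tested,
#'   dispersion, significance tallies).
#' @method glance window_test
#' @export
glance.window_test <- function(x, ...) {
  tibble(
    n_windows = nrow(x),
    dispersion = attr(x, "dispersion"),
    n_p_lt_1e4 = sum(x$p_value < 1e-4),
    n_q_lt_0.1 = sum(x$q_value < 0.1),
    min_p = min(x$p_value)
  )
}

#' @describeIn wcna_modules Window-to-module assignment tibble.
#' @param x A `wcna_fit`.
#' @param ... Unused.
#' @method tidy wcna_fit
#' @export
tidy.wcna_fit <- function(x, ...) as_tibble(x$assignment)

#' @describeIn wcna_modules One-row fit summary.
#' @method glance wcna_fit
#' @export
glance.wcna_fit <- function(x, ...) {
  mods <- setdiff(unique(x$assignment$module), "grey")
  tibble(
    n_windows = nrow(x$assignment),
    n_modules = length(mods),
    n_grey = sum(x$assignment$module == "grey"),
    largest_module = if (length(mods))
      max(table(x$assignment$module[x$assignment$module != "grey"]))
    else 0L,
    power = x$config$power,
    n_blocks = x$n_blocks
  )
}

#' @describeIn module_trait_cor All module-trait cells as a long tibble
#'   (`module`, `trait`, `r`, `p_value`).
#' @param x A `module_trait_cor`.
#' @param ... Unused.
#' @method tidy module_trait_cor
#' @export
tidy.module_trait_cor <- function(x, ...) {
  as_tibble(x$r, rownames = "module") |>
    pivot_longer(-"module", names_to = "trait", values_to = "r") |>
    left_join(as_tibble(x$p, rownames = "module") |>
                pivot_longer(-"module", names_to = "trait",
                             values_to = "p_value"),
              by = c("module", "trait"))
}

#' @describeIn module_trait_cor One-row summary of the correlation
#'   matrix.
#' @method glance module_trait_cor
#' @export
glance.module_trait_cor <- function(x, ...) {
  tibble(
    n_modules = nrow(x$r),
    n_traits = ncol(x$r),
    n_samples = x$n,
    n_significant = sum(x$p < x$p_filter, na.rm = TRUE),
    p_filter = x$p_filter
  )
}

#' @describeIn pca_dmr_features Sample scores as a tibble.
#' @param x A `dmr_pca`.
#' @param ... Unused.
#' @method tidy dmr_pca
#' @export
tidy.dmr_pca <- function(x, ...) x$scores

#' @describeIn pca_dmr_features One-row summary (variance explained,
#'   silhouette of the arms).
#' @method glance dmr_pca
#' @export
glance.dmr_pca <- function(x, ...) {
  tibble(
    pc1_var = x$var_explained[1],
    pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_,
    silhouette = x$silhouette
  )
}

#' @describeIn run_comparison Per-window results of the comparison.
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @method tidy comparison_report
#' @export
tidy.comparison_report <- function(x, ...) tidy(x$results)

#' @describeIn run_comparison One-row comparison summary.
#' @method glance comparison_report
#' @export
glance.comparison_report <- function(x, ...) {
  bind_cols(
    tibble(comparison = x$comparison, sex = x$sex,
           n_samples = nrow(x$groups)),
    classify_multi_window(x$dmrs),
    tibble(dispersion = x$params$dispersion)
  )
}
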