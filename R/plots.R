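# ggplot2 displays for the main result types.

#' Histogram of per-window p-values
#'
#' A flat histogram is the expected picture under the null; an excess in
#' the leftmost bins reflects differential methylation signal.
#'
#' @param results A [test_windows()] result.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_pvalue_histogram <- function(results, bins = 40) {
  ggplot2::ggplot(as_tibble(results), ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey35") +
    ggplot2::labs(x = "window p-value", y = "windows") +
    ggplot2::theme_minimal()
}

#' DMR counts across seed thresholds
#'
#' @param threshold_table Output of [dmr_threshold_table()].
#' @return A ggplot object (all-window vs multiple-window counts per seed
#'   threshold).
#' @export
plot_threshold_table <- function(threshold_table) {
  long <- threshold_table |>
    pivot_longer(c("all_window", "multiple_window"),
                 names_to = "class", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$p_seed),
                                     y = .data$n, fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "seed p-value threshold", y = "DMRs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn call_dmrs CpG-density and length histograms of the called
#'   DMRs.
#' @param object A `dmr_set`.
#' @method autoplot dmr_set
#' @export
autoplot.dmr_set <- function(object, ...) {
  dat <- as_tibble(object) |>
    transmute(`CpG per 100 bp (bin)` = as.numeric(
      if ("cpg_per_100bp" %in% names(object)) round(.data$cpg_per_100bp)
      else NA_real_),
      `length (kb)` = .data$length / 1000) |>
    pivot_longer(everything(), names_to = "feature", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey35") +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = NULL, y = "DMRs") +
    ggplot2::theme_minimal()
}

#' @describeIn module_trait_cor Module-trait correlation heatmap;
#'   cells reaching the significance filter are starred.
#' @param object A `module_trait_cor`.
#' @param ... Unused.
#' @method autoplot module_trait_cor
#' @export
autoplot.module_trait_cor <- function(object, ...) {
  long <- tidy(object) |>
    mutate(label = sprintf("%.2f%s", .data$r,
                           ifelse(.data$p_value < object$p_filter, "*", "")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trait, y = .data$module,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn pca_dmr_features Sample scatter on PC1/PC2 coloured by
#'   discordance arm.
#' @param object A `dmr_pca`.
#' @method autoplot dmr_pca
#' @export
autoplot.dmr_pca <- function(object, ...) {
  ve <- 100 * object$var_explained
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$arm)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", ve[1]),
      y = if (length(ve) > 1) sprintf("PC2 (%.1f%%)", ve[2]) else "PC2") +
    ggplot2::theme_minimal()
}

#' @describeIn wcna_modules Module size bar chart (grey last).
#' @param object A `wcna_fit`.
#' @method autoplot wcna_fit
#' @export
autoplot.wcna_fit <- function(object, ...) {
  sizes <- as_tibble(table(module = object$assignment$module), n = "n") |>
    arrange(.data$module == "grey", desc(.data$n)) |>
    mutate(module = factor(.data$module, levels = .data$module))
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$module, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "windows") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
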