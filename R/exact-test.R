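# Two-group negative-binomial exact test on window counts.
#
# The model for a scaled count is NB with mean mu and variance
# mu + phi * mu^2 (phi = 0 is Poisson). Counts are scaled to a common
# effective library size, summed within each group, and the two group
# sums are compared conditionally on their total: under the null of equal
# per-sample means the total is split between the groups according to the
# ratio of NB-sum probabilities, and the two-sided p-value is the summed
# probability of all splits no more likely than the observed one.

# Conditional two-sided exact p for group sums (sa, sb) from (na, nb)
# samples at dispersion phi, after scaling to a common library size.
# The sum of n iid NB(mu, phi) counts is NB(n * mu, phi / n), i.e. has
# size n / phi; conditioning on T = sa + sb the split distribution uses
# the null mean estimated from the window itself, mu0 = T / (na + nb).
nb_split_p <- function(sa, sb, na, nb, phi) {
  total <- sa + sb
  if (total == 0) return(1)
  a <- 0:total
  if (phi == 0) {
    w <- dbinom(a, total, na / (na + nb), log = FALSE)
  } else {
    mu0 <- total / (na + nb)
    w <- dnbinom(a, size = na / phi, mu = na * mu0) *
      dnbinom(total - a, size = nb / phi, mu = nb * mu0)
  }
  s <- sum(w)
  if (s <= 0) return(1)
  obs <- w[sa + 1]
  min(1, sum(w[w <= obs * (1 + 1e-12)]) / s)
}

scale_to_common_lib <- function(counts, lib_sizes) {
  if (any(lib_sizes <= 0)) abort("library sizes must be positive")
  common <- exp(mean(log(lib_sizes)))
  sweep(counts, 2, common / lib_sizes, "*")
}

#' Estimate the common negative-binomial dispersion
#'
#' Method-of-moments estimate of the dispersion \eqn{\phi} in
#' `Var = mu + phi * mu^2`, pooled across all windows. Counts are first
#' scaled to the geometric-mean library size; the per-window, per-group
#' sample variances in excess of the (scaling-corrected) mean are then
#' pooled against the squared means: `phi = sum(v - c * m) / sum(m^2)`,
#' floored at zero, where `c` corrects for the variance inflation caused
#' by library-size rescaling.
#'
#' @param counts Windows x samples count matrix.
#' @param groups Factor or vector of length `ncol(counts)` with two
#'   levels; each group needs at least two samples.
#' @param lib_sizes Per-sample library sizes (default: column sums).
#' @return A single non-negative dispersion estimate.
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       lib_sizes = colSums(counts)) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2L)) {
    abort(paste0("each group needs >= 2 samples to estimate dispersion; ",
                 "supply `dispersion` explicitly for single-sample groups"))
  }
  y <- scale_to_common_lib(counts, lib_sizes)
  common <- exp(mean(log(lib_sizes)))
  num <- 0
  den <- 0
  for (g in levels(groups)) {
    yg <- y[, groups == g, drop = FALSE]
    m <- rowMeans(yg)
    v <- apply(yg, 1, var)
    # scaled counts have variance c * mu + phi * mu^2 with
    # c = mean(common / lib) over the group's samples
    cg <- mean(common / lib_sizes[groups == g])
    num <- num + sum(v - cg * m)
    den <- den + sum(m^2)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

#' Negative-binomial exact test for one window
#'
#' Tests equality of mean methylation coverage between two sample groups
#' for a single genomic window. Per-sample counts are scaled to the
#' common (geometric-mean) library size, summed per group and compared by
#' the conditional exact test described in [test_windows()]. The log2
#' fold change is computed from the normalised group means with a 0.5
#' pseudo-count, oriented as group B over group A.
#'
#' @param counts_a,counts_b Per-sample counts for the two groups.
#' @param phi Dispersion (`>= 0`); 0 gives the Poisson/binomial limit.
#' @param lib_a,lib_b Per-sample library sizes (default: all equal).
#' @return A list with `p_value`, `log2fc`, `mean_a`, `mean_b` (normalised
#'   group means) and the scaled group sums `sum_a`, `sum_b`.
#' @examples
#' nb_exact_test(c(20, 20), c(2, 3), phi = 0.1)
#' @export
nb_exact_test <- function(counts_a, counts_b, phi, lib_a = NULL, lib_b = NULL) {
  if (any(c(counts_a, counts_b) < 0)) abort("counts must be non-negative")
  if (phi < 0) abort("`phi` must be non-negative")
  na <- length(counts_a)
  nb <- length(counts_b)
  libs <- c(lib_a %||% rep(1, na), lib_b %||% rep(1, nb))
  y <- scale_to_common_lib(matrix(c(counts_a, counts_b), nrow = 1), libs)
  sa <- round(sum(y[seq_len(na)]))
  sb <- round(sum(y[na + seq_len(nb)]))
  mean_a <- sa / na
  mean_b <- sb / nb
  list(
    p_value = nb_split_p(sa, sb, na, nb, phi),
    log2fc = log2((mean_b + 0.5) / (mean_a + 0.5)),
    mean_a = mean_a, mean_b = mean_b, sum_a = sa, sum_b = sb
  )
}

#' Per-window two-group exact tests with FDR
#'
#' Runs the negative-binomial exact test on every window of a count
#' matrix: counts are scaled to the common effective library size,
#' group-summed, and each window's total is split-enumerated to give a
#' two-sided conditional p-value; q-values are Benjamini-Hochberg across
#' all tested windows. Degenerate windows (total count 0) get `p = 1`,
#' `log2fc = 0` and are never dropped.
#'
#' @param counts Windows x samples count matrix (row names are window
#'   indices).
#' @param groups Two-level factor/vector over the columns; the first level
#'   is group A (reference), the second group B. `log2fc > 0` means
#'   higher coverage in group B.
#' @param lib_sizes Per-sample library sizes (default: column sums).
#' @param dispersion Common dispersion; estimated from the data via
#'   [estimate_common_dispersion()] when `NULL`.
#' @return A tibble (class `window_test`) with columns `window`,
#'   `p_value`, `q_value`, `log2fc`, `mean_a`, `mean_b`; the dispersion
#'   used is attached as attribute `"dispersion"`.
#' @export
test_windows <- function(counts, groups, lib_sizes = colSums(counts),
                         dispersion = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) abort("`groups` must have exactly two levels")
  if (length(groups) != ncol(counts)) {
    abort("`groups` must have one entry per sample column")
  }
  phi <- dispersion %||% estimate_common_dispersion(counts, groups, lib_sizes)
  y <- scale_to_common_lib(counts, lib_sizes)
  in_a <- groups == levels(groups)[1]
  na <- sum(in_a)
  nb <- sum(!in_a)
  sa <- unname(round(rowSums(y[, in_a, drop = FALSE])))
  sb <- unname(round(rowSums(y[, !in_a, drop = FALSE])))
  p <- vapply(seq_along(sa), function(i) nb_split_p(sa[i], sb[i], na, nb, phi),
              numeric(1))
  res <- tibble(
    window = as.integer(rownames(counts) %||% seq_len(nrow(counts))),
    p_value = p,
    q_value = bh_fdr(p),
    log2fc = log2((sb / nb + 0.5) / (sa / na + 0.5)),
    mean_a = sa / na,
    mean_b = sb / nb
  )
  attr(res, "dispersion") <- phi
  attr(res, "groups") <- levels(groups)
  class(res) <- c("window_test", class(res))
  res
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment across a vector of p-values
#' (a thin wrapper over [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length; empty input gives empty output.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
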