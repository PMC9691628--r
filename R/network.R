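# Weighted correlation network analysis of methylation window profiles:
# unsigned adjacency, topological overlap, average-linkage module
# detection, module eigengenes, eigengene-based merging and module-trait
# correlation.

module_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
    "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
    "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
    "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
    "darkolivegreen", "darkmagenta")
}

#' Unsigned network adjacency
#'
#' Soft-thresholded adjacency between window profiles:
#' `a_ij = |cor(x_i, x_j)|^power` with unit diagonal. Zero-variance
#' windows cannot be correlated and are removed with a warning.
#'
#' @param profiles Samples x windows numeric matrix (column names are
#'   window ids).
#' @param power Soft-threshold exponent `beta >= 1`.
#' @return A symmetric windows x windows adjacency matrix in `[0, 1]`.
#' @examples
#' x <- matrix(rnorm(30), nrow = 10)
#' range(wcna_adjacency(x, power = 6))
#' @export
wcna_adjacency <- function(profiles, power) {
  if (nrow(profiles) < 3L) abort("need at least 3 samples")
  if (power < 1) abort("`power` must be >= 1")
  sds <- apply(profiles, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("removing %d zero-variance window(s)", sum(sds == 0)))
    profiles <- profiles[, sds > 0, drop = FALSE]
  }
  a <- abs(cor(profiles))^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' The unsigned topological overlap of an adjacency matrix:
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu * a_uj` over `u != i, j` and connectivity
#' `k_i = sum_u a_iu` over `u != i`; `TOM_ii = 1`. Two windows overlap
#' topologically when they share network neighbours, which makes the
#' measure more robust than raw adjacency as a clustering similarity.
#'
#' @param adjacency Symmetric matrix with entries in `[0, 1]` and unit
#'   diagonal.
#' @return The TOM matrix; `1 - tom_similarity(a)` is the clustering
#'   dissimilarity.
#' @export
tom_similarity <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) {
    abort("`adjacency` must be symmetric")
  }
  if (any(adjacency < -1e-12 | adjacency > 1 + 1e-12)) {
    abort("adjacency entries must lie in [0, 1]")
  }
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a                       # sum_u a_iu a_uj, u not in {i, j}
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  pmin(pmax(tom, 0), 1)
}

#' Detect modules by average-linkage clustering of a dissimilarity
#'
#' Clusters windows by average-linkage hierarchical clustering of the
#' topological-overlap dissimilarity, cuts the dendrogram at
#' `cut_fraction` of its maximum merge height, and keeps every resulting
#' cluster with at least `min_module_size` windows as a module; all other
#' windows fall into the grey (unassigned) bucket. Module labels are
#' colour names assigned in decreasing module size; the label strings
#' carry no meaning. With no correlation structure the dendrogram is flat
#' near its top and the cut leaves only singletons, so everything ends up
#' grey.
#'
#' @param dissim Square symmetric dissimilarity matrix (e.g.
#'   `1 - tom_similarity(a)`), with window ids as dimnames.
#' @param min_module_size Minimum module size.
#' @param cut_fraction Fraction of the maximum merge height at which to
#'   cut.
#' @return A tibble `window`, `module` (character; `"grey"` = unassigned).
#' @export
detect_modules <- function(dissim, min_module_size = 30, cut_fraction = 0.99) {
  ids <- colnames(dissim) %||% as.character(seq_len(ncol(dissim)))
  if (ncol(dissim) < min_module_size) {
    warn("fewer windows than `min_module_size`; everything is grey")
    return(tibble(window = ids, module = "grey"))
  }
  tree <- hclust(as.dist(dissim), method = "average")
  cut_h <- cut_fraction * max(tree$height)
  cl <- cutree(tree, h = cut_h)
  label_by_size(cl, ids, min_module_size)
}

# Relabel integer cluster ids as size-ordered colour names, greying out
# clusters below the minimum size.
label_by_size <- function(cl, ids, min_module_size) {
  sizes <- sort(table(cl), decreasing = TRUE)
  keep <- names(sizes)[sizes >= min_module_size]
  pal <- module_palette()
  labels <- setNames(rep("grey", length(sizes)), names(sizes))
  if (length(keep)) {
    labels[keep] <- c(pal, paste0("module", seq_along(keep)))[seq_along(keep)]
  }
  tibble(window = ids, module = unname(labels[as.character(cl)]))
}

#' Module eigengene
#'
#' The first left singular vector of the sample x member matrix after
#' z-scoring each window profile across samples: the dominant sample-space
#' direction of the module, with unit norm and sign fixed so that its mean
#' correlation with the member profiles is non-negative.
#'
#' @param profiles Samples x windows matrix.
#' @param members Window ids (column names) or column indices of the
#'   module.
#' @return Numeric vector over samples (unit norm).
#' @export
module_eigengene <- function(profiles, members) {
  x <- profiles[, members, drop = FALSE]
  if (ncol(x) == 0L) abort("module has no members")
  z <- scale(x)
  z[, attr(z, "scaled:scale") == 0] <- 0
  if (ncol(z) == 1L) {
    e <- as.numeric(z)
    n <- sqrt(sum(e^2))
    return(if (n > 0) e / n else e)
  }
  sv <- svd(z, nu = 1, nv = 0)
  e <- sv$u[, 1]
  cors <- suppressWarnings(cor(e, z))
  if (mean(cors, na.rm = TRUE) < 0) e <- -e
  e
}

# Eigengene matrix (samples x modules) for all non-grey modules.
module_eigengenes <- function(profiles, assignment) {
  mods <- setdiff(unique(assignment$module), "grey")
  if (length(mods) == 0L) {
    return(matrix(numeric(0), nrow = nrow(profiles), ncol = 0))
  }
  me <- vapply(mods, function(m) {
    module_eigengene(profiles, assignment$window[assignment$module == m])
  }, numeric(nrow(profiles)))
  colnames(me) <- mods
  me
}

#' Merge modules with correlated eigengenes
#'
#' Modules whose eigengene dissimilarity `1 - cor` falls below
#' `merge_cut_height` are merged; eigengenes are recomputed after each
#' merge round and merging repeats until a fixed point, so chains of
#' pairwise-similar modules collapse into one. The merged module keeps the
#' label of its largest constituent.
#'
#' @param profiles Samples x windows matrix.
#' @param assignment Module assignment tibble (`window`, `module`).
#' @param merge_cut_height Dissimilarity threshold in (0, 1).
#' @return The merged assignment tibble.
#' @export
merge_modules <- function(profiles, assignment, merge_cut_height = 0.25) {
  repeat {
    mods <- setdiff(unique(assignment$module), "grey")
    if (length(mods) < 2L) break
    me <- module_eigengenes(profiles, assignment)
    diss <- 1 - cor(me)
    close_pairs <- which(diss < merge_cut_height & upper.tri(diss),
                         arr.ind = TRUE)
    if (nrow(close_pairs) == 0L) break
    # merge connected components of the "close" graph in one round
    comp <- seq_along(mods)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (r in seq_len(nrow(close_pairs))) {
      a <- find(close_pairs[r, 1]); b <- find(close_pairs[r, 2])
      if (a != b) comp[max(a, b)] <- min(a, b)
    }
    roots <- vapply(seq_along(mods), find, integer(1))
    sizes <- table(assignment$module)[mods]
    for (root in unique(roots[duplicated(roots) | duplicated(roots, fromLast = TRUE)])) {
      grp <- mods[roots == root]
      label <- grp[which.max(sizes[grp])]
      assignment$module[assignment$module %in% grp] <- label
    }
  }
  assignment
}

#' Module-trait Pearson correlation with Student asymptotic p-values
#'
#' Correlates each module eigengene with each (numeric-coded) trait and
#' attaches the two-sided Student p-value
#' `p = 2 * P(T_{n-2} > |r| sqrt(n-2) / sqrt(1-r^2))`. All samples are
#' treated as independent: twin pairing is deliberately ignored at this
#' stage. The filtered view drops modules and traits without any
#' correlation at `p < p_filter`.
#'
#' @param eigengenes Samples x modules matrix.
#' @param traits Samples x traits data frame or matrix of numeric codes
#'   (rows aligned with `eigengenes`).
#' @param p_filter Significance threshold of the filtered view.
#' @return A `module_trait_cor` object: list with matrices `r` and `p`,
#'   sample size `n`, `p_filter`, and `filtered` (long tibble of the
#'   retained cells).
#' @export
module_trait_cor <- function(eigengenes, traits, p_filter = 0.001) {
  traits <- as.data.frame(traits)
  num <- vapply(traits, is.numeric, logical(1))
  traits <- as.matrix(traits[num])
  n <- nrow(eigengenes)
  if (n < 4L) abort("need at least 4 samples for module-trait correlation")
  if (nrow(traits) != n) abort("`traits` rows must align with samples")
  constant <- apply(traits, 2, function(x) sd(x) == 0 || anyNA(x))
  if (any(constant)) {
    warn(paste0("constant or incomplete trait(s) give NA correlations: ",
                paste(colnames(traits)[constant], collapse = ", ")))
  }
  r <- suppressWarnings(cor(eigengenes, traits))
  p <- cor_pvalue_student(r, n)
  filtered <- tibble()
  if (length(r)) {
    keep_m <- apply(p, 1, function(x) any(x < p_filter, na.rm = TRUE))
    keep_t <- apply(p, 2, function(x) any(x < p_filter, na.rm = TRUE))
    if (any(keep_m) && any(keep_t)) {
      filtered <- as_tibble(r[keep_m, keep_t, drop = FALSE],
                            rownames = "module") |>
        pivot_longer(-"module", names_to = "trait", values_to = "r") |>
        left_join(as_tibble(p[keep_m, keep_t, drop = FALSE],
                            rownames = "module") |>
                    pivot_longer(-"module", names_to = "trait",
                                 values_to = "p_value"),
                  by = c("module", "trait"))
    }
  }
  structure(list(r = r, p = p, n = n, p_filter = p_filter,
                 filtered = filtered),
            class = "module_trait_cor")
}

#' Student-t p-value of a Pearson correlation
#'
#' Two-sided asymptotic p-value for a correlation `r` over `n` independent
#' samples, from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees
#' of freedom.
#'
#' @param r Correlation(s); vector or matrix.
#' @param n Sample size.
#' @return p-values with the shape of `r`.
#' @export
cor_pvalue_student <- function(r, n) {
  t <- abs(r) * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(t, df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  pmin(p, 1)
}

#' @export
print.module_trait_cor <- function(x, ...) {
  cat(sprintf("<module_trait_cor> %d module(s) x %d trait(s), n = %d samples\n",
              nrow(x$r), ncol(x$r), x$n))
  if (nrow(x$filtered)) {
    cat(sprintf("%d correlation(s) at p < %g:\n", nrow(x$filtered), x$p_filter))
    print(x$filtered, n = 10)
  } else {
    cat(sprintf("no correlation reaches p < %g\n", x$p_filter))
  }
  invisible(x)
}

#' Blockwise module detection driver
#'
#' End-to-end module detection for a set of window profiles: unsigned
#' adjacency at the chosen power, topological overlap, average-linkage
#' module detection and eigengene-based merging. Inputs larger than
#' `max_block_size` windows are pre-partitioned into blocks by k-means on
#' their leading right-singular-vector coordinates (deterministic given
#' the seed); detection runs per block and merging then reunites
#' correlated modules across blocks.
#'
#' @param profiles Samples x windows matrix (column names window ids).
#' @param config A [network_config()].
#' @param seed Integer seed controlling the block partition.
#' @return A `wcna_fit` object: list with `assignment` (tibble `window`,
#'   `module`), `eigengenes` (samples x modules matrix), `config`,
#'   `n_blocks`.
#' @export
wcna_modules <- function(profiles, config = network_config(), seed = 1L) {
  sds <- apply(profiles, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("removing %d zero-variance window(s)", sum(sds == 0)))
    profiles <- profiles[, sds > 0, drop = FALSE]
  }
  if (is.null(colnames(profiles))) {
    colnames(profiles) <- as.character(seq_len(ncol(profiles)))
  }
  nw <- ncol(profiles)
  blocks <- if (nw <= config$max_block_size) {
    list(seq_len(nw))
  } else {
    partition_blocks(profiles, config$max_block_size, seed)
  }
  assignment <- map(blocks, function(b) {
    a <- wcna_adjacency(profiles[, b, drop = FALSE], config$power)
    detect_modules(1 - tom_similarity(a),
                   min_module_size = config$min_module_size,
                   cut_fraction = config$cut_fraction)
  }) |> list_rbind()
  # make labels unique across blocks before merging
  if (length(blocks) > 1L) {
    assignment <- assignment |>
      mutate(block = rep(seq_along(blocks), lengths(blocks)),
             module = if_else(.data$module == "grey", "grey",
                              paste0(.data$module, ".", .data$block))) |>
      select(-"block")
  }
  assignment <- kme_filter(profiles, assignment, config$min_kme,
                           config$min_module_size)
  assignment <- merge_modules(profiles, assignment, config$merge_cut_height)
  # final size-ordered colour labels
  mods <- setdiff(unique(assignment$module), "grey")
  if (length(mods)) {
    sizes <- sort(table(assignment$module[assignment$module != "grey"]),
                  decreasing = TRUE)
    pal <- c(module_palette(), paste0("module", seq_along(sizes)))
    relabel <- setNames(pal[seq_along(sizes)], names(sizes))
    assignment$module[assignment$module != "grey"] <-
      unname(relabel[assignment$module[assignment$module != "grey"]])
  }
  assignment <- assignment[match(colnames(profiles), assignment$window), ]
  structure(list(
    assignment = assignment,
    eigengenes = module_eigengenes(profiles, assignment),
    config = config,
    n_blocks = length(blocks)
  ), class = "wcna_fit")
}

# Module-membership cleanup: a window whose correlation with its own
# module eigengene (kME) falls below the floor is released to grey, and
# modules that shrink below the minimum size dissolve entirely. This
# removes the weakly-attached stragglers that a fixed-height dendrogram
# cut accretes onto genuine modules.
kme_filter <- function(profiles, assignment, min_kme, min_module_size) {
  if (min_kme <= 0) return(assignment)
  for (m in setdiff(unique(assignment$module), "grey")) {
    members <- assignment$window[assignment$module == m]
    me <- module_eigengene(profiles, members)
    kme <- suppressWarnings(
      as.numeric(cor(me, profiles[, members, drop = FALSE])))
    drop <- is.na(kme) | abs(kme) < min_kme
    if (any(drop)) {
      assignment$module[assignment$window %in% members[drop]] <- "grey"
    }
    if (sum(assignment$module == m) < min_module_size) {
      assignment$module[assignment$module == m] <- "grey"
    }
  }
  assignment
}

# Deterministic k-means partition of windows into blocks of at most
# `max_block` windows, on the leading singular-vector coordinates.
partition_blocks <- function(profiles, max_block, seed) {
  nw <- ncol(profiles)
  k <- ceiling(nw / max_block)
  d <- min(10L, nrow(profiles) - 1L)
  sv <- svd(scale(profiles), nu = 0, nv = d)
  coords <- sv$v
  cl <- with_seed(child_seed(seed, 97L),
                  kmeans(coords, centers = k, nstart = 5)$cluster)
  blocks <- split(seq_len(nw), cl)
  # k-means does not bound cluster sizes; chop any oversize block
  blocks <- do.call(c, map(blocks, function(b) {
    unname(split(b, ceiling(seq_along(b) / max_block)))
  }))
  unname(map(blocks, as.integer))
}

#' @export
print.wcna_fit <- function(x, ...) {
  sizes <- table(x$assignment$module)
  cat(sprintf("<wcna_fit> %d windows, power %g, %d block(s)\n",
              nrow(x$assignment), x$config$power, x$n_blocks))
  print(sort(sizes, decreasing = TRUE))
  invisible(x)
}
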