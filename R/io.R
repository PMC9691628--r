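# On-disk formats. All interval files use 0-based half-open coordinates
# (BED dialect); the GTF gene annotation is 1-based inclusive on disk and
# converted at the boundary. The counts TSV carries the per-sample
# library sizes in a "#library_sizes" header line.

#' Write a synthetic study to disk
#'
#' Emits the study as plain-text files: `reference.fa`, `windows.bed`
#' (name = window index, score = CpG count), `genes.gtf`, `counts.tsv`,
#' `traits.tsv`, `truth_dmrs.tsv`, `truth_modules.tsv`,
#' `truth_links.json` and `codebook.json` (integer codings of the
#' categorical columns).
#'
#' @param study A `twin_study`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(study$reference, p("reference.fa"))
  write_windows_bed(study$windows, p("windows.bed"))
  write_genes_gtf(study$genes, p("genes.gtf"))
  write_counts_tsv(study$counts, study$lib_sizes, p("counts.tsv"))
  readr::write_tsv(study$cohort, p("traits.tsv"))
  readr::write_tsv(study$truth$planted_dmrs, p("truth_dmrs.tsv"))
  readr::write_tsv(study$truth$module_membership, p("truth_modules.tsv"))
  jsonlite::write_json(study$truth$trait_links, p("truth_links.json"),
                       digits = NA)
  jsonlite::write_json(
    list(sex = list(F = "female", M = "male"),
         coordinates = "0-based half-open (BED) in all interval files"),
    p("codebook.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_study
#' @param path File path.
#' @param windows Window grid tibble (with optional `cpg` column).
#' @export
write_windows_bed <- function(windows, path) {
  gr <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(windows$start + 1L, windows$end),
    name = as.character(windows$window),
    score = if ("cpg" %in% names(windows)) windows$cpg else 0L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a window grid BED file
#'
#' @param path BED file written by [write_windows_bed()].
#' @return A window grid tibble (`window`, `chrom`, `start`, `end`,
#'   `width`, `short`, `cpg`).
#' @export
read_windows_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    window = as.integer(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    cpg = as.integer(gr$score)
  ) |> arrange(.data$window)
  out |> mutate(width = .data$end - .data$start,
                short = .data$width < max(.data$width)) |>
    relocate("cpg", .after = "short")
}

#' @rdname write_study
#' @param genes Gene model tibble.
#' @export
write_genes_gtf <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand)
  gr$source <- "twindmr"
  gr$type <- "gene"
  gr$gene_id <- genes$gene_id
  gr$gene_name <- genes$symbol
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a GTF gene annotation
#'
#' Gene features are converted from the on-disk 1-based inclusive
#' coordinates to the package's 0-based half-open convention.
#'
#' @param path GTF file.
#' @return Gene tibble (`gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `strand`).
#' @export
read_genes_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "gene"]
  tibble(
    gene_id = gr$gene_id,
    symbol = if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' @rdname write_study
#' @param counts Windows x samples count matrix.
#' @param lib_sizes Per-sample library sizes.
#' @export
write_counts_tsv <- function(counts, lib_sizes, path) {
  writeLines(paste0("#library_sizes\t",
                    paste(colnames(counts), unname(lib_sizes[colnames(counts)]),
                          sep = "=", collapse = "\t")), path)
  df <- as.data.frame(counts) |> rownames_to_column("window")
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a window counts TSV
#'
#' @param path Counts file written by [write_counts_tsv()].
#' @return A list with `counts` (integer matrix) and `lib_sizes`.
#' @export
read_counts_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#library_sizes")) {
    abort("counts file must start with a '#library_sizes' header line")
  }
  fields <- strsplit(sub("^#library_sizes\t", "", header), "\t")[[1]]
  kv <- strsplit(fields, "=")
  lib_sizes <- setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                        vapply(kv, `[`, "", 1L))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$window
  storage.mode(counts) <- "integer"
  list(counts = counts, lib_sizes = lib_sizes[colnames(counts)])
}

#' Read a participant trait table
#'
#' Validates the header before parsing: `id`, `pair_id`, `sex`,
#' `mvpa_min_week`, `walkability_score` and `bmi` are required.
#'
#' @param path Traits TSV.
#' @return Participant tibble.
#' @export
read_traits_tsv <- function(path) {
  required <- c("id", "pair_id", "sex", "mvpa_min_week",
                "walkability_score", "bmi")
  header <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  missing <- setdiff(required, header)
  if (length(missing)) {
    abort(paste0("traits file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a study back from disk
#'
#' Inverse of [write_study()] for everything needed to re-run the
#' analysis (the simulation config itself is not round-tripped).
#'
#' @param dir Directory written by [write_study()].
#' @return A list with `reference`, `windows`, `genes`, `cohort`,
#'   `counts`, `lib_sizes`, `truth`.
#' @export
read_study <- function(dir) {
  p <- function(f) file.path(dir, f)
  cnt <- read_counts_tsv(p("counts.tsv"))
  list(
    reference = Biostrings::readDNAStringSet(p("reference.fa")),
    windows = read_windows_bed(p("windows.bed")),
    genes = read_genes_gtf(p("genes.gtf")),
    cohort = read_traits_tsv(p("traits.tsv")),
    counts = cnt$counts,
    lib_sizes = cnt$lib_sizes,
    truth = list(
      planted_dmrs = readr::read_tsv(p("truth_dmrs.tsv"),
                                     show_col_types = FALSE),
      module_membership = readr::read_tsv(p("truth_modules.tsv"),
                                          show_col_types = FALSE),
      trait_links = as_tibble(jsonlite::read_json(p("truth_links.json"),
                                                  simplifyVector = TRUE))
    )
  )
}
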