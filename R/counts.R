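#' UMI count matrix for one tumor sample
#'
#' Light container for a genes x cells matrix of UMI counts together with the
#' sample identifier and profiling platform (`"cells"` for whole-cell
#' scRNA-seq of fresh samples, `"nuclei"` for single-nuclei sequencing of
#' frozen samples). Duplicate gene symbols are collapsed by summation and
#' cells with zero total UMI are dropped.
#'
#' @param counts Integer matrix (genes x cells) with gene symbols as rownames
#'   and cell barcodes as colnames.
#' @param sample_id Sample identifier; prefixed to barcodes so that cell ids
#'   are unique across a cohort.
#' @param platform `"cells"` or `"nuclei"`.
#' @return An object of class `sinet_counts` with elements `counts`,
#'   `sample_id`, `platform`.
#' @examples
#' m <- matrix(1L, 3, 2, dimnames = list(paste0("g", 1:3), paste0("c", 1:2)))
#' sinet_counts(m, "S1", "cells")
#' @export
sinet_counts <- function(counts, sample_id, platform = c("cells", "nuclei")) {
  platform <- match.arg(platform)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts))) {
    stop("counts must be integers (UMI counts)", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene symbols as rownames and barcodes as colnames",
         call. = FALSE)
  }
  # collapse duplicate gene symbols by summation
  if (anyDuplicated(rownames(counts))) {
    counts <- rowsum(counts, group = rownames(counts), reorder = FALSE)
    storage.mode(counts) <- "integer"
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate cell barcodes within sample ", sample_id, call. = FALSE)
  }
  # prefix barcodes with the sample id so ids are cohort-unique
  pref <- paste0(sample_id, "_")
  no_pref <- !startsWith(colnames(counts), pref)
  colnames(counts)[no_pref] <- paste0(pref, colnames(counts)[no_pref])
  empty <- colSums(counts) == 0L
  if (any(empty)) {
    message(sum(empty), " empty cell(s) (zero total UMI) dropped from ",
            sample_id)
    counts <- counts[, !empty, drop = FALSE]
  }
  structure(
    list(counts = counts, sample_id = sample_id, platform = platform),
    class = "sinet_counts"
  )
}

#' @export
print.sinet_counts <- function(x, ...) {
  cat(sprintf("<sinet_counts> %s (%s): %d genes x %d cells\n",
              x$sample_id, x$platform, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.sinet_counts <- function(x) dim(x$counts)

#' Read a UMI count matrix
#'
#' Reads either a 10x-style MTX triplet directory (`matrix.mtx` plus
#' `features.tsv`/`genes.tsv` and `barcodes.tsv`, optionally gzipped) or a
#' dense tab-separated table with gene symbols in the first column and a
#' header row of barcodes.
#'
#' @param path Directory containing an MTX triplet, or path to a dense TSV.
#' @inheritParams sinet_counts
#' @return A [sinet_counts] object.
#' @export
read_counts <- function(path, platform = c("cells", "nuclei"), sample_id) {
  platform <- match.arg(platform)
  if (!file.exists(path)) {
    stop("no such file or directory: ", path, call. = FALSE)
  }
  if (dir.exists(path)) {
    counts <- read_mtx_dir(path)
  } else {
    counts <- read_dense_tsv(path)
  }
  sinet_counts(counts, sample_id = sample_id, platform = platform)
}

read_mtx_dir <- function(dir) {
  pick <- function(stem) {
    cand <- file.path(dir, c(stem, paste0(stem, ".gz")))
    cand <- cand[file.exists(cand)]
    if (!length(cand)) stop("missing ", stem, " in ", dir, call. = FALSE)
    cand[[1]]
  }
  mtx <- pick("matrix.mtx")
  feat <- tryCatch(pick("features.tsv"), error = function(e) pick("genes.tsv"))
  bc <- pick("barcodes.tsv")
  m <- as.matrix(Matrix::readMM(mtx))
  if (any(m != round(m))) {
    stop("non-integer entries in ", mtx, call. = FALSE)
  }
  features <- readr::read_tsv(feat, col_names = FALSE, show_col_types = FALSE,
                              progress = FALSE)
  barcodes <- readr::read_tsv(bc, col_names = FALSE, show_col_types = FALSE,
                              progress = FALSE)
  # features files carry id in col 1 and symbol in col 2 when both exist
  sym_col <- if (ncol(features) >= 2) 2L else 1L
  rownames(m) <- as.character(features[[sym_col]])
  colnames(m) <- as.character(barcodes[[1]])
  m
}

read_dense_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m) || any(m != round(m))) {
    stop("non-integer entries in ", path, call. = FALSE)
  }
  rownames(m) <- genes
  m
}

#' Write a count matrix
#'
#' Writes a [sinet_counts] object either as a 10x-style MTX triplet directory
#' or as a dense TSV; [read_counts()] round-trips both formats exactly.
#'
#' @param x A [sinet_counts] object.
#' @param path Output directory (`format = "mtx"`) or file (`format = "tsv"`).
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    readr::write_tsv(
      tibble::tibble(id = rownames(x$counts), symbol = rownames(x$counts)),
      file.path(path, "features.tsv"), col_names = FALSE)
    readr::write_tsv(tibble::tibble(bc = colnames(x$counts)),
                     file.path(path, "barcodes.tsv"), col_names = FALSE)
  } else {
    tab <- tibble::as_tibble(x$counts, rownames = "gene")
    readr::write_tsv(tab, path)
  }
  invisible(path)
}

#' Quality-control filter on detected genes per cell
#'
#' Removes low-quality cells by the number of detected genes (counts > 0),
#' with a platform-specific threshold: nuclei require at least
#' `min_genes_nuclei` (default 1000) detected genes, whole cells at least
#' `min_genes_cells` (default 700, lenient enough to retain lymphocytes).
#'
#' @param x A [sinet_counts] object.
#' @param config A [sinet_config] object.
#' @return A filtered [sinet_counts]; the numbers retained/removed are
#'   reported via `message()` and stored in attribute `"qc"`.
#' @export
qc_filter_cells <- function(x, config = sinet_config()) {
  config <- as_sinet_config(config)
  thr <- switch(x$platform,
                nuclei = config$min_genes_nuclei,
                cells = config$min_genes_cells)
  detected <- colSums(x$counts > 0L)
  keep <- detected >= thr
  if (!any(keep)) {
    stop("empty sample: all ", length(keep), " cells of ", x$sample_id,
         " fall below the QC threshold of ", thr, " detected genes",
         call. = FALSE)
  }
  message(x$sample_id, ": retained ", sum(keep), " of ", length(keep),
          " cells (threshold ", thr, " detected genes, platform ",
          x$platform, ")")
  out <- x
  out$counts <- x$counts[, keep, drop = FALSE]
  attr(out, "qc") <- tibble::tibble(
    sample_id = x$sample_id, platform = x$platform, threshold = thr,
    n_in = length(keep), n_retained = sum(keep), n_removed = sum(!keep))
  out
}
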