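#' Read signature gene sets from a two-column TSV
#'
#' Signature fixtures (cell-type markers, cell-cycle phase gene lists, the
#' germinal-center program, meta-programs) are stored as a two-column
#' tab-separated file with columns `set_name` and `gene`.
#'
#' @param path TSV with columns `set_name`, `gene`.
#' @return Named list of character vectors (one per set, unique genes).
#' @export
read_signatures <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2) stop("signature file needs columns set_name, gene",
                          call. = FALSE)
  sets <- split(as.character(tab[[2]]), as.character(tab[[1]]))
  lapply(sets, unique)
}

check_signature <- function(genes, name = "signature") {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("signature '", name, "' is empty", call. = FALSE)
  genes
}

#' Built-in signature fixtures
#'
#' Returns the signature sets shipped with the package: canonical cell-type
#' marker genes for the eight SiNET cell types (NE, T, B/plasma, macrophage,
#' fibroblast, endothelial, epithelial, NK) and canonical G1/S and G2/M
#' cell-cycle gene lists. These serve real-data analyses; synthetic-cohort
#' analyses use the generator's ground-truth sets
#' (see [truth_signatures()]).
#'
#' @param which `"markers"` or `"cell_cycle"`.
#' @return Named list of character vectors.
#' @export
sinet_signatures <- function(which = c("markers", "cell_cycle")) {
  which <- match.arg(which)
  fn <- switch(which, markers = "celltype_markers.tsv",
               cell_cycle = "cell_cycle_genes.tsv")
  read_signatures(system.file("extdata", fn, package = "sinetscape",
                              mustWork = TRUE))
}

#' Score cells for a signature
#'
#' The score of a cell is the mean centered log2 expression of the signature
#' genes present in the (filtered) matrix. The same operator is used for
#' cell-type markers, cell-cycle programs, the germinal-center program and
#' meta-programs. Because expression is centered within the sample, scores of
#' any signature average to ~0 over all cells of a sample.
#'
#' @param x A centered `sinet_norm`.
#' @param genes Character vector of signature genes.
#' @param name Signature name carried into the output.
#' @return Tibble with columns `sample_id`, `cell_id`, `signature`, `score`,
#'   and attribute `"n_genes_used"`.
#' @export
score_signature <- function(x, genes, name = "signature") {
  stopifnot(inherits(x, "sinet_norm"))
  if (!x$centered) {
    stop("score_signature() expects centered values", call. = FALSE)
  }
  genes <- check_signature(genes, name)
  present <- intersect(genes, rownames(x$values))
  if (!length(present)) {
    stop("signature '", name, "' has no genes in the filtered matrix of ",
         x$sample_id, call. = FALSE)
  }
  lost <- length(genes) - length(present)
  if (lost > 0) {
    message("signature '", name, "': ", lost, "/", length(genes),
            " genes absent from the filtered matrix of ", x$sample_id)
  }
  score <- colMeans(x$values[present, , drop = FALSE])
  out <- tibble::tibble(
    sample_id = x$sample_id,
    cell_id = colnames(x$values),
    signature = name,
    score = unname(score)
  )
  attr(out, "n_genes_used") <- length(present)
  out
}

#' Score cells for several signatures at once
#'
#' @param x A centered `sinet_norm`.
#' @param sets Named list of gene vectors.
#' @param on_missing `"error"` propagates the zero-overlap error from
#'   [score_signature()]; `"skip"` drops such signatures with a warning
#'   (useful when a cell type is absent from a sample and its markers did not
#'   survive the expression filter).
#' @return Long tibble of per-cell scores.
#' @export
score_signatures <- function(x, sets, on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  stopifnot(is.list(sets), !is.null(names(sets)))
  res <- purrr::imap(sets, function(genes, nm) {
    if (on_missing == "skip") {
      tryCatch(score_signature(x, genes, nm), error = function(e) {
        warning("skipping signature '", nm, "' in ", x$sample_id, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    } else {
      score_signature(x, genes, nm)
    }
  })
  dplyr::bind_rows(res)
}

#' Mean signature scores per group
#'
#' Averages per-cell signature scores over groups of cells (for instance
#' cell type within sample), reproducing group-level contrasts such as the
#' comparison of epithelial and neuronal reference signatures between NE
#' cells of the two subtypes and bona fide epithelial cells.
#'
#' @param scores Long tibble from [score_signature()]/[score_signatures()].
#' @param groups Tibble with columns `cell_id` and `group`.
#' @return Tibble with columns `signature`, `group`, `mean_score`, `n_cells`.
#'   Cells without a group are dropped; empty groups are dropped with a
#'   warning.
#' @export
group_signature_means <- function(scores, groups) {
  stopifnot(all(c("cell_id", "score", "signature") %in% names(scores)),
            all(c("cell_id", "group") %in% names(groups)))
  empty <- setdiff(unique(groups$group),
                   unique(groups$group[groups$cell_id %in% scores$cell_id]))
  if (length(empty)) {
    warning("dropping empty group(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  dplyr::inner_join(scores, groups, by = "cell_id") |>
    dplyr::group_by(.data$signature, .data$group) |>
    dplyr::summarise(mean_score = mean(.data$score),
                     n_cells = dplyr::n(), .groups = "drop")
}
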