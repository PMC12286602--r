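#' Differential expression between two clusters of the same cell type
#'
#' Within-tumor comparison of two clusters annotated as the same cell type
#' (e.g. resting vs proliferating B cells). Fold change is the difference of
#' cluster means in centered log2 units (signed, cluster A minus cluster B);
#' p-values from the configured two-sided test, BH-corrected over all tested
#' genes. A gene is DE when `|log2_fc| > log2(de_min_fc_within)` (fold 3) and
#' `q < de_alpha`.
#'
#' @param x The sample's centered `sinet_norm`.
#' @param clusters Annotation tibble with `cell_id`, `cluster`.
#' @param cluster_a,cluster_b Cluster labels to compare.
#' @param config A [sinet_config].
#' @return Tibble `gene`, `log2_fc`, `p_value`, `q_value`, `is_de`.
#' @export
within_type_de <- function(x, clusters, cluster_a, cluster_b,
                           config = sinet_config()) {
  config <- as_sinet_config(config)
  ids_a <- intersect(clusters$cell_id[clusters$cluster == cluster_a],
                     colnames(x$values))
  ids_b <- intersect(clusters$cell_id[clusters$cluster == cluster_b],
                     colnames(x$values))
  if (length(ids_a) < 10 || length(ids_b) < 10) {
    stop("each cluster needs >= 10 cells (got ", length(ids_a), " and ",
         length(ids_b), ")", call. = FALSE)
  }
  idx_a <- match(ids_a, colnames(x$values))
  idx_b <- match(ids_b, colnames(x$values))
  log2_fc <- rowMeans(x$values[, idx_a, drop = FALSE]) -
    rowMeans(x$values[, idx_b, drop = FALSE])
  p <- row_group_test(x$values, idx_a, idx_b, config$de_test)
  q <- p.adjust(p, method = "BH")
  tibble::tibble(
    gene = rownames(x$values),
    log2_fc = unname(log2_fc), p_value = unname(p), q_value = unname(q),
    is_de = abs(log2_fc) > log2(config$de_min_fc_within) & q < config$de_alpha
  )
}

#' Score cells of one type for meta-programs and cluster them
#'
#' Scores each cell for a set of previously defined meta-program signatures
#' of its cell type and hierarchically clusters the cells on the score matrix
#' (average linkage on correlation distance; deterministic). The
#' cluster-by-program mean table supports interpretation of subpopulations
#' (e.g. pericyte/myofibroblast-like fibroblasts, proliferating B cells).
#'
#' @param x A centered `sinet_norm`.
#' @param cell_ids Cells of the focal type.
#' @param programs Named list of meta-program gene sets (>= 2 that overlap
#'   the matrix for clustering; with a single program the clustering is
#'   skipped with a warning).
#' @param k Number of cell clusters to cut (default 2).
#' @return Object of class `sinet_metaprograms`: list with `scores` (tibble
#'   cell x program), `cell_cluster` (tibble), `cluster_means` (tibble).
#' @export
score_metaprograms <- function(x, cell_ids, programs, k = 2) {
  stopifnot(inherits(x, "sinet_norm"), x$centered)
  cell_ids <- intersect(cell_ids, colnames(x$values))
  if (!length(cell_ids)) stop("no cells to score", call. = FALSE)
  sub <- x
  sub$values <- x$values[, cell_ids, drop = FALSE]
  scores <- score_signatures(sub, programs, on_missing = "skip")
  wide <- tidyr::pivot_wider(scores, id_cols = "cell_id",
                             names_from = "signature",
                             values_from = "score")
  sm <- as.matrix(wide[, -1, drop = FALSE])
  rownames(sm) <- wide$cell_id
  if (ncol(sm) < 2) {
    warning("fewer than two meta-programs overlap the matrix; ",
            "clustering skipped", call. = FALSE)
    cl <- tibble::tibble(cell_id = rownames(sm), cluster = 1L)
  } else {
    dd <- stats::as.dist(1 - cor(t(sm)))
    hc <- hclust(dd, method = "average")
    cl <- tibble::tibble(cell_id = rownames(sm),
                         cluster = as.integer(cutree(hc, k = min(k, nrow(sm)))))
  }
  cm <- dplyr::inner_join(scores, cl, by = "cell_id") |>
    dplyr::group_by(.data$cluster, .data$signature) |>
    dplyr::summarise(mean_score = mean(.data$score), .groups = "drop")
  structure(list(scores = scores, cell_cluster = cl, cluster_means = cm),
            class = "sinet_metaprograms")
}

#' @export
print.sinet_metaprograms <- function(x, ...) {
  cat("<sinet_metaprograms>", length(unique(x$scores$signature)),
      "programs x", length(unique(x$scores$cell_id)), "cells;",
      length(unique(x$cell_cluster$cluster)), "cell clusters\n")
  invisible(x)
}

#' Subtype differential expression within each cell type
#'
#' Compares cells of one type between epithelial-like and neuronal-like
#' tumors. Because the two groups come from disjoint tumors, this analysis
#' runs on UNcentered log2(TPM/10+1) values (per-tumor centering would remove
#' any gene uniformly shifted across a whole tumor - exactly the signal of
#' interest, e.g. a MIF-like cytokine up in every cell type of one subtype).
#' Per the small number of tumors, p-values are intentionally uncorrected and
#' a strict fold-change criterion (fold > 4, i.e. `|log2_fc| > 2`) is applied
#' instead; this is the only stage without FDR correction. The gene universe
#' defaults to the union of genes present in the matrices; pass `genes` to
#' restrict it (e.g. the union of per-sample expression-filtered genes).
#' Values are taken from UNfiltered matrices so that a gene filtered out of
#' one subtype's tumors contributes its true low expression rather than an
#' imputed zero - zero-filling would fabricate subtype differences for genes
#' near the filter boundary.
#'
#' @param norms_uncentered Named list of uncentered, unfiltered `sinet_norm`
#'   objects.
#' @param genes Optional gene universe to test.
#' @param annotations Cohort annotation tibble.
#' @param subtype_calls Tibble from [call_subtypes()] with `profile_id` =
#'   sample id.
#' @param config A [sinet_config].
#' @param min_cells Minimum cells per subtype within a cell type (default 20);
#'   cell types failing it are skipped with a warning.
#' @return Tibble `gene`, `cell_type`, `log2_fc`
#'   (epithelial_like - neuronal_like), `p_value`, `is_de`.
#' @export
subtype_de_per_celltype <- function(norms_uncentered, annotations,
                                    subtype_calls,
                                    config = sinet_config(),
                                    min_cells = 20,
                                    genes = NULL) {
  config <- as_sinet_config(config)
  if (any(vapply(norms_uncentered, function(n) n$centered, logical(1)))) {
    stop("subtype DE requires uncentered matrices", call. = FALSE)
  }
  subtype_of <- setNames(subtype_calls$subtype, subtype_calls$profile_id)
  ann <- annotations |>
    dplyr::filter(.data$sample_id %in% names(subtype_of)) |>
    dplyr::mutate(subtype = subtype_of[.data$sample_id])
  if (is.null(genes)) {
    genes <- unique(unlist(lapply(norms_uncentered,
                                  function(n) rownames(n$values))))
  }
  types <- setdiff(unique(ann$cell_type), "Unknown")
  res <- purrr::map(types, function(ct) {
    ids_e <- ann$cell_id[ann$cell_type == ct & ann$subtype == "epithelial_like"]
    ids_n <- ann$cell_id[ann$cell_type == ct & ann$subtype == "neuronal_like"]
    mat <- assemble_cells(norms_uncentered, genes, c(ids_e, ids_n))
    ids_e <- intersect(ids_e, colnames(mat))
    ids_n <- intersect(ids_n, colnames(mat))
    if (length(ids_e) < min_cells || length(ids_n) < min_cells) {
      warning("cell type ", ct, ": a subtype has < ", min_cells,
              " cells; skipped", call. = FALSE)
      return(NULL)
    }
    idx_e <- match(ids_e, colnames(mat))
    idx_n <- match(ids_n, colnames(mat))
    log2_fc <- rowMeans(mat[, idx_e, drop = FALSE]) -
      rowMeans(mat[, idx_n, drop = FALSE])
    p <- row_group_test(mat, idx_e, idx_n, config$de_test)
    tibble::tibble(
      gene = rownames(mat), cell_type = ct,
      log2_fc = unname(log2_fc), p_value = unname(p),
      is_de = abs(log2_fc) > log2(config$de_min_fc_subtype) &
        p < config$de_alpha)
  })
  dplyr::bind_rows(res) |>
    dplyr::arrange(dplyr::desc(.data$log2_fc))
}

# genes x cells matrix over several samples; a gene filtered out of a sample's
# matrix is set to 0 there (log2(TPM/10+1) of an undetected gene)
assemble_cells <- function(norms, genes, cell_ids) {
  mats <- lapply(norms, function(n) {
    keep <- intersect(cell_ids, colnames(n$values))
    if (!length(keep)) return(NULL)
    m <- matrix(0, nrow = length(genes), ncol = length(keep),
                dimnames = list(genes, keep))
    shared <- intersect(genes, rownames(n$values))
    m[shared, ] <- n$values[shared, keep, drop = FALSE]
    m
  })
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (!length(mats)) {
    return(matrix(numeric(), nrow = length(genes), ncol = 0,
                  dimnames = list(genes, NULL)))
  }
  do.call(cbind, mats)
}

#' Bulk marker scores and their correlation with the cell-cycle score
#'
#' For a bulk RNA-seq dataset (genes x samples TPM), computes per-sample
#' scores as the mean `log2(TPM + 1)` of each marker set (absolute
#' expression, not centered) and of the cell-cycle gene set, excludes outlier
#' profiles whose NE score falls below `mean - bulk_outlier_sd * sd`, and
#' reports the Pearson correlation (with p-value) of each cell-type score
#' with the cell-cycle score.
#'
#' @param tpm Genes x samples matrix of TPM (columns sum to 1e6).
#' @param marker_sets Named list of marker gene sets; must include `"NE"`.
#' @param cycle_genes Cell-cycle gene set.
#' @param config A [sinet_config].
#' @return Object of class `sinet_bulk_corr`: list with `scores` (tibble
#'   profile x set), `correlations` (tibble `cell_type`, `r`, `p_value`),
#'   `excluded` (character).
#' @export
bulk_scores_and_correlations <- function(tpm, marker_sets, cycle_genes,
                                         config = sinet_config()) {
  config <- as_sinet_config(config)
  if (ncol(tpm) < 10) stop("need >= 10 bulk profiles", call. = FALSE)
  if (!"NE" %in% names(marker_sets)) {
    stop("marker_sets must include an 'NE' set", call. = FALSE)
  }
  logv <- log2(tpm + 1)
  set_score <- function(genes, nm) {
    present <- intersect(genes, rownames(logv))
    if (!length(present)) {
      stop("marker set '", nm, "' has no genes in the bulk matrix",
           call. = FALSE)
    }
    colMeans(logv[present, , drop = FALSE])
  }
  scores <- purrr::imap(marker_sets, set_score)
  cycle <- set_score(cycle_genes, "cycle")
  ne <- scores[["NE"]]
  cut <- mean(ne) - config$bulk_outlier_sd * sd(ne)
  keep <- ne >= cut
  excluded <- colnames(tpm)[!keep]
  if (length(excluded) > 0.10 * ncol(tpm)) {
    warning("outlier exclusion removed ", length(excluded), "/", ncol(tpm),
            " profiles (> 10%)", call. = FALSE)
  }
  if (sd(cycle[keep]) == 0) {
    stop("cell-cycle score is constant across retained profiles; ",
         "correlation undefined", call. = FALSE)
  }
  corrs <- purrr::imap(scores, function(s, nm) {
    ct <- stats::cor.test(s[keep], cycle[keep])
    tibble::tibble(cell_type = nm, r = unname(ct$estimate),
                   p_value = ct$p.value)
  }) |> dplyr::bind_rows()
  score_tab <- tibble::tibble(
    profile_id = colnames(tpm),
    retained = keep,
    cycle = unname(cycle),
    !!!purrr::map(scores, unname)
  )
  structure(list(scores = score_tab, correlations = corrs,
                 excluded = excluded),
            class = "sinet_bulk_corr")
}

#' @export
print.sinet_bulk_corr <- function(x, ...) {
  cat("<sinet_bulk_corr>", sum(x$scores$retained), "profiles retained (",
      length(x$excluded), "outliers excluded )\n")
  print(x$correlations)
  invisible(x)
}
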