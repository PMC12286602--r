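#' Cluster cells within one sample
#'
#' Per-tumor clustering (no cross-sample integration): PCA on the most
#' variable genes of the centered matrix, a shared-nearest-neighbour (SNN)
#' graph on the top principal components, and Louvain community detection.
#' The result is deterministic given `config$rng_seed`.
#'
#' @param x A centered `sinet_norm`.
#' @param config A [sinet_config]; uses `cluster_n_pcs`, `cluster_k`,
#'   `cluster_n_hvg`, `rng_seed`.
#' @return Tibble with columns `sample_id`, `cell_id`, `cluster` (integer,
#'   1-based, ordered by decreasing size).
#' @export
cluster_cells <- function(x, config = sinet_config()) {
  stopifnot(inherits(x, "sinet_norm"))
  config <- as_sinet_config(config)
  if (!x$centered) stop("cluster_cells() expects centered values", call. = FALSE)
  n <- ncol(x$values)
  if (n < 20) {
    warning("fewer than 20 cells in ", x$sample_id,
            "; assigning a single cluster", call. = FALSE)
    return(tibble::tibble(sample_id = x$sample_id,
                          cell_id = colnames(x$values),
                          cluster = 1L))
  }
  rv <- apply(x$values, 1, var)
  if (max(rv) < 1e-12) {
    # all cells identical: one cluster
    return(tibble::tibble(sample_id = x$sample_id,
                          cell_id = colnames(x$values),
                          cluster = 1L))
  }
  hvg <- order(rv, decreasing = TRUE)[seq_len(min(config$cluster_n_hvg, nrow(x$values)))]
  mat <- t(x$values[hvg, , drop = FALSE])
  npc <- min(config$cluster_n_pcs, n - 1L, ncol(mat))
  pc <- prcomp(mat, center = TRUE, scale. = FALSE, rank. = npc)$x
  k <- min(config$cluster_k, n - 1L)
  d <- as.matrix(dist(pc))
  nn <- t(apply(d, 1, function(r) order(r)[2:(k + 1)]))
  adj <- matrix(0L, n, n)
  adj[cbind(rep(seq_len(n), k), as.vector(nn))] <- 1L
  shared <- tcrossprod(adj)
  snn <- shared / (2 * k - shared)      # Jaccard-type SNN weight
  snn[snn < 1 / 15] <- 0                # prune weak edges
  diag(snn) <- 0
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                           weighted = TRUE)
  membership <- withr::with_seed(config$rng_seed, {
    igraph::cluster_louvain(g)$membership
  })
  # relabel clusters by decreasing size for stable, readable ids
  sizes <- sort(table(membership), decreasing = TRUE)
  relab <- setNames(seq_along(sizes), names(sizes))
  tibble::tibble(
    sample_id = x$sample_id,
    cell_id = colnames(x$values),
    cluster = as.integer(relab[as.character(membership)])
  )
}

#' Label clusters with cell types from marker scores
#'
#' Each cluster receives the cell type whose marker signature has the highest
#' cluster-mean score, provided that score beats the runner-up by at least
#' `config$annotate_margin` (default 0.25 log2); otherwise the cluster is
#' labeled `"Unknown"`. Annotation depends only on cluster-mean scores, so it
#' is invariant to shuffling cells within clusters.
#'
#' @param clusters Tibble from [cluster_cells()].
#' @param scores Long tibble of per-cell marker scores
#'   ([score_signatures()] over the cell-type marker sets).
#' @param config A [sinet_config].
#' @return `clusters` with an added `cell_type` column.
#' @export
annotate_clusters <- function(clusters, scores, config = sinet_config()) {
  config <- as_sinet_config(config)
  stopifnot(all(c("sample_id", "cell_id", "cluster") %in% names(clusters)),
            all(c("cell_id", "signature", "score") %in% names(scores)))
  scores <- dplyr::select(scores, "cell_id", "signature", "score")
  cluster_means <- dplyr::inner_join(scores, clusters, by = "cell_id") |>
    dplyr::group_by(.data$sample_id, .data$cluster, .data$signature) |>
    dplyr::summarise(mean_score = mean(.data$score), .groups = "drop")
  labels <- cluster_means |>
    dplyr::group_by(.data$sample_id, .data$cluster) |>
    dplyr::arrange(dplyr::desc(.data$mean_score), .by_group = TRUE) |>
    dplyr::summarise(
      cell_type = if (dplyr::n() == 1L ||
                      .data$mean_score[1] - .data$mean_score[2] >
                        config$annotate_margin) {
        .data$signature[1]
      } else "Unknown",
      .groups = "drop")
  dplyr::left_join(clusters, labels, by = c("sample_id", "cluster")) |>
    dplyr::mutate(cell_type = dplyr::coalesce(.data$cell_type, "Unknown"))
}
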