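#' Enumerate all binary expression patterns over S samples
#'
#' A binary pattern marks each sample as expressing (1) or not expressing (0)
#' a gene; with S samples there are `2^S` theoretical patterns (256 for the
#' eight-sample cohort). Patterns are ordered by their integer encoding (the
#' first sample is the most significant bit), so the order is deterministic
#' given the cohort's sample order. The constant patterns (all 0, all 1) have
#' no defined correlation with any profile and are flagged non-assignable.
#'
#' @param S Number of samples, between 1 and 20.
#' @param samples Optional sample ids used as vector names.
#' @return Tibble `pattern_id` (0-based integer encoding), `pattern`
#'   (binary string), `n_expressed`, `assignable`; the 0/1 matrix is in
#'   attribute `"matrix"` (patterns in rows).
#' @examples
#' nrow(enumerate_patterns(8)) # 256
#' @export
enumerate_patterns <- function(S, samples = NULL) {
  if (!is.numeric(S) || length(S) != 1 || S < 1 || S > 20 || S != round(S)) {
    stop("S must be an integer in [1, 20]", call. = FALSE)
  }
  S <- as.integer(S)
  ids <- 0:(2^S - 1)
  bits <- vapply(ids, function(i) as.integer(intToBits(i)[S:1]), integer(S))
  m <- if (S == 1L) matrix(bits, ncol = 1L) else t(bits)
  colnames(m) <- samples %||% paste0("S", seq_len(S))
  out <- tibble::tibble(
    pattern_id = ids,
    pattern = apply(m, 1, paste, collapse = ""),
    n_expressed = rowSums(m),
    assignable = rowSums(m) > 0 & rowSums(m) < S
  )
  attr(out, "matrix") <- m
  out
}

#' Per-sample NE expression profiles of genes
#'
#' For each gene, the profile entry of a sample is the mean centered log2
#' expression over that sample's NE cells; the profile is then standardised
#' (z-scored) across samples. Matrices should be centered but NOT
#' gene-filtered: a pattern's 0-samples are exactly those where the gene is
#' unexpressed, so the per-sample expression filter must not remove it from
#' the profile. Genes absent from a sample's count matrix altogether are
#' dropped with a warning rather than imputed; genes with zero variance
#' across samples are flagged non-assignable.
#'
#' @param genes Character vector of genes (typically the subset-specific
#'   tier).
#' @param norms Named list of centered `sinet_norm` objects for the eligible
#'   samples (defines the sample order).
#' @param annotations Cohort annotation tibble.
#' @return Tibble `gene`, `sample_id`, `value` (standardised), plus matrix
#'   attribute `"matrix"` (genes x samples) and `"assignable"` flags.
#' @export
gene_sample_profiles <- function(genes, norms, annotations) {
  samples <- names(norms)
  ne_means <- vapply(samples, function(s) {
    ids <- annotations$cell_id[annotations$sample_id == s &
                                 annotations$cell_type == "NE"]
    ids <- intersect(ids, colnames(norms[[s]]$values))
    present <- intersect(genes, rownames(norms[[s]]$values))
    v <- rep(NA_real_, length(genes))
    names(v) <- genes
    v[present] <- rowMeans(norms[[s]]$values[present, ids, drop = FALSE])
    v
  }, numeric(length(genes)))
  if (length(genes) == 1L) ne_means <- matrix(ne_means, nrow = 1,
                                              dimnames = list(genes, samples))
  keep <- rowSums(is.na(ne_means)) == 0
  if (any(!keep)) {
    warning(sum(!keep), " gene(s) absent from >= 1 eligible sample dropped ",
            "from pattern analysis", call. = FALSE)
    ne_means <- ne_means[keep, , drop = FALSE]
  }
  sds <- apply(ne_means, 1, sd)
  assignable <- sds > 0
  z <- ne_means
  z[assignable, ] <- (ne_means[assignable, , drop = FALSE] -
                        rowMeans(ne_means[assignable, , drop = FALSE])) /
    sds[assignable]
  out <- tibble::as_tibble(z, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "value")
  attr(out, "matrix") <- z
  attr(out, "assignable") <- assignable
  out
}

#' Assign genes to their best-correlated binary pattern
#'
#' Computes the Pearson correlation between each gene's standardised
#' cross-sample profile and every assignable (non-constant) binary pattern,
#' and assigns the gene to the pattern with the highest correlation. Ties are
#' broken by the lowest pattern id (deterministic) and logged. Pearson
#' correlation is invariant to affine rescaling of the profile, so the
#' standardisation in [gene_sample_profiles()] does not change the argmax.
#'
#' @param profiles Output of [gene_sample_profiles()] (or any tibble with a
#'   genes x samples matrix in attribute `"matrix"`).
#' @param patterns Output of [enumerate_patterns()] for the same samples.
#' @return Tibble `gene`, `pattern_id`, `correlation`.
#' @export
assign_patterns <- function(profiles, patterns) {
  pm <- attr(patterns, "matrix")
  ok <- patterns$assignable
  if (!any(ok)) stop("no assignable (non-constant) pattern", call. = FALSE)
  pm <- pm[ok, , drop = FALSE]
  ids <- patterns$pattern_id[ok]
  z <- attr(profiles, "matrix")
  assignable <- attr(profiles, "assignable") %||% rep(TRUE, nrow(z))
  z <- z[assignable, , drop = FALSE]
  if (!nrow(z)) stop("no assignable gene profiles", call. = FALSE)
  r <- cor_rows_cols(z, t(pm))
  best <- apply(r, 1, which.max)  # which.max takes the first (lowest id) on ties
  n_tied <- sum(apply(r, 1, function(x) sum(x == max(x)) > 1))
  if (n_tied > 0) {
    message(n_tied, " gene(s) had tied pattern correlations; ",
            "lowest pattern_id kept")
  }
  tibble::tibble(
    gene = rownames(z),
    pattern_id = ids[best],
    correlation = r[cbind(seq_len(nrow(r)), best)]
  )
}

#' Retain patterns supported by more than five genes
#'
#' Keeps the patterns to which strictly more than five genes were assigned
#' (`pattern_min_genes = 6`), ordered by decreasing gene count; the largest
#' is "pattern #1", whose genes define the epithelial-like subtype score.
#'
#' @param assignments Tibble from [assign_patterns()].
#' @param patterns Tibble from [enumerate_patterns()].
#' @param config A [sinet_config].
#' @return Object of class `sinet_patterns`: tibble `rank`, `pattern_id`,
#'   `pattern`, `n_genes`, `genes` (list-column).
#' @export
retain_patterns <- function(assignments, patterns, config = sinet_config()) {
  config <- as_sinet_config(config)
  tab <- assignments |>
    dplyr::group_by(.data$pattern_id) |>
    dplyr::summarise(n_genes = dplyr::n(),
                     genes = list(.data$gene), .groups = "drop") |>
    dplyr::filter(.data$n_genes >= config$pattern_min_genes) |>
    dplyr::arrange(dplyr::desc(.data$n_genes), .data$pattern_id) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1) |>
    dplyr::left_join(dplyr::select(patterns, "pattern_id", "pattern"),
                     by = "pattern_id") |>
    dplyr::relocate("pattern", .after = "pattern_id")
  if (!nrow(tab)) {
    stop("no pattern retained: none reached ", config$pattern_min_genes,
         " genes; review pattern_min_genes or the DE stage", call. = FALSE)
  }
  structure(tab, class = c("sinet_patterns", class(tab)))
}

#' Call epithelial-like vs neuronal-like subtypes
#'
#' Scores each profile (a tumor's NE-cell mean profile, or a bulk RNA-seq
#' sample) for the pattern-#1 gene set and for the union of all other
#' retained patterns' genes, and assigns the subtype with the higher score:
#' `epithelial_like` when the pattern-#1 score wins, `neuronal_like`
#' otherwise. Input is a genes x profiles matrix of relative expression; for
#' bulk data pass `log2(TPM + 1)` and leave `center = TRUE` so genes are
#' row-centered across the bulk samples first.
#'
#' @param retained A `sinet_patterns` object from [retain_patterns()].
#' @param expr Genes x profiles numeric matrix.
#' @param center Row-center `expr` across profiles before scoring (default
#'   TRUE; set FALSE if the matrix is already relative expression).
#' @param min_overlap Minimum genes required from pattern #1 and from the
#'   other patterns (default 5).
#' @return Tibble `profile_id`, `subtype`, `score_pattern1`, `score_others`.
#' @export
call_subtypes <- function(retained, expr, center = TRUE, min_overlap = 5) {
  stopifnot(inherits(retained, "sinet_patterns"))
  if (center) expr <- expr - rowMeans(expr)
  g1 <- intersect(retained$genes[[1]], rownames(expr))
  others <- unique(unlist(retained$genes[-1]))
  g2 <- intersect(others, rownames(expr))
  if (length(g1) < min_overlap || length(g2) < min_overlap) {
    stop("pattern gene overlap with the expression matrix below ",
         min_overlap, " (pattern #1: ", length(g1), ", others: ", length(g2),
         ")", call. = FALSE)
  }
  s1 <- colMeans(expr[g1, , drop = FALSE])
  s2 <- colMeans(expr[g2, , drop = FALSE])
  tibble::tibble(
    profile_id = colnames(expr),
    subtype = unname(ifelse(s1 > s2, "epithelial_like", "neuronal_like")),
    score_pattern1 = unname(s1),
    score_others = unname(s2)
  )
}

#' NE-cell mean expression matrix across eligible samples
#'
#' Helper assembling the genes x samples matrix of NE-cell mean centered
#' expression used for single-cell subtype calling.
#'
#' @param genes Genes to include (e.g. union of retained pattern genes).
#' @param norms Named list of centered `sinet_norm` objects.
#' @param annotations Cohort annotation tibble.
#' @return Genes x samples matrix (genes missing somewhere are dropped).
#' @export
ne_mean_matrix <- function(genes, norms, annotations) {
  prof <- gene_sample_profiles(genes, norms, annotations)
  m <- attr(prof, "matrix")
  # un-standardised means are wanted here; recompute without scaling
  samples <- names(norms)
  mm <- vapply(samples, function(s) {
    ids <- annotations$cell_id[annotations$sample_id == s &
                                 annotations$cell_type == "NE"]
    ids <- intersect(ids, colnames(norms[[s]]$values))
    rowMeans(norms[[s]]$values[rownames(m), ids, drop = FALSE])
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) mm <- matrix(mm, 1, dimnames = list(rownames(m), samples))
  mm
}
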