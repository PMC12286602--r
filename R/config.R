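#' Analysis configuration
#'
#' Collects every tunable threshold of the SiNET analysis in one object.
#' Defaults are the values used throughout the package: platform-specific QC
#' thresholds on detected genes (nuclei 1000, cells 700), the expression filter
#' on logged gene row-means (4.5), the sampled 50-vs-50 differential-expression
#' scheme with a minimum fold change of 8 for NE signature genes, tier
#' boundaries for common (>= 6 samples) and subset-specific (2-5 samples)
#' genes, the 100-NE-cell eligibility threshold, the >5-gene rule for retaining
#' binary patterns, and the lenient (1.5) / strict (2.0) cycling-score cutoffs
#' in centered log2 units.
#'
#' All comparisons against these thresholds are strict (`>` / `<`), so a cell
#' with exactly 1000 detected genes on the nuclei platform is retained
#' (`>= min_genes_nuclei`), while a gene whose filter statistic is exactly 4.5
#' is excluded.
#'
#' @param min_genes_nuclei Minimum detected genes to keep a nucleus.
#' @param min_genes_cells Minimum detected genes to keep a whole cell.
#' @param gene_filter_logmean Gene retention cutoff on `log2(mean(TPM/10) + 1)`
#'   (or mean of logs, see `gene_filter_mode`).
#' @param gene_filter_mode `"log_of_means"` (default) computes
#'   `log2(mean(TPM/10) + 1)` per gene; `"mean_of_logs"` averages the logged
#'   values instead.
#' @param de_n_sampled Cells sampled per group for NE-vs-reference DE.
#' @param de_min_fc Minimum fold change for NE signature genes (8).
#' @param de_min_fc_within Minimum fold change for within-cell-type DE (3).
#' @param de_min_fc_subtype Minimum fold change for subtype DE per cell type (4).
#' @param de_alpha Significance level applied to FDR-adjusted q-values (or to
#'   uncorrected p-values in the subtype DE stage).
#' @param de_test `"wilcoxon"` (rank-sum, default) or `"t"` (Welch).
#' @param common_min_samples Minimum samples for the common tier (6).
#' @param subset_range Inclusive sample-count range of the subset-specific tier.
#' @param min_ne_cells NE cells required for a sample to enter signature DE.
#' @param pattern_min_genes Minimum genes (strictly more than 5, i.e. >= 6) for
#'   a binary pattern to be retained.
#' @param cycle_threshold_lenient Lenient cycling cutoff on the max cycle score.
#' @param cycle_threshold_strict Strict ("twofold") cycling cutoff.
#' @param annotate_margin Margin (log2 score units) by which the best marker
#'   signature must beat the runner-up before a cluster is labeled.
#' @param cluster_n_pcs Principal components used for the SNN graph.
#' @param cluster_k Nearest neighbours for the SNN graph.
#' @param cluster_n_hvg Most-variable genes used for PCA.
#' @param bulk_outlier_sd Bulk profiles with NE score below
#'   `mean - bulk_outlier_sd * sd` are excluded as outliers.
#' @param rng_seed Seed controlling every stochastic step (reference sampling,
#'   clustering).
#'
#' @return A list of class `sinet_config`.
#' @examples
#' cfg <- sinet_config(rng_seed = 1)
#' cfg$de_min_fc
#' @export
sinet_config <- function(min_genes_nuclei = 1000,
                         min_genes_cells = 700,
                         gene_filter_logmean = 4.5,
                         gene_filter_mode = c("log_of_means", "mean_of_logs"),
                         de_n_sampled = 50,
                         de_min_fc = 8,
                         de_min_fc_within = 3,
                         de_min_fc_subtype = 4,
                         de_alpha = 0.05,
                         de_test = c("wilcoxon", "t"),
                         common_min_samples = 6,
                         subset_range = c(2, 5),
                         min_ne_cells = 100,
                         pattern_min_genes = 6,
                         cycle_threshold_lenient = 1.5,
                         cycle_threshold_strict = 2.0,
                         annotate_margin = 0.25,
                         cluster_n_pcs = 30,
                         cluster_k = 20,
                         cluster_n_hvg = 1000,
                         bulk_outlier_sd = 2,
                         rng_seed = 1L) {
  gene_filter_mode <- match.arg(gene_filter_mode)
  de_test <- match.arg(de_test)
  cfg <- list(
    min_genes_nuclei = as.integer(min_genes_nuclei),
    min_genes_cells = as.integer(min_genes_cells),
    gene_filter_logmean = gene_filter_logmean,
    gene_filter_mode = gene_filter_mode,
    de_n_sampled = as.integer(de_n_sampled),
    de_min_fc = de_min_fc,
    de_min_fc_within = de_min_fc_within,
    de_min_fc_subtype = de_min_fc_subtype,
    de_alpha = de_alpha,
    de_test = de_test,
    common_min_samples = as.integer(common_min_samples),
    subset_range = as.integer(subset_range),
    min_ne_cells = as.integer(min_ne_cells),
    pattern_min_genes = as.integer(pattern_min_genes),
    cycle_threshold_lenient = cycle_threshold_lenient,
    cycle_threshold_strict = cycle_threshold_strict,
    annotate_margin = annotate_margin,
    cluster_n_pcs = as.integer(cluster_n_pcs),
    cluster_k = as.integer(cluster_k),
    cluster_n_hvg = as.integer(cluster_n_hvg),
    bulk_outlier_sd = bulk_outlier_sd,
    rng_seed = as.integer(rng_seed)
  )
  thresholds <- c(
    cfg$min_genes_nuclei, cfg$min_genes_cells, cfg$gene_filter_logmean,
    cfg$de_n_sampled, cfg$de_min_fc, cfg$de_min_fc_within,
    cfg$de_min_fc_subtype, cfg$de_alpha, cfg$common_min_samples,
    cfg$min_ne_cells, cfg$pattern_min_genes, cfg$cycle_threshold_lenient,
    cfg$cycle_threshold_strict
  )
  if (any(thresholds <= 0)) {
    stop("all configuration thresholds must be strictly positive", call. = FALSE)
  }
  if (length(cfg$subset_range) != 2L ||
      cfg$subset_range[1] > cfg$subset_range[2] ||
      cfg$subset_range[1] < 1L ||
      cfg$subset_range[2] > cfg$common_min_samples - 1L) {
    stop("subset_range must lie within [1, common_min_samples - 1]", call. = FALSE)
  }
  structure(cfg, class = "sinet_config")
}

#' @export
print.sinet_config <- function(x, ...) {
  cat("<sinet_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

as_sinet_config <- function(cfg) {
  if (is.null(cfg)) return(sinet_config())
  if (!inherits(cfg, "sinet_config")) {
    stop("`config` must be created with sinet_config()", call. = FALSE)
  }
  cfg
}
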