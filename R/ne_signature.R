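#' Samples eligible for NE signature analysis
#'
#' A sample enters the NE-vs-reference differential expression stage when it
#' contains at least `config$min_ne_cells` (default 100) annotated NE cells.
#' An explicit `include` override admits listed samples regardless of their NE
#' count (used in the original cohort for a small sample whose absolute NE
#' count sufficed despite a low NE fraction); overrides are logged.
#'
#' @param annotations Tibble with `sample_id`, `cell_id`, `cell_type`.
#' @param config A [sinet_config].
#' @param include Character vector of sample ids to admit regardless.
#' @return Tibble `sample_id`, `n_ne`, `eligible`, `override`.
#' @export
eligible_samples <- function(annotations, config = sinet_config(),
                             include = character()) {
  config <- as_sinet_config(config)
  tab <- annotations |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_ne = sum(.data$cell_type == "NE"), .groups = "drop") |>
    dplyr::mutate(
      override = .data$sample_id %in% include,
      eligible = .data$n_ne >= config$min_ne_cells | .data$override)
  for (s in tab$sample_id[tab$override & tab$n_ne < config$min_ne_cells]) {
    message("sample ", s, " included by override despite ",
            tab$n_ne[tab$sample_id == s], " NE cells")
  }
  if (!any(tab$eligible)) {
    stop("no sample reaches ", config$min_ne_cells, " NE cells", call. = FALSE)
  }
  tab
}

reference_types <- c("Macrophage", "Fibroblast", "Endothelial")

#' Build the reference cell set for one sample
#'
#' The reference for NE-vs-reference DE is `config$de_n_sampled` (default 50)
#' cells sampled without replacement from the pooled macrophages, fibroblasts
#' and endothelial cells of the sample. When the pool is smaller than the
#' required number, reference cells are borrowed from the other sample whose
#' mean NE expression profile has the highest Pearson correlation with this
#' sample's (computed over shared genes of the centered matrices); the donor
#' is recorded in the output.
#'
#' @param sample_id Sample to build a reference for.
#' @param annotations Cohort annotation tibble (`sample_id`, `cell_id`,
#'   `cell_type`).
#' @param norms Named list of centered `sinet_norm` objects, one per sample.
#' @param config A [sinet_config]; `rng_seed` makes the draw reproducible.
#' @return Tibble `sample_id`, `cell_id`, `donor_sample`.
#' @export
build_reference <- function(sample_id, annotations, norms,
                            config = sinet_config()) {
  config <- as_sinet_config(config)
  n_ref <- config$de_n_sampled
  pool_of <- function(s) {
    ids <- annotations$cell_id[annotations$sample_id == s &
                                 annotations$cell_type %in% reference_types]
    intersect(ids, colnames(norms[[s]]$values))
  }
  pool <- pool_of(sample_id)
  donor <- sample_id
  if (length(pool) < n_ref) {
    donor <- best_correlated_donor(sample_id, annotations, norms,
                                   min_pool = n_ref, pool_of = pool_of)
    message("sample ", sample_id, ": reference pool of ", length(pool),
            " < ", n_ref, "; borrowing reference cells from ", donor)
    pool <- pool_of(donor)
  }
  picked <- if (length(pool) == n_ref) pool else {
    withr::with_seed(config$rng_seed + match(sample_id, sort(names(norms))),
                     sample(pool, n_ref))
  }
  tibble::tibble(sample_id = sample_id, cell_id = picked, donor_sample = donor)
}

# Donor = other sample with >= min_pool reference cells whose NE-mean profile
# best correlates (Pearson over shared genes) with the target sample's.
best_correlated_donor <- function(sample_id, annotations, norms, min_pool,
                                  pool_of) {
  ne_profile <- function(s) {
    ids <- annotations$cell_id[annotations$sample_id == s &
                                 annotations$cell_type == "NE"]
    ids <- intersect(ids, colnames(norms[[s]]$values))
    if (!length(ids)) return(NULL)
    rowMeans(norms[[s]]$values[, ids, drop = FALSE])
  }
  target <- ne_profile(sample_id)
  candidates <- setdiff(names(norms), sample_id)
  candidates <- candidates[vapply(candidates,
                                  function(s) length(pool_of(s)) >= min_pool,
                                  logical(1))]
  if (!length(candidates)) {
    stop("no sample has ", min_pool, " reference cells to borrow",
         call. = FALSE)
  }
  cors <- vapply(candidates, function(s) {
    prof <- ne_profile(s)
    if (is.null(prof) || is.null(target)) return(-Inf)
    shared <- intersect(names(target), names(prof))
    if (length(shared) < 3) return(-Inf)
    cor(target[shared], prof[shared])
  }, numeric(1))
  candidates[which.max(cors)]
}

#' NE-vs-reference differential expression for one sample
#'
#' Samples `config$de_n_sampled` NE cells and the same number of reference
#' cells (see [build_reference()]), then tests every retained gene. The fold
#' change is the difference of group means in centered log2 units, p-values
#' come from a two-sided Wilcoxon rank-sum test (Welch t optional), and
#' Benjamini-Hochberg correction is applied over all tested genes of the
#' sample. A gene is a NE signature candidate (`is_de`) when it is
#' upregulated with `log2_fc > log2(de_min_fc)` (fold 8, so delta > 3) and
#' `q_value < de_alpha`.
#'
#' @param sample_id Sample to test.
#' @param annotations Cohort annotation tibble.
#' @param norm The sample's centered `sinet_norm`.
#' @param reference Tibble from [build_reference()]; when the donor is a
#'   different sample, pass its matrix as `donor_norm`.
#' @param config A [sinet_config].
#' @param donor_norm Centered `sinet_norm` of the donor sample (only needed
#'   when reference cells were borrowed).
#' @return Tibble `gene`, `sample_id`, `log2_fc`, `p_value`, `q_value`,
#'   `is_de`.
#' @export
de_ne_vs_reference <- function(sample_id, annotations, norm, reference,
                               config = sinet_config(), donor_norm = NULL) {
  config <- as_sinet_config(config)
  n_smp <- config$de_n_sampled
  ne_ids <- annotations$cell_id[annotations$sample_id == sample_id &
                                  annotations$cell_type == "NE"]
  ne_ids <- intersect(ne_ids, colnames(norm$values))
  if (length(ne_ids) < n_smp) {
    stop("sample ", sample_id, " has ", length(ne_ids),
         " NE cells; cannot sample ", n_smp, call. = FALSE)
  }
  ne_pick <- withr::with_seed(
    config$rng_seed + 10000L + sum(utf8ToInt(sample_id)),
    sample(ne_ids, n_smp))
  donor <- unique(reference$donor_sample)
  ref_mat <- if (identical(donor, sample_id)) norm$values else {
    if (is.null(donor_norm)) {
      stop("reference was borrowed from ", donor,
           "; supply donor_norm", call. = FALSE)
    }
    donor_norm$values
  }
  genes <- intersect(rownames(norm$values), rownames(ref_mat))
  x <- cbind(norm$values[genes, ne_pick, drop = FALSE],
             ref_mat[genes, reference$cell_id, drop = FALSE])
  idx_a <- seq_len(n_smp)
  idx_b <- n_smp + seq_len(nrow(reference))
  log2_fc <- rowMeans(x[, idx_a, drop = FALSE]) -
    rowMeans(x[, idx_b, drop = FALSE])
  p <- row_group_test(x, idx_a, idx_b, config$de_test)
  q <- p.adjust(p, method = "BH")
  tibble::tibble(
    gene = genes, sample_id = sample_id,
    log2_fc = unname(log2_fc), p_value = unname(p), q_value = unname(q),
    is_de = log2_fc > log2(config$de_min_fc) & q < config$de_alpha
  )
}

#' Run NE signature DE over all eligible samples
#'
#' Convenience wrapper: determines eligibility, builds each sample's
#' reference (borrowing where needed) and runs [de_ne_vs_reference()].
#'
#' @param annotations Cohort annotation tibble.
#' @param norms Named list of centered `sinet_norm` objects.
#' @param config A [sinet_config].
#' @param include Eligibility overrides, see [eligible_samples()].
#' @return Tibble of per-sample DE results (one row per gene and sample).
#' @export
run_ne_de <- function(annotations, norms, config = sinet_config(),
                      include = character()) {
  config <- as_sinet_config(config)
  elig <- eligible_samples(annotations, config, include)
  samples <- elig$sample_id[elig$eligible]
  purrr::map(samples, function(s) {
    ref <- build_reference(s, annotations, norms, config)
    donor <- unique(ref$donor_sample)
    de_ne_vs_reference(
      s, annotations, norms[[s]], ref, config,
      donor_norm = if (identical(donor, s)) NULL else norms[[donor]])
  }) |>
    dplyr::bind_rows()
}

#' Classify NE genes into common / subset-specific / sample-specific tiers
#'
#' Counts, per gene, the eligible samples in which it was differentially
#' expressed. Genes DE in at least `common_min_samples` (default 6) samples
#' are `common`; in `subset_range` (default 2-5) samples `subset_specific`;
#' in exactly one sample `sample_specific`; otherwise `none`.
#'
#' @param de Tibble from [run_ne_de()] (rows over genes x samples).
#' @param config A [sinet_config].
#' @return Object of class `sinet_ne_tiers`: a tibble `gene`, `n_samples_de`,
#'   `tier`, `de_flags` (binary string over eligible samples, sorted by
#'   sample id). Attribute `"samples"` records the sample order;
#'   `tidy()`/`glance()` methods and [autoplot.sinet_ne_tiers()] summarise it.
#' @export
classify_ne_genes <- function(de, config = sinet_config()) {
  config <- as_sinet_config(config)
  samples <- sort(unique(de$sample_id))
  if (length(samples) < config$common_min_samples) {
    warning("only ", length(samples), " eligible samples; the common tier ",
            "requires ", config$common_min_samples, call. = FALSE)
  }
  flags <- de |>
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = samples)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_samples_de = sum(.data$is_de),
      de_flags = paste(as.integer(samples %in% .data$sample_id[.data$is_de]),
                       collapse = ""),
      .groups = "drop")
  out <- flags |>
    dplyr::mutate(tier = dplyr::case_when(
      .data$n_samples_de >= config$common_min_samples ~ "common",
      .data$n_samples_de >= config$subset_range[1] &
        .data$n_samples_de <= config$subset_range[2] ~ "subset_specific",
      .data$n_samples_de == 1L ~ "sample_specific",
      TRUE ~ "none"))
  structure(out, samples = samples, class = c("sinet_ne_tiers", class(out)))
}
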