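# Shared fixtures: all synthetic, generated in code at test time.
# Heavy multi-seed sweeps are computed once per session and memoised as small
# summary tables (never full fit objects, which hold large matrices).

.cache <- new.env(parent = emptyenv())

cache_get <- function(key, fn) {
  if (!exists(key, envir = .cache)) assign(key, fn(), envir = .cache)
  get(key, envir = .cache)
}

# small cohort for unit tests: 4 tumors (2 epithelial-like), modest size
small_design <- function(...) {
  # all-cells platforms: at 1,500 genes a nucleus detects ~800 genes and the
  # 1000-gene QC threshold would wipe out nuclei samples
  cohort_design(n_tumors = 4, n_epithelial_like = 2, n_cells = 250,
                n_genes = 1500, platforms = rep("cells", 4), ...)
}

small_cohort <- function(seed = 1) {
  cache_get(paste0("small_cohort_", seed),
            function() generate_cohort(small_design(), seed = seed))
}

# a tiny sinet_counts object built by hand
toy_counts <- function(mat = NULL, sample_id = "S1", platform = "cells") {
  if (is.null(mat)) {
    mat <- matrix(1L, 3, 2, dimnames = list(paste0("g", 1:3),
                                            paste0("c", 1:2)))
  }
  sinet_counts(mat, sample_id, platform)
}

# centered sinet_norm directly from a values matrix (internal constructor)
toy_norm <- function(values, sample_id = "S1", centered = TRUE) {
  if (centered) values <- values - rowMeans(values)
  sinetscape:::sinet_norm(values, sample_id, "cells", centered = centered)
}

# counts matrix in which cell j has exactly `detected[j]` nonzero genes
counts_with_detected <- function(detected, n_genes) {
  m <- matrix(0L, n_genes, length(detected),
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("c%02d", seq_along(detected))))
  for (j in seq_along(detected)) m[seq_len(detected[j]), j] <- 2L
  m
}

# One full-default-cohort pipeline run, reduced to small summaries.
run_default_seed <- function(seed) {
  d <- cohort_design()
  co <- generate_cohort(d, seed = seed)
  sig <- truth_signatures(co)
  fit <- run_sinet_pipeline(co$samples, sig, sinet_config(rng_seed = seed))
  truth <- co$truth

  ann <- dplyr::inner_join(fit$annotations, truth$cells,
                           by = c("sample_id", "cell_id"),
                           suffix = c("_called", "_true"))
  tiers <- dplyr::left_join(tibble::as_tibble(fit$tiers), truth$genes,
                            by = "gene")
  planted <- tiers[!is.na(tiers$tier.y), ]
  sub_truth <- truth$samples[, c("sample_id", "subtype")]
  subtypes <- if (is.null(fit$subtype_calls)) NULL else
    dplyr::inner_join(fit$subtype_calls, sub_truth,
                      by = c(profile_id = "sample_id"),
                      suffix = c("_called", "_true"))
  cyc <- tidy(fit$cycling)
  cyc <- dplyr::left_join(cyc, sub_truth, by = "sample_id")
  pooled <- cyc |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(n = sum(.data$n_cells), n_cyc = sum(.data$n_cycling),
                     .groups = "drop")
  b_by_subtype <- cyc |>
    dplyr::filter(.data$cell_type == "B_plasma") |>
    dplyr::group_by(.data$subtype) |>
    dplyr::summarise(n = sum(.data$n_cells), n_cyc = sum(.data$n_cycling),
                     .groups = "drop")
  # a planted subset gene is recovered when its called pattern string has 1s
  # exactly at its program's planted member tumors (eligible order = T1..Tn)
  pat_recovery <- NA_real_
  if (!is.null(fit$patterns)) {
    n_t <- nrow(truth$samples)
    planted_string <- vapply(co$design$patterns, function(members) {
      paste(as.integer(seq_len(n_t) %in% members), collapse = "")
    }, character(1))
    gt <- truth$genes[!is.na(truth$genes$pattern_index), ]
    gt$planted_pattern <- planted_string[gt$pattern_index]
    assigned <- tidy(fit$patterns)[, c("gene", "pattern")]
    joined <- dplyr::left_join(gt, assigned, by = "gene")
    pat_recovery <- mean(!is.na(joined$pattern) &
                           joined$pattern == joined$planted_pattern)
  }
  list(
    seed = seed,
    annotation_accuracy = mean(ann$cell_type_called == ann$cell_type_true),
    tier_agreement = mean(planted$tier.x == planted$tier.y),
    n_planted_tiers = nrow(planted),
    n_patterns = if (is.null(fit$patterns)) 0L else nrow(fit$patterns),
    pattern_recovery = pat_recovery,
    subtypes = subtypes,
    subtype_all_correct = !is.null(subtypes) &&
      nrow(subtypes) == nrow(sub_truth) &&
      all(subtypes$subtype_called == subtypes$subtype_true),
    pooled_cycling = pooled,
    b_by_subtype = b_by_subtype
  )
}

default_sweep <- function(seeds = 1:10) {
  cache_get(paste0("sweep_", paste(range(seeds), collapse = "_")),
            function() lapply(seeds, run_default_seed))
}

# Null (zero-effect) cohort analysed with ground-truth labels: without planted
# markers, clustering-based annotation is meaningless by construction, so the
# calibration isolates the DE machinery.
run_null_seed <- function(seed) {
  d <- cohort_design(n_tumors = 6, n_epithelial_like = 2, n_cells = 400,
                     n_genes = 2500, zero_effects = TRUE,
                     platforms = rep("cells", 6))
  co <- generate_cohort(d, seed = seed)
  cfg <- sinet_config(rng_seed = seed)
  norms <- list(); norms_unc <- list(); retained <- list()
  for (s in names(co$samples)) {
    qc <- suppressMessages(qc_filter_cells(co$samples[[s]], cfg))
    raw_norm <- normalize_tpm(qc)
    nn <- filter_genes(raw_norm, cfg)
    retained[[s]] <- rownames(nn$values)
    norms_unc[[s]] <- raw_norm
    norms[[s]] <- center_within_sample(nn)
  }
  ann <- co$truth$cells[, c("sample_id", "cell_id", "cell_type")]
  de <- suppressMessages(run_ne_de(ann, norms, cfg))
  tiers <- suppressWarnings(classify_ne_genes(de, cfg))
  sub_calls <- tibble::tibble(
    profile_id = co$truth$samples$sample_id,
    subtype = co$truth$samples$subtype)
  sde <- suppressWarnings(
    subtype_de_per_celltype(norms_unc, ann, sub_calls, cfg,
                            genes = unique(unlist(retained))))
  sde_per_type <- sde |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(n_de = sum(.data$is_de), .groups = "drop")
  list(
    seed = seed,
    n_ne_de = sum(de$is_de),
    n_subset_tier = sum(tiers$tier == "subset_specific"),
    n_genes_tested = length(unique(de$gene)),
    subtype_de_per_type = sde_per_type
  )
}

null_sweep <- function(seeds = 1:10) {
  cache_get("null_sweep", function() lapply(seeds, run_null_seed))
}
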