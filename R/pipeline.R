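#' Run the full SiNET analysis pipeline on a cohort
#'
#' Chains the per-sample preprocessing (QC filter, TPM/10 log normalisation,
#' gene filter, per-tumor centering), clustering and marker-based annotation,
#' NE signature DE with tier classification, binary-pattern analysis with
#' subtype calling, and the cell-cycle census.
#'
#' @param counts Named list of [sinet_counts] (e.g. `cohort$samples` from
#'   [generate_cohort()]).
#' @param signatures List with elements `markers` (named list of marker gene
#'   sets) and `cell_cycle` (list with `G1S`, `G2M`); see
#'   [truth_signatures()] or [sinet_signatures()].
#' @param config A [sinet_config].
#' @param include Eligibility overrides passed to [eligible_samples()].
#' @param quiet Suppress per-step messages (default TRUE).
#' @return Object of class `sinet_fit`: list with `annotations`, `norms`
#'   (centered, gene-filtered), `norms_uncentered` (uncentered, unfiltered;
#'   for absolute-expression analyses such as [subtype_de_per_celltype()]),
#'   `norms_full` (centered, unfiltered; used for cross-sample pattern
#'   profiles), `retained_genes` (per-sample expression-filtered gene sets),
#'   `de`, `tiers`, `patterns`, `subtype_calls`, `cycle_calls`, `cycling`,
#'   `config`.
#' @export
run_sinet_pipeline <- function(counts, signatures, config = sinet_config(),
                               include = character(), quiet = TRUE) {
  config <- as_sinet_config(config)
  run <- function(expr) if (quiet) suppressWarnings(suppressMessages(expr)) else expr

  norms_unc <- list()  # uncentered, unfiltered (absolute-expression analyses)
  norms <- list()      # centered, gene-filtered (most analyses)
  norms_full <- list() # centered, unfiltered (cross-sample pattern profiles)
  retained_genes <- list()
  for (s in names(counts)) {
    qc <- run(qc_filter_cells(counts[[s]], config))
    raw_norm <- normalize_tpm(qc)
    nn <- run(filter_genes(raw_norm, config))
    retained_genes[[s]] <- rownames(nn$values)
    norms_unc[[s]] <- raw_norm
    norms[[s]] <- center_within_sample(nn)
    norms_full[[s]] <- center_within_sample(raw_norm)
  }

  annotations <- purrr::map(names(norms), function(s) {
    cl <- run(cluster_cells(norms[[s]], config))
    sc <- run(score_signatures(norms[[s]], signatures$markers,
                               on_missing = "skip"))
    run(annotate_clusters(cl, sc, config))
  }) |> dplyr::bind_rows()

  de <- run(run_ne_de(annotations, norms, config, include = include))
  tiers <- run(classify_ne_genes(de, config))

  elig <- run(eligible_samples(annotations, config, include))
  elig_ids <- elig$sample_id[elig$eligible]
  subset_genes <- tiers$gene[tiers$tier == "subset_specific"]
  patterns_tbl <- enumerate_patterns(length(elig_ids), samples = elig_ids)
  retained <- NULL
  subtype_calls <- NULL
  if (length(subset_genes) >= config$pattern_min_genes) {
    profs <- run(gene_sample_profiles(subset_genes, norms_full[elig_ids],
                                      annotations))
    assignments <- run(assign_patterns(profs, patterns_tbl))
    retained <- tryCatch(retain_patterns(assignments, patterns_tbl, config),
                         error = function(e) NULL)
    if (!is.null(retained) && nrow(retained) >= 2) {
      expr <- run(ne_mean_matrix(unique(unlist(retained$genes)),
                                 norms_full[elig_ids], annotations))
      subtype_calls <- tryCatch(call_subtypes(retained, expr, center = TRUE),
                                error = function(e) NULL)
    }
  }

  cycle_calls <- purrr::map(norms, function(nn) {
    run(call_cycling(score_cell_cycle(nn, signatures$cell_cycle$G1S,
                                      signatures$cell_cycle$G2M), config))
  }) |> dplyr::bind_rows()
  cycling <- cycling_fractions(annotations, cycle_calls)

  structure(list(
    annotations = annotations, norms = norms, norms_uncentered = norms_unc,
    norms_full = norms_full, retained_genes = retained_genes,
    de = de, tiers = tiers, patterns = retained,
    subtype_calls = subtype_calls, cycle_calls = cycle_calls,
    cycling = cycling, eligible = elig, config = config
  ), class = "sinet_fit")
}

#' @export
print.sinet_fit <- function(x, ...) {
  cat("<sinet_fit>\n")
  cat("  samples:", length(x$norms), " cells:", nrow(x$annotations), "\n")
  cat("  eligible for NE DE:", sum(x$eligible$eligible), "\n")
  cat("  NE tiers:", sum(x$tiers$tier == "common"), "common /",
      sum(x$tiers$tier == "subset_specific"), "subset /",
      sum(x$tiers$tier == "sample_specific"), "sample-specific\n")
  if (!is.null(x$patterns)) {
    cat("  retained patterns:", nrow(x$patterns), "\n")
  }
  if (!is.null(x$subtype_calls)) {
    cat("  subtype calls:",
        sum(x$subtype_calls$subtype == "epithelial_like"), "epithelial-like /",
        sum(x$subtype_calls$subtype == "neuronal_like"), "neuronal-like\n")
  }
  invisible(x)
}
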