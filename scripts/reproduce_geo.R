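#!/usr/bin/env Rscript
# Optional reproduction on the original cohorts. Requires locally downloaded
# data (no network access is attempted):
#
#   Rscript scripts/reproduce_geo.R --sc-dir DIR --meta META.tsv \
#       --bulk BULK_TPM.tsv --out results/geo/
#
# --sc-dir  directory with one 10x MTX triplet subdirectory per sample
#           (GEO accession GSE292163)
# --meta    TSV with columns: sample_id, dir, platform (cells|nuclei)
# --bulk    genes x samples TPM table for the 81 SiNET bulk profiles
#           (GEO accession GSE98894); optional
# --out     output directory
#
# Writes per-sample annotations, the NE tier table, retained patterns,
# subtype calls (single-cell and, if --bulk is given, bulk), and the cycling
# census as TSVs.

suppressPackageStartupMessages({
  library(sinetscape)
  library(dplyr)
  library(readr)
})

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}
sc_dir <- get_arg("--sc-dir")
meta_path <- get_arg("--meta")
bulk_path <- get_arg("--bulk")
out_dir <- get_arg("--out", "results/geo")
seed <- as.integer(get_arg("--seed", "1"))
if (is.null(sc_dir) || is.null(meta_path)) {
  stop("usage: reproduce_geo.R --sc-dir DIR --meta META.tsv [--bulk TPM.tsv] ",
       "[--out DIR] [--seed N]", call. = FALSE)
}
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

meta <- read_tsv(meta_path, show_col_types = FALSE)
counts <- list()
for (i in seq_len(nrow(meta))) {
  counts[[meta$sample_id[i]]] <- read_counts(
    file.path(sc_dir, meta$dir[i]),
    platform = meta$platform[i],
    sample_id = meta$sample_id[i])
}

signatures <- list(markers = sinet_signatures("markers"),
                   cell_cycle = sinet_signatures("cell_cycle"))
fit <- run_sinet_pipeline(counts, signatures, sinet_config(rng_seed = seed),
                          quiet = FALSE)

write_tsv(fit$annotations, file.path(out_dir, "annotations.tsv"))
write_tsv(tidy(fit$tiers), file.path(out_dir, "ne_tiers.tsv"))
if (!is.null(fit$patterns)) {
  write_tsv(tidy(fit$patterns), file.path(out_dir, "patterns.tsv"))
}
if (!is.null(fit$subtype_calls)) {
  write_tsv(fit$subtype_calls, file.path(out_dir, "subtypes_sc.tsv"))
}
write_tsv(tidy(fit$cycling), file.path(out_dir, "cycling_census.tsv"))
write_tsv(glance(fit$cycling), file.path(out_dir, "cycling_type_means.tsv"))
print(glance(fit))

if (!is.null(bulk_path) && !is.null(fit$patterns)) {
  bulk <- read_tsv(bulk_path, show_col_types = FALSE)
  tpm <- as.matrix(bulk[, -1])
  rownames(tpm) <- as.character(bulk[[1]])
  tpm <- t(t(tpm) / colSums(tpm)) * 1e6
  calls <- call_subtypes(fit$patterns, log2(tpm + 1), center = TRUE)
  write_tsv(calls, file.path(out_dir, "subtypes_bulk.tsv"))
  cc <- sinet_signatures("cell_cycle")
  bc <- bulk_scores_and_correlations(
    tpm, sinet_signatures("markers")[c("NE", "T", "B_plasma", "Epithelial")],
    c(cc$G1S, cc$G2M), sinet_config())
  write_tsv(tidy(bc), file.path(out_dir, "bulk_correlations.tsv"))
}
cat("wrote", out_dir, "\n")
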