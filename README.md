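# sinetscape

Subtype discovery and a cell-cycle census for small-intestine neuroendocrine
tumor (SiNET) single-cell and single-nuclei RNA-seq, with a bulk RNA-seq
cross-validation stage and a fully specified synthetic cohort generator.

## The problem

SiNETs are low-grade tumors whose malignant compartment consists of
neuroendocrine (NE) cells (marked by *CHGA*, *CHGB*, *TPH1*). Three questions
drive the analysis this package implements:

1. **What is the NE expression signature, and how does it vary between
   patients?** Per tumor, NE cells are compared against a sampled reference
   of macrophages, fibroblasts and endothelial cells (50 cells vs 50 cells,
   rank-sum test, fold change > 8, FDR < 0.05). Genes upregulated in at
   least six tumors form the *common* signature; genes upregulated in 2–5
   tumors are *subset-specific*; genes private to one tumor are
   *sample-specific*.
2. **Do subset-specific genes define tumor subtypes?** Each subset-specific
   gene's relative NE expression across the S tumors is correlated against
   all 2^S binary presence/absence patterns (256 for eight tumors) and
   assigned to the best-correlated pattern; patterns supported by more than
   five genes are retained. Scoring each tumor for pattern-#1 genes versus
   the union of all other retained patterns splits SiNETs into
   *epithelial-like* and *neuronal-like* subtypes — in single-cell cohorts
   and, by the same score rule, in bulk RNA-seq profiles.
3. **Which cells proliferate?** Every cell is scored for canonical G1/S and
   G2/M programs on per-tumor centered expression; a cell is cycling when
   its larger phase score exceeds 1.5 (lenient) or 2.0 (strict) in log2
   units. The census tabulates cycling percentages per cell type and tumor;
   in bulk profiles, cell-type marker scores are correlated with the
   cell-cycle score.

Expression is `log2(TPM/10 + 1)` (the /10 reflects ~100,000 true transcripts
per cell rather than the million implied by TPM), genes are filtered at
`log2(mean(TPM/10) + 1) > 4.5`, and most analyses run on per-tumor centered
("relative") expression.

Every stage is verifiable offline: `generate_cohort()` draws
negative-binomial cohorts with planted cell types, NE programs, binary
pattern structure, a MIF-like cytokine and per-type cycling fractions, and
returns the full ground truth.

## A worked example

```r
library(sinetscape)

design <- cohort_design()                 # 8 tumors, 3 epithelial-like
cohort <- generate_cohort(design, seed = 1)
sig    <- truth_signatures(cohort)        # planted marker / cycle gene sets
fit    <- run_sinet_pipeline(cohort$samples, sig, sinet_config(rng_seed = 1))
fit
#> <sinet_fit>
#>   samples: 8  cells: 4800
#>   eligible for NE DE: 8
#>   NE tiers: 70 common / 107 subset / 39 sample-specific
#>   retained patterns: 9
#>   subtype calls: 3 epithelial-like / 5 neuronal-like
```

The 70 common genes are the 30 planted common-NE genes plus the 40 NE marker
genes — markers are, correctly, upregulated in NE cells of every tumor. The
107 subset-specific genes fall into exactly the nine planted patterns, and
the subtype calls reproduce the planted 3 / 5 split. The census:

```r
glance(fit$cycling)
#> # A tibble: 8 x 3
#>   cell_type   n_samples mean_pct_cycling
#>   B_plasma            8           13.0
#>   Endothelial         8            2.60
#>   ...
#>   NE                  8            0.117
```

NE cells cycle least (planted 0.25%), and B/plasma cells in epithelial-like
tumors most (planted 32%). `autoplot(fit$cycling)`,
`plot_subtype_scores(fit$subtype_calls)` and `plot_tier_histogram(fit$tiers)`
draw the standard figures; `tidy()`/`glance()` return tibbles for further
work. For real data, `read_counts()` ingests 10x MTX triplets or dense TSVs
and `sinet_signatures()` provides canonical marker and cell-cycle gene sets.

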