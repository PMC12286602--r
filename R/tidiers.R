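#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the NE gene tier classification
#'
#' @param x A `sinet_ne_tiers` object from [classify_ne_genes()].
#' @param ... Unused.
#' @return The gene-level tibble (`gene`, `n_samples_de`, `de_flags`,
#'   `tier`).
#' @method tidy sinet_ne_tiers
#' @export
tidy.sinet_ne_tiers <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of the tier classification
#'
#' @inheritParams tidy.sinet_ne_tiers
#' @return Tibble with tier counts and the number of eligible samples.
#' @method glance sinet_ne_tiers
#' @export
glance.sinet_ne_tiers <- function(x, ...) {
  tibble::tibble(
    n_samples = length(attr(x, "samples")),
    n_common = sum(x$tier == "common"),
    n_subset_specific = sum(x$tier == "subset_specific"),
    n_sample_specific = sum(x$tier == "sample_specific"),
    n_de_any = sum(x$n_samples_de >= 1)
  )
}

#' Tidy retained binary patterns
#'
#' @param x A `sinet_patterns` object from [retain_patterns()].
#' @param ... Unused.
#' @return Gene-level tibble (`rank`, `pattern_id`, `pattern`, `gene`).
#' @method tidy sinet_patterns
#' @export
tidy.sinet_patterns <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("rank", "pattern_id", "pattern", "genes") |>
    tidyr::unnest_longer("genes", values_to = "gene")
}

#' One-row summary of retained patterns
#'
#' @inheritParams tidy.sinet_patterns
#' @return Tibble with the number of retained patterns and gene counts.
#' @method glance sinet_patterns
#' @export
glance.sinet_patterns <- function(x, ...) {
  tibble::tibble(
    n_patterns = nrow(x),
    n_genes_pattern1 = x$n_genes[1],
    n_genes_total = sum(x$n_genes)
  )
}

#' Tidy a cycling census
#'
#' @param x A `sinet_cycling` object from [cycling_fractions()].
#' @param ... Unused.
#' @return The per-(sample, cell type) tibble.
#' @method tidy sinet_cycling
#' @export
tidy.sinet_cycling <- function(x, ...) tibble::as_tibble(x)

#' Cross-sample average cycling percentages per cell type
#'
#' @inheritParams tidy.sinet_cycling
#' @return Tibble `cell_type`, `n_samples`, `mean_pct_cycling`.
#' @method glance sinet_cycling
#' @export
glance.sinet_cycling <- function(x, ...) attr(x, "type_means")

#' Tidy bulk score/cycle correlations
#'
#' @param x A `sinet_bulk_corr` object.
#' @param ... Unused.
#' @return Tibble `cell_type`, `r`, `p_value`.
#' @method tidy sinet_bulk_corr
#' @export
tidy.sinet_bulk_corr <- function(x, ...) x$correlations

#' One-row summary of the bulk correlation analysis
#'
#' @inheritParams tidy.sinet_bulk_corr
#' @return Tibble with profile counts and the top correlated cell type.
#' @method glance sinet_bulk_corr
#' @export
glance.sinet_bulk_corr <- function(x, ...) {
  top <- x$correlations[which.max(x$correlations$r), ]
  tibble::tibble(
    n_profiles = nrow(x$scores),
    n_retained = sum(x$scores$retained),
    n_excluded = length(x$excluded),
    top_cell_type = top$cell_type,
    top_r = top$r
  )
}

#' Tidy a full pipeline fit
#'
#' @param x A `sinet_fit` from [run_sinet_pipeline()].
#' @param ... Unused.
#' @return The gene tier tibble, joined with the retained pattern (if any).
#' @method tidy sinet_fit
#' @export
tidy.sinet_fit <- function(x, ...) {
  out <- tibble::as_tibble(x$tiers)
  if (!is.null(x$patterns)) {
    pat <- tidy(x$patterns) |>
      dplyr::select("gene", pattern_rank = "rank", "pattern")
    out <- dplyr::left_join(out, pat, by = "gene")
  }
  out
}

#' One-row summary of a pipeline fit
#'
#' @inheritParams tidy.sinet_fit
#' @return Tibble with cohort-level counts: cells, eligible samples, tier
#'   sizes, retained patterns, subtype split and the NE cycling percentage.
#' @method glance sinet_fit
#' @export
glance.sinet_fit <- function(x, ...) {
  ne_cyc <- dplyr::filter(glance(x$cycling), .data$cell_type == "NE")
  tibble::tibble(
    n_samples = length(x$norms),
    n_cells = nrow(x$annotations),
    n_eligible = sum(x$eligible$eligible),
    n_common = sum(x$tiers$tier == "common"),
    n_subset_specific = sum(x$tiers$tier == "subset_specific"),
    n_sample_specific = sum(x$tiers$tier == "sample_specific"),
    n_patterns = if (is.null(x$patterns)) 0L else nrow(x$patterns),
    n_epithelial_like = if (is.null(x$subtype_calls)) NA_integer_ else
      sum(x$subtype_calls$subtype == "epithelial_like"),
    mean_ne_pct_cycling = if (nrow(ne_cyc)) ne_cyc$mean_pct_cycling else
      NA_real_
  )
}
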