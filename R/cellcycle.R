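#' Score cells for the G1/S and G2/M cell-cycle programs
#'
#' Applies [score_signature()] with the two canonical phase gene lists and
#' reports, per cell, both scores and the phase with the larger score.
#'
#' @param x A centered `sinet_norm`.
#' @param g1s,g2m Character vectors of phase genes (defaults: the package's
#'   canonical lists, see [sinet_signatures()]).
#' @return Tibble `sample_id`, `cell_id`, `score_g1s`, `score_g2m`, `phase`.
#' @export
score_cell_cycle <- function(x, g1s = NULL, g2m = NULL) {
  if (is.null(g1s) || is.null(g2m)) {
    cc <- sinet_signatures("cell_cycle")
    g1s <- g1s %||% cc$G1S
    g2m <- g2m %||% cc$G2M
  }
  s1 <- score_signature(x, g1s, "G1S")
  s2 <- score_signature(x, g2m, "G2M")
  tibble::tibble(
    sample_id = s1$sample_id,
    cell_id = s1$cell_id,
    score_g1s = s1$score,
    score_g2m = s2$score,
    phase = ifelse(s1$score >= s2$score, "G1S", "G2M")
  )
}

#' Flag cycling cells
#'
#' A cell is called cycling when the larger of its two phase scores strictly
#' exceeds the threshold: 1.5 under the lenient call and 2.0 ("twofold")
#' under the strict call, both in centered log2 score units. The strict set
#' is by construction a subset of the lenient set.
#'
#' @param scores Tibble from [score_cell_cycle()].
#' @param config A [sinet_config].
#' @return `scores` with added `cycling_lenient`, `cycling_strict`.
#' @export
call_cycling <- function(scores, config = sinet_config()) {
  config <- as_sinet_config(config)
  mx <- pmax(scores$score_g1s, scores$score_g2m)
  dplyr::mutate(scores,
    cycling_lenient = mx > config$cycle_threshold_lenient,
    cycling_strict = mx > config$cycle_threshold_strict)
}

#' Cycling-cell census per cell type and tumor
#'
#' Tabulates, for every (sample, cell type) with at least one cell, the
#' number of cells, the number of cycling cells and the percentage, plus the
#' unweighted cross-sample average percentage per cell type (the horizontal
#' reference lines of the census plot). Cell types absent from a sample are
#' simply not reported (absence, not 0%).
#'
#' @param annotations Cohort annotation tibble.
#' @param calls Tibble from [call_cycling()].
#' @param which `"lenient"` (default) or `"strict"` threshold.
#' @return Object of class `sinet_cycling`: tibble `sample_id`, `cell_type`,
#'   `n_cells`, `n_cycling`, `pct_cycling`; per-type averages in attribute
#'   `"type_means"` (also via `glance()`).
#' @export
cycling_fractions <- function(annotations, calls, which = c("lenient", "strict")) {
  which <- match.arg(which)
  flag <- if (which == "lenient") "cycling_lenient" else "cycling_strict"
  tab <- dplyr::inner_join(
    dplyr::select(annotations, "sample_id", "cell_id", "cell_type"),
    dplyr::select(calls, "cell_id", dplyr::all_of(flag)),
    by = "cell_id") |>
    dplyr::group_by(.data$sample_id, .data$cell_type) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_cycling = sum(.data[[flag]]),
      pct_cycling = 100 * .data$n_cycling / .data$n_cells,
      .groups = "drop")
  means <- tab |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     mean_pct_cycling = mean(.data$pct_cycling),
                     .groups = "drop")
  structure(tab, type_means = means, threshold = which,
            class = c("sinet_cycling", class(tab)))
}

#' Germinal-center scores for B cells
#'
#' Scores the B/plasma cells of each sample for a germinal-center (GC)
#' signature, to assess whether proliferating B cells reflect sampled
#' germinal centers. Samples without B cells yield an empty result with a
#' warning.
#'
#' @param x A centered `sinet_norm`.
#' @param annotations Cohort annotation tibble.
#' @param gc_genes Character vector: the GC signature.
#' @return Tibble `sample_id`, `cell_id`, `score` (B/plasma cells only).
#' @export
score_germinal_center <- function(x, annotations, gc_genes) {
  b_ids <- annotations$cell_id[annotations$sample_id == x$sample_id &
                                 annotations$cell_type == "B_plasma"]
  b_ids <- intersect(b_ids, colnames(x$values))
  if (!length(b_ids)) {
    warning("no B/plasma cells in ", x$sample_id, call. = FALSE)
    return(tibble::tibble(sample_id = character(), cell_id = character(),
                          score = numeric()))
  }
  sc <- score_signature(x, gc_genes, "GC")
  sc |>
    dplyr::filter(.data$cell_id %in% b_ids) |>
    dplyr::select("sample_id", "cell_id", "score")
}
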