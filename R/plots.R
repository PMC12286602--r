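#' Plot the cycling-cell census
#'
#' Bar plot of the percentage of cycling cells per cell type and tumor, with
#' horizontal lines at the cross-sample average per cell type.
#'
#' @param object A `sinet_cycling` object from [cycling_fractions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sinet_cycling
#' @export
autoplot.sinet_cycling <- function(object, ...) {
  means <- attr(object, "type_means")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$sample_id, y = .data$pct_cycling,
                               fill = .data$sample_id)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(data = means,
                        ggplot2::aes(yintercept = .data$mean_pct_cycling),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~cell_type, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "% cycling cells",
                  title = paste0("Cycling cells per cell type (",
                                 attr(object, "threshold"), " threshold)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot subtype scores
#'
#' Pattern-#1 score against the score of all other retained patterns, one
#' point per profile, coloured by the called subtype.
#'
#' @param calls Tibble from [call_subtypes()].
#' @return A ggplot object.
#' @export
plot_subtype_scores <- function(calls) {
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$score_others,
                               y = .data$score_pattern1,
                               colour = .data$subtype)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "mean relative expression, other patterns",
                  y = "mean relative expression, pattern #1",
                  colour = "subtype") +
    ggplot2::theme_minimal()
}

#' Histogram of DE recurrence across samples
#'
#' Number of NE-upregulated genes by the number of samples in which they are
#' differentially expressed, coloured by tier.
#'
#' @param tiers A `sinet_ne_tiers` object.
#' @return A ggplot object.
#' @export
plot_tier_histogram <- function(tiers) {
  dat <- dplyr::filter(tibble::as_tibble(tiers), .data$n_samples_de >= 1)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n_samples_de,
                                    fill = .data$tier)) +
    ggplot2::geom_bar() +
    ggplot2::scale_x_continuous(breaks = seq_len(max(dat$n_samples_de))) +
    ggplot2::labs(x = "samples in which the gene is DE",
                  y = "number of genes", fill = "tier") +
    ggplot2::theme_minimal()
}

#' Plot bulk cell-type scores against the cell-cycle score
#'
#' One panel per cell-type score, Pearson r in the panel label; outliers
#' excluded by the NE-score rule are drawn hollow.
#'
#' @param object A `sinet_bulk_corr` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sinet_bulk_corr
#' @export
autoplot.sinet_bulk_corr <- function(object, ...) {
  long <- object$scores |>
    tidyr::pivot_longer(-c("profile_id", "retained", "cycle"),
                        names_to = "cell_type", values_to = "score") |>
    dplyr::left_join(object$correlations, by = "cell_type") |>
    dplyr::mutate(panel = sprintf("%s (r = %.2f)", .data$cell_type, .data$r))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$score, y = .data$cycle,
                                     shape = .data$retained)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = "cell-type score (mean log2 TPM+1)",
                  y = "cell-cycle score") +
    ggplot2::theme_minimal()
}
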