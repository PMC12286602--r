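#' Normalised expression matrix for one sample
#'
#' Internal constructor; users obtain these from [normalize_tpm()].
#' Values are `log2(TPM/10 + 1)`: counts are scaled to transcripts-per-million
#' within each cell, then divided by 10 because the true complexity of a cell
#' is closer to ~100,000 transcripts than to the million implied by TPM, then
#' log-transformed with an offset of 1. `centered = TRUE` means every gene row
#' has had its within-sample mean subtracted ("relative expression").
#'
#' @keywords internal
sinet_norm <- function(values, sample_id, platform, centered = FALSE) {
  structure(
    list(values = values, sample_id = sample_id, platform = platform,
         centered = centered),
    class = "sinet_norm"
  )
}

#' @export
print.sinet_norm <- function(x, ...) {
  cat(sprintf("<sinet_norm> %s: %d genes x %d cells (%s)\n",
              x$sample_id, nrow(x$values), ncol(x$values),
              if (x$centered) "centered" else "uncentered log2(TPM/10+1)"))
  invisible(x)
}

#' @export
dim.sinet_norm <- function(x) dim(x$values)

#' Normalise UMI counts to log2(TPM/10 + 1)
#'
#' Each cell's counts are scaled to sum to one million (TPM), divided by 10,
#' and transformed as `log2(x + 1)`. The result is the absolute-expression
#' matrix on which gene filtering and bulk-style scoring operate; most other
#' analyses use the per-tumor centered version from [center_within_sample()].
#'
#' @param x A [sinet_counts] object with no zero-total cells.
#' @return A `sinet_norm` object with `centered = FALSE`.
#' @export
normalize_tpm <- function(x) {
  stopifnot(inherits(x, "sinet_counts"))
  tot <- colSums(x$counts)
  if (any(tot == 0)) {
    stop("zero-total cell encountered in ", x$sample_id,
         "; run sinet_counts()/read_counts() first", call. = FALSE)
  }
  tpm10 <- sweep(x$counts, 2, tot, "/") * 1e5  # TPM / 10
  sinet_norm(log2(tpm10 + 1), x$sample_id, x$platform, centered = FALSE)
}

#' Filter genes by logged mean expression
#'
#' Retains genes whose logged row-mean across all cells of the sample strictly
#' exceeds `gene_filter_logmean` (default 4.5). By default the statistic is
#' `log2(mean(TPM/10) + 1)` (log of means); the alternative mean-of-logs
#' reading is available via `gene_filter_mode = "mean_of_logs"` but at the
#' same cutoff would retain almost nothing in sparse UMI data.
#'
#' @param x An uncentered `sinet_norm` object.
#' @param config A [sinet_config].
#' @return A `sinet_norm` restricted to the retained genes.
#' @export
filter_genes <- function(x, config = sinet_config()) {
  stopifnot(inherits(x, "sinet_norm"))
  config <- as_sinet_config(config)
  if (x$centered) {
    stop("filter_genes() expects uncentered values", call. = FALSE)
  }
  stat <- switch(config$gene_filter_mode,
    log_of_means = log2(rowMeans(2^x$values - 1) + 1),
    mean_of_logs = rowMeans(x$values)
  )
  keep <- stat > config$gene_filter_logmean
  if (!any(keep)) {
    stop("no genes pass the expression filter (", config$gene_filter_logmean,
         ") in ", x$sample_id, call. = FALSE)
  }
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  out
}

#' Center each gene within the sample
#'
#' Subtracts the within-sample mean from every gene row, converting absolute
#' log2 expression into relative expression. Most downstream analyses
#' (scoring, clustering, DE) run on centered values; analyses of absolute
#' expression (gene filtering, bulk scoring, subtype DE across tumors) do not.
#'
#' @param x An uncentered `sinet_norm`.
#' @return A `sinet_norm` with `centered = TRUE`.
#' @export
center_within_sample <- function(x) {
  stopifnot(inherits(x, "sinet_norm"))
  if (x$centered) {
    stop("values are already centered (double-centering guard)", call. = FALSE)
  }
  out <- x
  out$values <- x$values - rowMeans(x$values)
  out$centered <- TRUE
  out
}
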