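#' @importFrom rlang .data
#' @importFrom stats cor dist hclust cutree p.adjust prcomp pnorm pt rbinom
#'   rlnorm rnbinom rnorm runif sd var setNames
#' @importFrom utils head
NULL

# Vectorised two-sided Wilcoxon rank-sum test across the rows of a matrix.
# Normal approximation with tie correction and continuity correction; at the
# group sizes used here (>= 20 per group) this agrees with wilcox.test to well
# below any decision threshold (checked in the test suite).
rank_sum_rows <- function(x, idx_a, idx_b) {
  n_a <- length(idx_a)
  n_b <- length(idx_b)
  sub <- x[, c(idx_a, idx_b), drop = FALSE]
  n <- n_a + n_b
  w <- numeric(nrow(sub))
  tie_term <- numeric(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    r <- rank(sub[i, ])
    w[i] <- sum(r[seq_len(n_a)])
    tt <- table(sub[i, ])
    tt <- tt[tt > 1]
    tie_term[i] <- if (length(tt)) sum(tt^3 - tt) else 0
  }
  u <- w - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(pmax(sigma2, .Machine$double.eps))
  z[sigma2 <= 0] <- 0
  p <- 2 * pnorm(-abs(z))
  pmin(p, 1)
}

# Vectorised Welch t-test across rows; two-sided p.
welch_rows <- function(x, idx_a, idx_b) {
  a <- x[, idx_a, drop = FALSE]
  b <- x[, idx_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  se2 <- va / na + vb / nb
  t_stat <- (ma - mb) / sqrt(pmax(se2, .Machine$double.eps))
  df <- se2^2 / pmax(va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)),
                     .Machine$double.eps)
  p <- 2 * pt(-abs(t_stat), df)
  p[se2 <= 0] <- 1
  p
}

row_group_test <- function(x, idx_a, idx_b, method = "wilcoxon") {
  switch(method,
    wilcoxon = rank_sum_rows(x, idx_a, idx_b),
    t = welch_rows(x, idx_a, idx_b),
    stop("unknown test: ", method, call. = FALSE)
  )
}

# Pearson correlation of each row of `m` with each column of `patterns`,
# computed in one matrix product.
cor_rows_cols <- function(m, patterns) {
  ms <- m - rowMeans(m)
  msd <- sqrt(rowSums(ms^2))
  ps <- sweep(patterns, 2, colMeans(patterns))
  psd <- sqrt(colSums(ps^2))
  r <- (ms %*% ps) / (msd %o% psd)
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
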