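test_that("within-type DE matches the mean-difference oracle and is symmetric", {
  set.seed(14)
  ng <- 200
  vals <- matrix(rnorm(ng * 60), ng,
                 dimnames = list(sprintf("g%03d", 1:ng),
                                 sprintf("S1_c%03d", 1:60)))
  cyc_genes <- sprintf("g%03d", 1:30)
  vals[cyc_genes, 1:25] <- vals[cyc_genes, 1:25] + 2.5
  nn <- toy_norm(vals)
  cl <- tibble::tibble(cell_id = colnames(vals),
                       cluster = rep(c(1L, 2L), c(25, 35)))
  de <- within_type_de(nn, cl, 1L, 2L, sinet_config())
  oracle <- rowMeans(nn$values[, 1:25]) - rowMeans(nn$values[, 26:60])
  expect_equal(de$log2_fc, unname(oracle), tolerance = 1e-12)
  # planted proliferating subcluster: cycle genes recovered among DE genes
  expect_true(all(cyc_genes %in% de$gene[de$is_de & de$log2_fc > 0]))
  # swapping cluster labels negates fold changes, preserves the DE set
  de_sw <- within_type_de(nn, cl, 2L, 1L, sinet_config())
  expect_equal(de_sw$log2_fc, -de$log2_fc, tolerance = 1e-12)
  expect_equal(de_sw$is_de, de$is_de)
  # identical clusters -> no DE genes
  flat <- toy_norm(matrix(rnorm(ng * 60, 0, 1), ng,
                          dimnames = dimnames(vals)))
  expect_equal(sum(within_type_de(flat, cl, 1L, 2L, sinet_config())$is_de), 0L)
  # undersized cluster errors
  cl_bad <- cl; cl_bad$cluster <- rep(c(1L, 2L), c(5, 55))
  expect_error(within_type_de(nn, cl_bad, 1L, 2L, sinet_config()), ">= 10")
})

test_that("meta-program scoring separates planted loadings and handles degenerate input", {
  set.seed(15)
  ng <- 300; n <- 80
  vals <- matrix(rnorm(ng * n), ng,
                 dimnames = list(sprintf("g%03d", 1:ng),
                                 sprintf("S1_c%03d", 1:n)))
  progs <- list(pericyte = sprintf("g%03d", 1:30),
                myofibro = sprintf("g%03d", 31:60))
  vals[progs$pericyte, 1:40] <- vals[progs$pericyte, 1:40] + 2
  vals[progs$myofibro, 41:80] <- vals[progs$myofibro, 41:80] + 2
  nn <- toy_norm(vals)
  mp <- score_metaprograms(nn, colnames(vals), progs, k = 2)
  truth <- rep(1:2, each = 40)
  tab <- table(mp$cell_cluster$cluster, truth)
  purity <- sum(apply(tab, 1, max)) / n
  expect_gte(purity, 0.95)
  # score matrix invariant to gene order within a program
  mp2 <- score_metaprograms(nn, colnames(vals),
                            lapply(progs, rev), k = 2)
  expect_equal(dplyr::arrange(mp2$scores, cell_id, signature)$score,
               dplyr::arrange(mp$scores, cell_id, signature)$score)
  # a single program: degenerate, clustering skipped with warning
  expect_warning(one <- score_metaprograms(nn, colnames(vals),
                                           progs["pericyte"]),
                 "clustering skipped")
  expect_equal(unique(one$cell_cluster$cluster), 1L)
})

test_that("subtype DE flags a planted MIF-like gene in every cell type and negates under swap", {
  co <- small_cohort(1)
  cfg <- sinet_config(rng_seed = 1)
  norms_unc <- lapply(co$samples, function(x) {
    normalize_tpm(suppressMessages(qc_filter_cells(x, cfg)))
  })
  retained <- lapply(norms_unc, function(nn) {
    rownames(filter_genes(nn, cfg)$values)
  })
  ann <- co$truth$cells[, c("sample_id", "cell_id", "cell_type")]
  sub_calls <- tibble::tibble(profile_id = co$truth$samples$sample_id,
                              subtype = co$truth$samples$subtype)
  sde <- suppressWarnings(
    subtype_de_per_celltype(norms_unc, ann, sub_calls, cfg,
                            genes = unique(unlist(retained))))
  mif <- co$design$blocks$mif
  mif_rows <- sde[sde$gene == mif, ]
  shared_types <- c("NE", "T", "B_plasma", "Macrophage", "Fibroblast",
                    "Endothelial")
  tested <- intersect(shared_types, mif_rows$cell_type)
  expect_gte(length(tested), 5L)
  expect_true(all(mif_rows$is_de[mif_rows$cell_type %in% tested]))
  expect_true(all(mif_rows$log2_fc > 0))
  # in TME cell types nothing else separates the subtypes, so the MIF-like
  # gene tops the fold-change ordering there (in NE cells the planted
  # pattern-1 program genes legitimately outrank it)
  for (ct in c("T", "Macrophage", "Fibroblast")) {
    rows <- sde[sde$cell_type == ct, ]
    expect_true(mif %in% head(rows$gene, 3))
  }
  # swapping subtype labels negates all fold changes
  sw <- sub_calls
  sw$subtype <- ifelse(sw$subtype == "epithelial_like", "neuronal_like",
                       "epithelial_like")
  sde_sw <- suppressWarnings(
    subtype_de_per_celltype(norms_unc, ann, sw, cfg,
                            genes = unique(unlist(retained))))
  j <- dplyr::inner_join(sde, sde_sw, by = c("gene", "cell_type"))
  expect_equal(j$log2_fc.x, -j$log2_fc.y, tolerance = 1e-12)
})

test_that("bulk scores, outlier rule, and correlations match direct formulas", {
  set.seed(16)
  ng <- 200; n <- 30
  tpm <- matrix(stats::rgamma(ng * n, 2, 0.01), ng,
                dimnames = list(sprintf("g%03d", 1:ng), sprintf("P%02d", 1:n)))
  tpm <- t(t(tpm) / colSums(tpm)) * 1e6
  markers <- list(NE = sprintf("g%03d", 1:20), B = sprintf("g%03d", 21:40))
  cyc <- sprintf("g%03d", 41:60)
  bc <- bulk_scores_and_correlations(tpm, markers, cyc, sinet_config())
  logv <- log2(tpm + 1)
  ne <- colMeans(logv[markers$NE, ]); b <- colMeans(logv[markers$B, ])
  cy <- colMeans(logv[cyc, ])
  keep <- ne >= mean(ne) - 2 * sd(ne)
  r_direct <- sum((b[keep] - mean(b[keep])) * (cy[keep] - mean(cy[keep]))) /
    sqrt(sum((b[keep] - mean(b[keep]))^2) * sum((cy[keep] - mean(cy[keep]))^2))
  expect_equal(bc$correlations$r[bc$correlations$cell_type == "B"], r_direct,
               tolerance = 1e-12)
  expect_true(all(abs(bc$correlations$r) <= 1))
  # planted low-NE outlier is excluded
  tpm2 <- tpm
  tpm2[markers$NE, 1] <- 0
  tpm2 <- t(t(tpm2) / colSums(tpm2)) * 1e6
  bc2 <- bulk_scores_and_correlations(tpm2, markers, cyc, sinet_config())
  expect_true("P01" %in% bc2$excluded)
  # degenerate: constant cycle score -> explicit error
  tpm3 <- tpm; tpm3[cyc, ] <- 100
  tpm3 <- t(t(tpm3) / colSums(tpm3)) * 1e6
  # renormalisation breaks exact constancy; force it on the log scale instead
  expect_error(
    bulk_scores_and_correlations(
      matrix(1, ng, 12, dimnames = list(rownames(tpm), sprintf("Q%02d", 1:12))) *
        1e6 / ng,
      markers, cyc, sinet_config()),
    "constant")
  # fewer than 10 profiles or zero marker overlap error
  expect_error(bulk_scores_and_correlations(tpm[, 1:5], markers, cyc),
               ">= 10")
  expect_error(bulk_scores_and_correlations(tpm, list(NE = "zz"), cyc),
               "no genes")
})
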