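planted_two_types <- function(seed = 1, n1 = 120, n2 = 80, ng = 400) {
  set.seed(seed)
  vals <- matrix(rnorm(ng * (n1 + n2), 0, 1), ng,
                 dimnames = list(sprintf("g%03d", seq_len(ng)),
                                 sprintf("S1_c%03d", seq_len(n1 + n2))))
  vals[1:40, seq_len(n1)] <- vals[1:40, seq_len(n1)] + 3
  vals[41:80, n1 + seq_len(n2)] <- vals[41:80, n1 + seq_len(n2)] + 3
  list(norm = toy_norm(vals), truth = rep(1:2, c(n1, n2)))
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab)); si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab))); n <- comb2(sum(tab))
  (sij - si * sj / n) / ((si + sj) / 2 - si * sj / n)
}

test_that("clustering recovers a planted two-type partition exactly", {
  pl <- planted_two_types()
  cl <- cluster_cells(pl$norm, sinet_config(rng_seed = 1))
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(adjusted_rand(cl$cluster, pl$truth), 1.0)
})

test_that("clustering handles degenerate inputs and is order invariant", {
  # all-identical cells -> one cluster
  flat <- toy_norm(matrix(0, 50, 30,
                          dimnames = list(sprintf("g%02d", 1:50),
                                          sprintf("S1_c%02d", 1:30))),
                   centered = FALSE)
  flat$centered <- TRUE
  expect_equal(unique(cluster_cells(flat, sinet_config())$cluster), 1L)
  # < 20 cells -> single cluster with warning
  tiny <- toy_norm(matrix(rnorm(50 * 10), 50, 10,
                          dimnames = list(sprintf("g%02d", 1:50),
                                          sprintf("S1_c%02d", 1:10))))
  expect_warning(cl <- cluster_cells(tiny, sinet_config()), "fewer than 20")
  expect_equal(unique(cl$cluster), 1L)
  # permuting cells leaves the partition unchanged up to relabeling
  pl <- planted_two_types(seed = 5)
  cl1 <- cluster_cells(pl$norm, sinet_config(rng_seed = 3))
  perm <- sample(ncol(pl$norm$values))
  normp <- pl$norm; normp$values <- pl$norm$values[, perm]
  cl2 <- cluster_cells(normp, sinet_config(rng_seed = 3))
  m <- dplyr::inner_join(cl1, cl2, by = "cell_id")
  expect_equal(adjusted_rand(m$cluster.x, m$cluster.y), 1.0)
})

test_that("signature scoring is the mean of centered values with zero per-sample mean", {
  set.seed(2)
  vals <- matrix(rnorm(200 * 60), 200, 60,
                 dimnames = list(sprintf("g%03d", 1:200),
                                 sprintf("S1_c%03d", 1:60)))
  nn <- toy_norm(vals)
  # single gene signature equals that gene's centered value
  s1 <- score_signature(nn, "g005", "one")
  expect_equal(s1$score, unname(nn$values["g005", ]))
  # multi-gene scores average the rows; per-sample mean ~ 0
  sig <- sprintf("g%03d", 1:40)
  sm <- score_signature(nn, sig, "forty")
  expect_equal(sm$score, unname(colMeans(nn$values[sig, ])))
  expect_lt(abs(mean(sm$score)), 1e-9)
  # zero-overlap errors name the signature; genes outside the matrix are logged
  expect_error(score_signature(nn, c("zz1", "zz2"), "ghost"), "ghost")
  expect_message(score_signature(nn, c("g001", "zz9"), "partial"), "1/2")
})

test_that("planted score shifts are recovered within the stated tolerance", {
  # cells carrying +2 on 40 signature genes score ~2 above background
  set.seed(4)
  ng <- 300; n <- 200
  vals <- matrix(rnorm(ng * n, 0, 1), ng,
                 dimnames = list(sprintf("g%03d", 1:ng),
                                 sprintf("S1_c%03d", 1:n)))
  hot <- 1:30
  vals[1:40, hot] <- vals[1:40, hot] + 2
  nn <- toy_norm(vals)
  sc <- score_signature(nn, sprintf("g%03d", 1:40), "prog")
  gap <- mean(sc$score[hot]) - mean(sc$score[-hot])
  expect_lt(abs(gap - 2), 0.2)
})

test_that("cluster annotation uses the margin rule and ignores within-cluster shuffles", {
  scores <- tibble::tibble(
    cell_id = rep(sprintf("c%02d", 1:10), 2),
    signature = rep(c("NE", "T"), each = 10),
    score = c(rep(2, 10), rep(0, 10)))
  cl <- tibble::tibble(sample_id = "S1", cell_id = sprintf("c%02d", 1:10),
                       cluster = 1L)
  ann <- annotate_clusters(cl, scores, sinet_config())
  expect_true(all(ann$cell_type == "NE"))
  # all marker scores within the margin -> Unknown
  tied <- scores; tied$score <- c(rep(1.0, 10), rep(0.9, 10))
  annt <- annotate_clusters(cl, tied, sinet_config(annotate_margin = 0.25))
  expect_true(all(annt$cell_type == "Unknown"))
  # shuffling cells within the cluster changes nothing (cluster-mean function)
  shuf <- scores[sample(nrow(scores)), ]
  expect_equal(annotate_clusters(cl, shuf, sinet_config())$cell_type,
               ann$cell_type)
})

test_that("on a synthetic cohort >= 95% of cells get their planted type", {
  co <- small_cohort(1)
  sig <- truth_signatures(co)
  cfg <- sinet_config(rng_seed = 1)
  acc <- vapply(names(co$samples), function(s) {
    qc <- suppressMessages(qc_filter_cells(co$samples[[s]], cfg))
    nn <- center_within_sample(filter_genes(normalize_tpm(qc), cfg))
    cl <- suppressWarnings(cluster_cells(nn, cfg))
    sc <- suppressWarnings(suppressMessages(
      score_signatures(nn, sig$markers, on_missing = "skip")))
    ann <- annotate_clusters(cl, sc, cfg)
    tr <- dplyr::inner_join(ann, co$truth$cells, by = c("sample_id", "cell_id"))
    mean(tr$cell_type.x == tr$cell_type.y)
  }, numeric(1))
  expect_true(all(acc >= 0.95))
})

test_that("group means equal per-cell score means and empty groups warn", {
  set.seed(9)
  vals <- matrix(rnorm(100 * 30), 100, 30,
                 dimnames = list(sprintf("g%03d", 1:100),
                                 sprintf("S1_c%02d", 1:30)))
  nn <- toy_norm(vals)
  sc <- score_signature(nn, sprintf("g%03d", 1:10), "sig")
  groups <- tibble::tibble(cell_id = sc$cell_id,
                           group = rep(c("a", "b"), 15))
  gm <- group_signature_means(sc, groups)
  expect_equal(gm$mean_score[gm$group == "a"],
               mean(sc$score[groups$group == "a"]), tolerance = 1e-12)
  # single-cell groups return the cell's own score
  solo <- tibble::tibble(cell_id = sc$cell_id[1], group = "only")
  expect_equal(group_signature_means(sc, solo)$mean_score, sc$score[1])
  # empty group dropped with warning
  withmiss <- dplyr::bind_rows(groups,
                               tibble::tibble(cell_id = "ghost", group = "z"))
  expect_warning(group_signature_means(sc, withmiss), "empty group")
})

test_that("epithelial/neuronal reference ordering holds for planted NE subtypes", {
  co <- small_cohort(1)
  sig <- truth_signatures(co)
  cfg <- sinet_config(rng_seed = 1)
  truth <- co$truth$cells
  sub_of <- setNames(co$truth$samples$subtype, co$truth$samples$sample_id)
  res <- lapply(names(co$samples), function(s) {
    qc <- suppressMessages(qc_filter_cells(co$samples[[s]], cfg))
    nn <- center_within_sample(filter_genes(normalize_tpm(qc), cfg))
    sc <- tryCatch(score_signature(nn, sig$epithelial_ref, "epi_ref"),
                   error = function(e) NULL)
    if (is.null(sc)) return(NULL)
    tr <- truth[truth$sample_id == s, ]
    dplyr::inner_join(sc, tr, by = c("sample_id", "cell_id")) |>
      dplyr::mutate(subtype = sub_of[s])
  })
  res <- dplyr::bind_rows(res)
  epi_ne <- mean(res$score[res$cell_type == "NE" &
                             res$subtype == "epithelial_like"])
  neu_ne <- mean(res$score[res$cell_type == "NE" &
                             res$subtype == "neuronal_like"])
  bona_fide <- mean(res$score[res$cell_type == "Epithelial"])
  expect_gt(epi_ne, neu_ne)
  expect_gt(bona_fide, epi_ne)
})
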