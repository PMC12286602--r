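#' Design of a synthetic SiNET cohort
#'
#' Describes the multi-tumor cohort the generator emulates: eight tumors
#' (three epithelial-like, five neuronal-like), tumor-specific cell-type
#' proportions over up to eight cell types (NK present in a single tumor,
#' bona fide epithelial cells in two), a shared NE marker program, a common
#' NE-specific program, nine subset-specific programs structured as binary
#' presence/absence patterns across tumors, per-tumor private NE genes, a
#' MIF-like cytokine upregulated in every cell type of epithelial-like
#' tumors, canonical G1/S and G2/M blocks with planted per-(cell type,
#' subtype) cycling fractions (NE 0.25%; B/plasma 32% in epithelial-like vs
#' 0.2% in neuronal-like), a germinal-center program in a subset of B cells,
#' and epithelial/neuronal reference blocks mildly shifted in the NE cells of
#' the corresponding subtype.
#'
#' Planted effects are expressed on the analysis scale `log2(TPM/10 + 1)`:
#' an effect `e` on a gene with baseline mean `b` multiplies the
#' negative-binomial mean so that the population-level logged value shifts by
#' `e` (i.e. `b' = 2^e (b+1) - 1`). Effect sizes default to values that
#' remain detectable after count noise compresses them (see the methods
#' vignette): common NE +5, subset/private +4.5, MIF-like +5, cycling +2.5 on
#' the cell's phase block, marker blocks at absolute level 9.3.
#'
#' @param n_tumors Number of tumors (default 8).
#' @param n_epithelial_like Tumors of the epithelial-like subtype (default 3;
#'   the first `n_epithelial_like` tumors).
#' @param n_cells Cells per tumor (default 600).
#' @param n_genes Total genes (default 5000).
#' @param dispersion Negative-binomial dispersion (default 0.5; `size = 1/d`).
#' @param cycling_fractions Named per-type cycling fractions; `B_plasma` is a
#'   two-vector (epithelial-like, neuronal-like).
#' @param effect_common,effect_subset,effect_private,effect_mif,effect_cycle
#'   Planted effect sizes (log2 analysis scale).
#' @param marker_level Absolute expression level (log2 scale) of marker genes
#'   in their own cell type.
#' @param effect_ref Shift of the epithelial/neuronal reference blocks in NE
#'   cells of the matching subtype.
#' @param zero_effects If TRUE, all planted effects (including markers and
#'   cycling) are removed: a pure negative-binomial null cohort used for
#'   calibration. Ground-truth labels are still emitted.
#' @param platforms Optional per-tumor platform vector ("cells"/"nuclei");
#'   default: the first three tumors are fresh (cells), the rest nuclei.
#' @param lib_meanlog Named vector of log mean library sizes per platform;
#'   default c(cells = log(9000), nuclei = log(7000)). Reduced designs with
#'   few genes need library sizes that keep detected-gene counts above the
#'   QC thresholds.
#' @return Object of class `sinet_design` (a list of tibbles and scalars).
#' @export
cohort_design <- function(n_tumors = 8,
                          n_epithelial_like = 3,
                          n_cells = 600,
                          n_genes = 5000,
                          dispersion = 0.5,
                          cycling_fractions = NULL,
                          effect_common = 5,
                          effect_subset = 4.5,
                          effect_private = 4.5,
                          effect_mif = 5,
                          effect_cycle = 2.5,
                          marker_level = 9.3,
                          effect_ref = 1.5,
                          zero_effects = FALSE,
                          platforms = NULL,
                          lib_meanlog = c(cells = log(9000),
                                          nuclei = log(7000))) {
  stopifnot(n_tumors >= 2, n_epithelial_like >= 1,
            n_epithelial_like < n_tumors)
  sample_id <- sprintf("T%d", seq_len(n_tumors))
  subtype <- rep(c("epithelial_like", "neuronal_like"),
                 c(n_epithelial_like, n_tumors - n_epithelial_like))
  platform <- platforms %||%
    rep(c("cells", "nuclei"),
        c(min(3, n_tumors - 1), n_tumors - min(3, n_tumors - 1)))
  stopifnot(length(platform) == n_tumors,
            all(platform %in% c("cells", "nuclei")))
  samples <- tibble::tibble(sample_id, subtype, platform,
                            n_cells = as.integer(n_cells))

  base_props <- c(NE = 0.48, T = 0.10, B_plasma = 0.09, Macrophage = 0.08,
                  Fibroblast = 0.11, Endothelial = 0.08)
  # NK in one tumor, bona fide epithelial in two; remainder goes to NE
  nk_tumor <- sample_id[min(5, n_tumors)]
  epi_tumors <- sample_id[unique(c(min(3, n_tumors), min(6, n_tumors)))]
  props <- purrr::map(sample_id, function(s) {
    p <- base_props
    extra <- 0.06
    if (s %in% epi_tumors) p <- c(p, Epithelial = extra) else
      if (s == nk_tumor) p <- c(p, NK = extra) else
        p["NE"] <- p["NE"] + extra
    # mild deterministic tumor-to-tumor variation in NE content
    shift <- 0.04 * ((match(s, sample_id) %% 3) - 1)
    p["NE"] <- p["NE"] + shift
    p["Fibroblast"] <- p["Fibroblast"] - shift
    p / sum(p)
  })
  proportions <- tibble::tibble(
    sample_id = rep(sample_id, lengths(props)),
    cell_type = unlist(lapply(props, names)),
    prop = unlist(props))

  if (is.null(cycling_fractions)) {
    cycling_fractions <- list(
      NE = 0.0025, T = 0.02, B_plasma = c(0.32, 0.002), Macrophage = 0.03,
      Fibroblast = 0.02, Endothelial = 0.025, Epithelial = 0.05, NK = 0.02)
  }

  # binary patterns of the subset-specific programs: pattern 1 marks the
  # epithelial-like tumors; the rest live among the neuronal-like tumors
  epi_idx <- seq_len(n_epithelial_like)
  neu_idx <- setdiff(seq_len(n_tumors), epi_idx)
  pat_members <- c(list(epi_idx), subset_pattern_members(neu_idx))
  pat_sizes <- c(26, 14, 12, 11, 10, 9, 9, 8, 8)[seq_along(pat_members)]

  gene_id <- sprintf("gene_%04d", seq_len(n_genes))
  types <- unique(proportions$cell_type)
  blocks <- list()
  cursor <- 0L
  take <- function(n) {
    out <- gene_id[cursor + seq_len(n)]
    cursor <<- cursor + n
    out
  }
  for (ct in types) blocks[[paste0("marker_", ct)]] <- take(40L)
  blocks$common_ne <- take(30L)
  for (i in seq_along(pat_members)) blocks[[paste0("pattern_", i)]] <- take(pat_sizes[i])
  for (s in sample_id) blocks[[paste0("private_", s)]] <- take(5L)
  blocks$mif <- take(1L)
  blocks$cycle_g1s <- take(40L)
  blocks$cycle_g2m <- take(50L)
  blocks$gc <- take(30L)
  blocks$epithelial_ref <- take(40L)
  blocks$neuronal_ref <- take(40L)
  if (cursor > n_genes) {
    stop("program gene sets exceed n_genes (need ", cursor, ")", call. = FALSE)
  }

  structure(list(
    samples = samples, proportions = proportions, blocks = blocks,
    patterns = pat_members, n_genes = n_genes, dispersion = dispersion,
    cycling_fractions = cycling_fractions, gene_id = gene_id,
    lib_meanlog = lib_meanlog,
    effects = list(common = effect_common, subset = effect_subset,
                   private = effect_private, mif = effect_mif,
                   cycle = effect_cycle, cycle_other = 0.8,
                   marker_level = marker_level, ref = effect_ref,
                   gc = 2),
    gc_fraction = 0.30,
    zero_effects = isTRUE(zero_effects)
  ), class = "sinet_design")
}

# fixed catalogue of subset patterns (2-5 members) over the neuronal tumors
subset_pattern_members <- function(neu_idx) {
  k <- length(neu_idx)
  picks <- list(c(1, 2), c(2, 3, 4), c(3, 4, 5), c(1, 3, 5), c(2, 4),
                c(1, 2, 3, 4), c(1, 4, 5), c(2, 3, 4, 5))
  picks <- purrr::keep(picks, ~ max(.x) <= k)
  lapply(picks, function(ix) neu_idx[ix])
}

#' @export
print.sinet_design <- function(x, ...) {
  cat("<sinet_design>", nrow(x$samples), "tumors,", x$n_genes, "genes,",
      sum(x$samples$n_cells), "cells;",
      sum(x$samples$subtype == "epithelial_like"), "epithelial-like /",
      sum(x$samples$subtype == "neuronal_like"), "neuronal-like\n")
  invisible(x)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws UMI counts from a negative-binomial model: cohort-level baseline
#' gene means from a log-normal, per-cell multiplicative program effects
#' (cell type markers, NE programs, cycling, germinal center, MIF-like,
#' reference blocks), log-normal library sizes (platform-specific), and
#' `NB(mean, size = 1/dispersion)` sampling. Fully reproducible from `seed`.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed for all randomness.
#' @return Object of class `sinet_cohort`: list with `samples` (named list of
#'   [sinet_counts]), `truth` (list of tibbles `cells`, `genes`, `samples`),
#'   and `design`.
#' @export
generate_cohort <- function(design, seed = 1L) {
  stopifnot(inherits(design, "sinet_design"))
  withr::with_seed(as.integer(seed), generate_cohort_impl(design))
}

generate_cohort_impl <- function(design) {
  G <- design$n_genes
  genes <- design$gene_id
  blocks <- design$blocks
  eff <- design$effects
  zero <- design$zero_effects

  baseline <- rlnorm(G, meanlog = log(8), sdlog = 1.2)
  names(baseline) <- genes
  # program genes get moderate, filter-safe baselines
  baseline[blocks$common_ne] <- rlnorm(length(blocks$common_ne), log(4), 0.4)
  for (nm in grep("^pattern_|^private_", names(blocks), value = TRUE)) {
    baseline[blocks[[nm]]] <- rlnorm(length(blocks[[nm]]), log(4), 0.4)
  }
  for (nm in grep("^marker_", names(blocks), value = TRUE)) {
    baseline[blocks[[nm]]] <- rlnorm(length(blocks[[nm]]), log(0.5), 0.3)
  }
  baseline[blocks$mif] <- 0.2
  baseline[blocks$cycle_g1s] <- rlnorm(length(blocks$cycle_g1s), log(35), 0.25)
  baseline[blocks$cycle_g2m] <- rlnorm(length(blocks$cycle_g2m), log(35), 0.25)
  baseline[blocks$gc] <- rlnorm(length(blocks$gc), log(25), 0.3)
  baseline[blocks$epithelial_ref] <- rlnorm(40, log(25), 0.3)
  baseline[blocks$neuronal_ref] <- rlnorm(40, log(25), 0.3)
  baseline <- baseline / sum(baseline) * 1e5  # TPM/10 scale

  shift_up <- function(w, e) 2^e * (w + 1) - 1  # effect on log2(TPM/10+1) scale
  size <- 1 / design$dispersion

  truth_cells <- list()
  counts_list <- list()
  for (i in seq_len(nrow(design$samples))) {
    smp <- design$samples[i, ]
    s <- smp$sample_id
    props <- design$proportions[design$proportions$sample_id == s, ]
    n <- smp$n_cells
    n_type <- floor(props$prop * n)
    rem <- n - sum(n_type)
    if (rem > 0) {
      ord <- order(props$prop * n - n_type, decreasing = TRUE)
      n_type[ord[seq_len(rem)]] <- n_type[ord[seq_len(rem)]] + 1L
    }
    cell_type <- sample(rep(props$cell_type, n_type))
    cyc_frac <- vapply(cell_type, function(ct) {
      f <- design$cycling_fractions[[ct]] %||% 0
      if (length(f) == 2) f <- if (smp$subtype == "epithelial_like") f[1] else f[2]
      f
    }, numeric(1))
    cycling <- if (zero) rep(FALSE, n) else runif(n) < cyc_frac
    phase <- ifelse(cycling, ifelse(runif(n) < 0.5, "G1S", "G2M"), NA)
    gc_like <- if (zero) rep(FALSE, n) else {
      cell_type == "B_plasma" & smp$subtype == "epithelial_like" &
        runif(n) < design$gc_fraction
    }

    # weight vector per expression class (type x phase x gc); cells of a class
    # share NB means up to library size
    class_key <- paste(cell_type, ifelse(cycling, phase, "none"),
                       ifelse(gc_like, "gc", "no"), sep = "|")
    lib_meanlog <- design$lib_meanlog[[smp$platform]]
    lib <- round(rlnorm(n, lib_meanlog, 0.3))
    counts <- matrix(0L, nrow = G, ncol = n,
                     dimnames = list(genes, sprintf("%s_c%04d", s, seq_len(n))))
    for (cls in unique(class_key)) {
      idx <- which(class_key == cls)
      parts <- strsplit(cls, "|", fixed = TRUE)[[1]]
      ct <- parts[1]; ph <- parts[2]; gc <- parts[3]
      w <- baseline
      if (!zero) {
        mk <- blocks[[paste0("marker_", ct)]]
        if (!is.null(mk)) w[mk] <- 2^eff$marker_level - 1
        if (ct == "NE") {
          w[blocks$common_ne] <- shift_up(w[blocks$common_ne], eff$common)
          for (pi in seq_along(design$patterns)) {
            if (i %in% design$patterns[[pi]]) {
              b <- blocks[[paste0("pattern_", pi)]]
              w[b] <- shift_up(w[b], eff$subset)
            }
          }
          pv <- blocks[[paste0("private_", s)]]
          w[pv] <- shift_up(w[pv], eff$private)
          if (smp$subtype == "epithelial_like") {
            w[blocks$epithelial_ref] <- shift_up(w[blocks$epithelial_ref], eff$ref)
          } else {
            w[blocks$neuronal_ref] <- shift_up(w[blocks$neuronal_ref], eff$ref)
          }
        }
        if (ct == "Epithelial") {
          w[blocks$epithelial_ref] <- shift_up(w[blocks$epithelial_ref], 3)
        }
        if (smp$subtype == "epithelial_like") {
          w[blocks$mif] <- shift_up(w[blocks$mif], eff$mif)
        }
        if (ph == "G1S") {
          w[blocks$cycle_g1s] <- shift_up(w[blocks$cycle_g1s], eff$cycle)
          w[blocks$cycle_g2m] <- shift_up(w[blocks$cycle_g2m], eff$cycle_other)
        } else if (ph == "G2M") {
          w[blocks$cycle_g2m] <- shift_up(w[blocks$cycle_g2m], eff$cycle)
          w[blocks$cycle_g1s] <- shift_up(w[blocks$cycle_g1s], eff$cycle_other)
        }
        if (gc == "gc") w[blocks$gc] <- shift_up(w[blocks$gc], eff$gc)
      }
      p <- w / sum(w)
      mu <- p %o% (lib[idx] / 1)        # genes x cells-in-class
      draw <- rnbinom(length(mu), size = size, mu = as.vector(mu))
      counts[, idx] <- matrix(as.integer(draw), nrow = G)
    }
    truth_cells[[s]] <- tibble::tibble(
      sample_id = s, cell_id = colnames(counts), cell_type = cell_type,
      cycling = cycling, phase = phase, gc_like = gc_like)
    counts_list[[s]] <- sinet_counts(counts, s, smp$platform)
  }

  truth_genes <- tibble::tibble(
    gene = unlist(blocks, use.names = FALSE),
    program = rep(names(blocks), lengths(blocks))) |>
    dplyr::mutate(
      tier = dplyr::case_when(
        .data$program == "common_ne" ~ "common",
        grepl("^pattern_", .data$program) ~ "subset_specific",
        grepl("^private_", .data$program) ~ "sample_specific",
        TRUE ~ NA_character_),
      pattern_index = dplyr::if_else(
        grepl("^pattern_", .data$program),
        suppressWarnings(as.integer(sub("^pattern_", "", .data$program))),
        NA_integer_))

  structure(list(samples = counts_list,
                 truth = list(cells = dplyr::bind_rows(truth_cells),
                              genes = truth_genes,
                              samples = design$samples),
                 design = design),
            class = "sinet_cohort")
}

#' @export
print.sinet_cohort <- function(x, ...) {
  cat("<sinet_cohort>", length(x$samples), "tumors,",
      nrow(x$truth$cells), "cells,", x$design$n_genes, "genes\n")
  invisible(x)
}

#' Ground-truth signature sets of a synthetic cohort
#'
#' Returns the planted gene blocks in the form the analysis functions expect:
#' cell-type marker sets, the G1/S and G2/M lists, the germinal-center set
#' and the epithelial/neuronal reference sets. In a real analysis these are
#' prior knowledge; in the synthetic world the planted blocks play that role.
#'
#' @param cohort A `sinet_cohort` (or `sinet_design`).
#' @return List with elements `markers` (named list), `cell_cycle` (list
#'   `G1S`, `G2M`), `gc`, `epithelial_ref`, `neuronal_ref`.
#' @export
truth_signatures <- function(cohort) {
  design <- if (inherits(cohort, "sinet_cohort")) cohort$design else cohort
  b <- design$blocks
  mk <- b[grep("^marker_", names(b))]
  names(mk) <- sub("^marker_", "", names(mk))
  list(markers = mk,
       cell_cycle = list(G1S = b$cycle_g1s, G2M = b$cycle_g2m),
       gc = b$gc,
       epithelial_ref = b$epithelial_ref,
       neuronal_ref = b$neuronal_ref,
       mif = b$mif)
}

#' Generate pseudobulk profiles from a synthetic cohort
#'
#' Each profile mixes cells sampled (with replacement) from the tumors of a
#' drawn subtype: the profile's NE content is drawn independently and
#' moderately (uniform over `ne_fraction_range`), while the remaining
#' tumor-microenvironment fraction is split by a Dirichlet draw around the
#' cohort's base proportions — so immune/stromal content (in particular the
#' B/plasma compartment, which can be follicle-rich) varies much more between
#' profiles than NE content, as in bulk NET cohorts. The chosen cells' counts
#' are summed and the column scaled to TPM (sums to 1e6). Compositions and
#' subtypes are recorded as ground truth.
#'
#' @param cohort A `sinet_cohort`.
#' @param n_profiles Number of bulk profiles (default 81; fewer than 10
#'   triggers a warning since the correlation stage becomes unstable).
#' @param subtype_mix Probability that a profile is epithelial-like
#'   (default 0.2).
#' @param n_cells_per_profile Cells mixed into each profile (default 300).
#' @param concentration Dirichlet concentration scale for the
#'   tumor-microenvironment composition noise (lower = more variable).
#' @param ne_fraction_range Range of the independently drawn NE fraction.
#' @param seed Integer seed.
#' @return List with `tpm` (genes x profiles matrix), `truth` (tibble
#'   `profile_id`, `subtype`, and per-type fractions in list-col `fractions`).
#' @export
generate_pseudobulk <- function(cohort, n_profiles = 81, subtype_mix = 0.2,
                                n_cells_per_profile = 300,
                                concentration = 10,
                                ne_fraction_range = c(0.45, 0.55),
                                seed = 1L) {
  stopifnot(inherits(cohort, "sinet_cohort"))
  if (n_profiles < 10) {
    warning("fewer than 10 bulk profiles; downstream correlations unstable",
            call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    cells <- cohort$truth$cells
    sub_of <- setNames(cohort$truth$samples$subtype,
                       cohort$truth$samples$sample_id)
    cells$subtype <- sub_of[cells$sample_id]
    base <- c(NE = 0.5, T = 0.1, B_plasma = 0.09, Macrophage = 0.08,
              Fibroblast = 0.1, Endothelial = 0.08, Epithelial = 0.05)
    all_counts <- do.call(cbind, lapply(cohort$samples, function(x) x$counts))
    profiles <- matrix(0, nrow = nrow(all_counts), ncol = n_profiles,
                       dimnames = list(rownames(all_counts),
                                       sprintf("P%03d", seq_len(n_profiles))))
    truth <- vector("list", n_profiles)
    for (j in seq_len(n_profiles)) {
      st <- if (runif(1) < subtype_mix) "epithelial_like" else "neuronal_like"
      pool <- cells[cells$subtype == st, ]
      avail <- intersect(names(base), unique(pool$cell_type))
      ne_frac <- runif(1, ne_fraction_range[1], ne_fraction_range[2])
      tme <- setdiff(avail, "NE")
      alpha <- base[tme] / sum(base[tme]) * concentration
      gam <- stats::rgamma(length(alpha), shape = alpha)
      frac <- setNames(numeric(length(avail)), avail)
      frac["NE"] <- ne_frac
      frac[tme] <- (1 - ne_frac) * gam / sum(gam)
      n_type <- stats::rmultinom(1, n_cells_per_profile, frac[avail])[, 1]
      picked <- unlist(purrr::map2(avail, n_type, function(ct, nt) {
        if (nt == 0) return(character())
        sample(pool$cell_id[pool$cell_type == ct], nt, replace = TRUE)
      }))
      mix <- rowSums(all_counts[, picked, drop = FALSE])
      profiles[, j] <- mix / sum(mix) * 1e6
      truth[[j]] <- tibble::tibble(
        profile_id = colnames(profiles)[j], subtype = st,
        fractions = list(setNames(as.numeric(n_type) / sum(n_type), avail)))
    }
    list(tpm = profiles, truth = dplyr::bind_rows(truth))
  })
}
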