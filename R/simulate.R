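#' Simulation configuration
#'
#' Parameters of the synthetic single-nucleus RNA-seq generator. The generator
#' emulates a malignant epithelial tumor sample: a majority-malignant cell
#' population carrying epithelial/mesenchymal/hybrid EMT states, stem-like and
#' glycolysis-shifted subpopulations, a non-malignant epithelial rest, planted
#' cluster identities, negative-binomial counts and log-normal library sizes.
#'
#' Default fractions state the simulated world once: 70% malignant cells (a
#' tumor-rich biopsy), 20% of malignant cells in the hybrid EMT state (the
#' published top-20% hybrid rule), 20% stem-like and 30% glycolytic, with
#' mean library size 5,000 counts (typical snRNA-seq depth) and
#' inverse-dispersion 2 (strongly overdispersed counts).
#'
#' @param n_cells total cells.
#' @param n_genes total genes; must accommodate all disjoint programs, i.e.
#'   `(7 + n_clusters) * program_size <= n_genes` (six signature programs, one
#'   malignant marker program, one identity program per planted cluster).
#' @param frac_malignant fraction of cells that are malignant.
#' @param frac_hybrid fraction of malignant cells in the hybrid EMT state;
#'   the non-hybrid remainder splits equally into epithelial and mesenchymal.
#' @param frac_stem fraction of malignant cells that are stem-like.
#' @param frac_glycolytic fraction of malignant cells that are glycolytic
#'   (the rest are oxidative).
#' @param state_correlation latent correlation in \[0, 1) between the hybrid,
#'   stem-like and glycolytic state assignments. The three flags are cut from
#'   a shared standard-normal propensity mixed with independent noise
#'   (`sqrt(state_correlation) * z + sqrt(1 - state_correlation) * noise`), so
#'   marginal fractions are exact while aggressive programs co-occur, the
#'   structure the initiation analysis assumes; 0 gives independent flags.
#' @param program_size genes per planted program (>= 5).
#' @param effect_size log-fold activation of program genes in carrier cells;
#'   hybrid cells carry both EMT programs at `effect_size / 2`.
#' @param dispersion negative-binomial inverse-dispersion (`size`).
#' @param lib_size_mean mean library size on the natural scale.
#' @param lib_size_sigma log-scale standard deviation of library sizes.
#' @param n_clusters planted cluster count.
#' @param seed RNG seed; identical configs give bit-identical datasets.
#' @return A list of class `SimulationConfig`.
#' @export
sim_config <- function(n_cells = 2000L,
                       n_genes = 2000L,
                       frac_malignant = 0.7,
                       frac_hybrid = 0.2,
                       frac_stem = 0.2,
                       frac_glycolytic = 0.3,
                       state_correlation = 0.6,
                       program_size = 50L,
                       effect_size = 2.0,
                       dispersion = 2.0,
                       lib_size_mean = 5000,
                       lib_size_sigma = 0.35,
                       n_clusters = 4L,
                       seed = 0L) {
  cfg <- list(
    n_cells = check_count(n_cells, "n_cells"),
    n_genes = check_count(n_genes, "n_genes"),
    frac_malignant = check_fraction(frac_malignant, "frac_malignant"),
    frac_hybrid = check_fraction(frac_hybrid, "frac_hybrid"),
    frac_stem = check_fraction(frac_stem, "frac_stem"),
    frac_glycolytic = check_fraction(frac_glycolytic, "frac_glycolytic"),
    state_correlation = {
      r <- check_fraction(state_correlation, "state_correlation")
      if (r >= 1) config_error("'state_correlation' must be < 1")
      r
    },
    program_size = check_count(program_size, "program_size", 5L),
    effect_size = {
      e <- check_positive(effect_size + 1, "effect_size + 1") - 1  # allow 0
      if (e < 0) config_error("'effect_size' must be non-negative")
      e
    },
    dispersion = check_positive(dispersion, "dispersion"),
    lib_size_mean = check_positive(lib_size_mean, "lib_size_mean"),
    lib_size_sigma = check_positive(lib_size_sigma, "lib_size_sigma"),
    n_clusters = check_count(n_clusters, "n_clusters"),
    seed = check_count(seed, "seed", 0L)
  )
  n_prog <- 7L + cfg$n_clusters
  if (n_prog * cfg$program_size > cfg$n_genes) {
    config_error(sprintf(
      "n_genes = %d cannot hold %d disjoint programs of %d genes each",
      cfg$n_genes, n_prog, cfg$program_size))
  }
  structure(cfg, class = c("SimulationConfig", "list"))
}

PROGRAM_NAMES <- c(REQUIRED_SETS, "malignant")

#' Simulate a single-nucleus RNA-seq dataset with planted structure
#'
#' Counts are drawn as `NB(mu = libsize_c * p_cg, size = dispersion)` where
#' `p_cg` is the cell's expected expression profile normalized to sum to one:
#' a log-normal gene baseline multiplied by `exp(effect_size)` on the genes of
#' every program the cell carries (`exp(effect_size / 2)` for the epithelial
#' and mesenchymal programs in hybrid cells). Library sizes are log-normal
#' with natural-scale mean `lib_size_mean`.
#'
#' Programs are pairwise-disjoint gene blocks: the six initiation signatures
#' (epithelial, mesenchymal, emt_drivers, stemness, glycolysis, oxphos), a
#' malignant marker program carried by every malignant cell, and one identity
#' program per planted cluster. Mesenchymal and hybrid cells carry the EMT
#' drivers; stem-like cells the stemness program; glycolytic cells the
#' glycolysis program and oxidative cells the OXPHOS program; non-malignant
#' cells are epithelial, oxidative and non-stem.
#'
#' @param config a [sim_config()].
#' @return A list with `counts` (an `ExpressionMatrix`), `truth` (a
#'   `data.frame` with per-cell `malignant`, `emt_state`, `stem`,
#'   `metabolic_state`, `cluster`, `aggressive` columns), `programs` (the
#'   program -> gene-id map, also covering cluster identity programs) and
#'   `signatures` (the six required sets plus the malignant markers, ready for
#'   the scoring pipeline) and `initiation_markers` (genes of the EMT-driver,
#'   stemness and glycolysis programs). `aggressive` marks hybrid & stem-like
#'   & glycolytic cells, the harness's ground truth for high initiation
#'   potential.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_local_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  n <- cfg$n_cells
  g <- cfg$n_genes
  ps <- cfg$program_size

  prog_names <- c(PROGRAM_NAMES, paste0("cluster_", seq_len(cfg$n_clusters)))
  gene_names <- sprintf("gene_%05d", seq_len(g))
  # disjoint blocks over a shuffled gene order, so program genes are not
  # systematically the first columns of the matrix
  perm <- sample.int(g)
  programs <- list()
  for (i in seq_along(prog_names)) {
    idx <- perm[((i - 1L) * ps + 1L):(i * ps)]
    programs[[prog_names[i]]] <- sort(gene_names[idx])
  }

  # --- per-cell states ------------------------------------------------------
  n_malig <- round(cfg$frac_malignant * n)
  malignant <- rep(FALSE, n)
  malignant[sample.int(n, n_malig)] <- TRUE
  mal_idx <- which(malignant)

  # hybrid / stem-like / glycolytic flags share a latent aggressiveness
  # propensity (Gaussian copula): marginal fractions are exact, co-occurrence
  # is controlled by state_correlation
  emt_state <- rep("epithelial", n)
  stem <- rep(FALSE, n)
  metabolic <- rep("oxidative", n)
  if (n_malig > 0L) {
    a <- sqrt(cfg$state_correlation)
    b <- sqrt(1 - cfg$state_correlation)
    z <- rnorm(n_malig)
    top_frac <- function(frac) {
      k <- round(frac * n_malig)
      u <- a * z + b * rnorm(n_malig)
      flags <- rep(FALSE, n_malig)
      if (k > 0L) flags[order(-u)[seq_len(k)]] <- TRUE
      flags
    }
    hybrid <- top_frac(cfg$frac_hybrid)
    emt_state[mal_idx[hybrid]] <- "hybrid"
    rest <- mal_idx[!hybrid]
    n_mes <- floor(length(rest) / 2)
    emt_state[sample(rest, n_mes)] <- "mesenchymal"
    stem[mal_idx[top_frac(cfg$frac_stem)]] <- TRUE
    metabolic[mal_idx[top_frac(cfg$frac_glycolytic)]] <- "glycolytic"
  }
  cluster <- sample.int(cfg$n_clusters, n, replace = TRUE)

  # --- expected expression --------------------------------------------------
  baseline <- rlnorm(g, meanlog = 0, sdlog = 1)
  names(baseline) <- gene_names
  s <- cfg$effect_size
  prog_cols <- lapply(programs, function(gs) match(gs, gene_names))

  logmult <- matrix(0, n, g)  # log activation per cell x gene
  add <- function(cells, prog, eff) {
    if (length(cells)) {
      logmult[cells, prog_cols[[prog]]] <<- logmult[cells, prog_cols[[prog]]] + eff
    }
  }
  add(which(emt_state == "epithelial"), "epithelial", s)
  add(which(emt_state == "mesenchymal"), "mesenchymal", s)
  add(which(emt_state == "hybrid"), "epithelial", s / 2)
  add(which(emt_state == "hybrid"), "mesenchymal", s / 2)
  add(which(emt_state %in% c("mesenchymal", "hybrid")), "emt_drivers", s)
  add(which(stem), "stemness", s)
  add(which(metabolic == "glycolytic"), "glycolysis", s)
  add(which(metabolic == "oxidative"), "oxphos", s)
  add(mal_idx, "malignant", s)
  for (k in seq_len(cfg$n_clusters)) {
    add(which(cluster == k), paste0("cluster_", k), s)
  }

  expected <- sweep(exp(logmult), 2L, baseline, "*")
  expected <- expected / rowSums(expected)           # per-cell proportions

  meanlog <- log(cfg$lib_size_mean) - cfg$lib_size_sigma^2 / 2
  libsize <- rlnorm(n, meanlog = meanlog, sdlog = cfg$lib_size_sigma)

  mu <- expected * libsize
  counts <- matrix(rnbinom(n * g, mu = mu, size = cfg$dispersion), n, g)
  cell_names <- sprintf("cell_%05d", seq_len(n))

  truth <- data.frame(
    cell_id = cell_names,
    malignant = malignant,
    emt_state = emt_state,
    stem = stem,
    metabolic_state = metabolic,
    cluster = cluster,
    aggressive = emt_state == "hybrid" & stem & metabolic == "glycolytic",
    stringsAsFactors = FALSE
  )

  list(
    counts = expression_matrix(counts, cell_names, gene_names, layer = "counts"),
    truth = truth,
    programs = programs,
    signatures = programs[PROGRAM_NAMES],
    # genes planted to rise in high-initiation cells: the programs defining
    # the aggressive (hybrid & stem-like & glycolytic) phenotype
    initiation_markers = sort(unique(unlist(
      programs[c("emt_drivers", "stemness", "glycolysis")]))),
    config = cfg
  )
}

#' Area under the ROC curve against a planted label
#'
#' Computed as the Mann-Whitney U statistic divided by `n_pos * n_neg`; tied
#' scores count one half.
#'
#' @param score per-cell numeric score.
#' @param label per-cell logical (or 0/1) label.
#' @return AUROC in \[0, 1\].
#' @export
truth_roc <- function(score, label) {
  label <- as.logical(label)
  if (length(score) != length(label)) data_error("score and label lengths differ")
  if (any(is.na(score)) || any(is.na(label))) data_error("NA in score or label")
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L) {
    data_error("AUROC undefined: need at least one positive and one negative label")
  }
  r <- rank(score)  # midranks handle ties as 1/2
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Write a simulated dataset to disk
#'
#' Counts as a Matrix Market triplet directory, ground truth as TSV,
#' signatures (all planted programs) as GMT, and the simulation config as JSON.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$counts, file.path(dir, "counts"))
  write_tsv(sim$truth, file.path(dir, "ground_truth.tsv"))
  write_gmt(sim$programs, file.path(dir, "signatures.gmt"))
  write_config(sim$config, file.path(dir, "sim_config.json"))
  invisible(dir)
}
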