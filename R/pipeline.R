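#' Run the full Molecular Initiation Score pipeline
#'
#' Stages, in fixed order:
#' 1. QC filtering, library-size normalization, log transform.
#' 2. HVG selection, PCA, kNN graph, Louvain clustering of all retained cells.
#' 3. Malignant-cell isolation: user labels if given, otherwise the
#'    cluster-median rule on the `malignant` signature set.
#' 4. On malignant cells only: per-cell signature scores E, M, D, S, G, O with
#'    binned-control scoring; min-max normalization; hybrid EMT
#'    `H = min(E_hat, M_hat)` with the top-`(1 - q_hybrid)` flag; metabolic
#'    ratio `R = (G_hat + eps) / (O_hat + eps)`, normalized to `R_hat`.
#' 5. PC1 integration of `(D_hat, H, S_hat, R_hat)` (plus any extra feature
#'    columns) into the Molecular Initiation Score `I`, with the
#'    top-`(1 - q_init)` high-initiation flag.
#' 6. Louvain re-clustering of the malignant cells and cluster-level
#'    aggregation of `I`.
#' 7. Rank-sum DE (high vs rest), BH correction, and hypergeometric ORA of
#'    the significantly upregulated genes against the signature collection.
#'
#' @param counts an `ExpressionMatrix` with layer `"counts"`.
#' @param signatures named list of gene sets; must contain the six required
#'   initiation sets, plus `malignant` when `malignant_labels` is not given.
#' @param config a [pipeline_config()].
#' @param malignant_labels optional logical per-cell labels (in the order of
#'   `counts`); cells dropped by QC are dropped from the labels too.
#' @param extra_features optional per-cell numeric matrix of additional
#'   normalized \[0, 1\] features (rownames = cell ids) appended to the
#'   integration, e.g. a genetic-alteration burden.
#' @return A list with `per_cell` (scores table), `cluster_summary`,
#'   `de_table`, `ora_table`, `model` (the `IntegrationModel`),
#'   `init_threshold`, `hybrid_threshold`, `top_cluster`, `qc`, `config`,
#'   and bookkeeping counts.
#' @export
run_initiation_pipeline <- function(counts, signatures,
                                    config = pipeline_config(),
                                    malignant_labels = NULL,
                                    extra_features = NULL) {
  validate_signatures(signatures)
  if (is.null(malignant_labels) && is.null(signatures$malignant)) {
    config_error("need malignant_labels or a 'malignant' signature set")
  }

  qcres <- qc_filter(counts, config)
  filtered <- qcres$matrix
  if (!is.null(malignant_labels)) {
    if (length(malignant_labels) != nrow(counts$X)) {
      data_error("malignant_labels length != number of input cells")
    }
    malignant_labels <- malignant_labels[qcres$qc$kept]
  }
  lognorm <- normalize_log1p(filtered, config$target_sum)

  n_hvg <- min(config$n_hvg, ncol(lognorm$X))
  hvg <- select_hvg(lognorm, n_hvg)
  emb <- pca_embed(subset_cells(lognorm, genes = hvg),
                   min(config$n_pcs, min(nrow(lognorm$X) - 1L, n_hvg)))
  graph <- knn_graph(emb, min(config$knn_k, nrow(lognorm$X) - 1L))
  clusters_all <- louvain_cluster(graph, config$louvain_resolution,
                                  config$louvain_seed)

  malignant <- flag_malignant(lognorm, clusters_all,
                              malignant_signature = signatures$malignant,
                              labels = malignant_labels, config = config)
  if (sum(malignant) < 3L) data_error("fewer than 3 malignant cells after isolation")
  mal <- subset_cells(lognorm, cells = which(malignant))

  score_one <- function(set) {
    score_gene_set(mal, signatures[[set]], n_bins = config$n_bins,
                   ctrl_size = config$ctrl_size, seed = config$score_seed)
  }
  E <- score_one("epithelial"); M <- score_one("mesenchymal")
  D <- score_one("emt_drivers"); S <- score_one("stemness")
  G <- score_one("glycolysis"); O <- score_one("oxphos")

  E_hat <- minmax_normalize(E); M_hat <- minmax_normalize(M)
  D_hat <- minmax_normalize(D); S_hat <- minmax_normalize(S)
  G_hat <- minmax_normalize(G); O_hat <- minmax_normalize(O)
  H <- hybrid_emt(E_hat, M_hat)
  hyb <- classify_top_quantile(H, config$q_hybrid)
  R <- metabolic_ratio(G_hat, O_hat, config$eps)
  R_hat <- minmax_normalize(R)

  F <- cbind(D_hat = D_hat, H = H, S_hat = S_hat, R_hat = R_hat)
  if (!is.null(extra_features)) {
    ef <- as.matrix(extra_features)
    if (nrow(ef) != nrow(F)) {
      ef <- ef[match(cell_ids(mal), rownames(ef)), , drop = FALSE]
      if (any(is.na(ef))) data_error("extra_features missing some malignant cells")
    }
    F <- cbind(F, ef)
  }
  model <- fit_integration(F, eps = config$eps)
  I <- initiation_score(F, model)
  hi <- classify_top_quantile(I, config$q_init)

  # re-cluster the malignant compartment for state mapping and aggregation
  n_mal <- nrow(mal$X)
  hvg_mal <- select_hvg(mal, min(n_hvg, ncol(mal$X)))
  emb_mal <- pca_embed(subset_cells(mal, genes = hvg_mal),
                       min(config$n_pcs, min(n_mal - 1L, length(hvg_mal))))
  graph_mal <- knn_graph(emb_mal, min(config$knn_k, n_mal - 1L))
  clusters_mal <- louvain_cluster(graph_mal, config$louvain_resolution,
                                  config$louvain_seed)
  agg <- aggregate_by_cluster(I, clusters_mal)

  de <- rank_sum_de(mal, hi$flags)
  up <- de$gene[de$q < config$alpha & de$log2fc > 0]
  ora <- ora_enrichment(up, signatures[REQUIRED_SETS], universe = de$gene)

  per_cell <- data.frame(
    cell_id = cell_ids(mal),
    E = E, M = M, D = D, S = S, G = G, O = O,
    E_hat = E_hat, M_hat = M_hat, H = H, S_hat = S_hat, D_hat = D_hat,
    R = R, R_hat = R_hat,
    initiation_score = I,
    hybrid_flag = hyb$flags,
    high_init_flag = hi$flags,
    cluster = clusters_mal,
    stringsAsFactors = FALSE
  )
  rownames(per_cell) <- NULL

  list(
    per_cell = per_cell,
    cluster_summary = agg$table,
    de_table = de,
    ora_table = ora,
    model = model,
    init_threshold = hi$threshold,
    hybrid_threshold = hyb$threshold,
    top_cluster = agg$top_cluster,
    qc = qcres$qc,
    clusters_all = clusters_all,
    malignant = malignant,
    embedding = emb,
    config = config,
    n_cells_qc = nrow(lognorm$X),
    n_genes_qc = ncol(lognorm$X),
    n_malignant = n_mal
  )
}
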