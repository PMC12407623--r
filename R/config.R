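#' Pipeline configuration
#'
#' All tunable parameters of the initiation-scoring pipeline. Defaults follow
#' common single-cell practice (QC and HVG settings) and the published
#' classification rules: the hybrid-EMT flag takes the top 20% of cells by
#' hybrid score (`q_hybrid = 0.80`) and the high-initiation flag the top 25%
#' by Molecular Initiation Score (`q_init = 0.75`).
#'
#' @param min_genes_per_cell minimum detected genes for a cell to pass QC.
#' @param min_cells_per_gene minimum cells in which a gene must be detected.
#' @param max_mito_frac maximum mitochondrial-count fraction per cell.
#' @param mito_prefix gene-id prefix identifying mitochondrial genes.
#' @param target_sum per-cell total after library-size normalization.
#' @param n_hvg number of highly variable genes.
#' @param n_pcs number of principal components for the embedding.
#' @param knn_k neighbors per cell in the kNN graph.
#' @param louvain_resolution Louvain resolution parameter.
#' @param louvain_seed seed for the Louvain node-sweep order.
#' @param n_bins expression bins for control-gene matching in signature scoring.
#' @param ctrl_size control genes drawn per signature gene.
#' @param score_seed seed for the control-gene draws.
#' @param eps pseudocount for the glycolysis-to-OXPHOS ratio (on normalized
#'   scores, so a bare 0/0 is never formed).
#' @param q_hybrid quantile defining the hybrid-EMT flag (cells at or above
#'   this quantile of the hybrid score are flagged).
#' @param q_init quantile defining the high-initiation flag.
#' @param alpha BH false-discovery-rate level for DE and ORA significance.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(min_genes_per_cell = 200L,
                            min_cells_per_gene = 3L,
                            max_mito_frac = 0.2,
                            mito_prefix = "MT-",
                            target_sum = 1e4,
                            n_hvg = 2000L,
                            n_pcs = 50L,
                            knn_k = 15L,
                            louvain_resolution = 1.0,
                            louvain_seed = 0L,
                            n_bins = 25L,
                            ctrl_size = 50L,
                            score_seed = 0L,
                            eps = 0.01,
                            q_hybrid = 0.80,
                            q_init = 0.75,
                            alpha = 0.05) {
  cfg <- list(
    min_genes_per_cell = check_count(min_genes_per_cell, "min_genes_per_cell", 0L),
    min_cells_per_gene = check_count(min_cells_per_gene, "min_cells_per_gene", 0L),
    max_mito_frac = check_fraction(max_mito_frac, "max_mito_frac"),
    mito_prefix = as.character(mito_prefix),
    target_sum = check_positive(target_sum, "target_sum"),
    n_hvg = check_count(n_hvg, "n_hvg"),
    n_pcs = check_count(n_pcs, "n_pcs"),
    knn_k = check_count(knn_k, "knn_k"),
    louvain_resolution = check_positive(louvain_resolution, "louvain_resolution"),
    louvain_seed = check_count(louvain_seed, "louvain_seed", 0L),
    n_bins = check_count(n_bins, "n_bins"),
    ctrl_size = check_count(ctrl_size, "ctrl_size"),
    score_seed = check_count(score_seed, "score_seed", 0L),
    eps = check_positive(eps, "eps"),
    q_hybrid = check_fraction(q_hybrid, "q_hybrid", open = TRUE),
    q_init = check_fraction(q_init, "q_init", open = TRUE),
    alpha = check_fraction(alpha, "alpha", open = TRUE)
  )
  structure(cfg, class = c("PipelineConfig", "list"))
}

#' Read a pipeline or simulation configuration file
#'
#' Dispatches on extension: `.yaml`/`.yml` are parsed with the yaml package,
#' `.json` with jsonlite. Unknown keys are rejected so typos fail loudly.
#'
#' @param path configuration file.
#' @param type `"pipeline"` or `"simulation"`.
#' @return A `PipelineConfig` or `SimulationConfig`.
#' @export
read_config <- function(path, type = c("pipeline", "simulation")) {
  type <- match.arg(type)
  if (!file.exists(path)) format_error(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    format_error(sprintf("unsupported config extension '.%s' (use yaml or json)", ext))
  )
  if (!is.list(raw)) format_error("config file must hold a key: value mapping")
  ctor <- if (type == "pipeline") pipeline_config else sim_config
  known <- names(formals(ctor))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    config_error(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  }
  do.call(ctor, raw)
}

#' Write a configuration as JSON
#' @param cfg a `PipelineConfig` or `SimulationConfig`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

config_hash <- function(cfg) {
  digest::digest(unclass(cfg), algo = "sha256")
}
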