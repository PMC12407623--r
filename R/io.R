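REQUIRED_SETS <- c("epithelial", "mesenchymal", "emt_drivers",
                   "stemness", "glycolysis", "oxphos")

#' Read a count matrix
#'
#' Accepts either a Matrix Market triplet directory (`matrix.mtx` or
#' `matrix.mtx.gz`, plus `barcodes.tsv` and `features.tsv`) in the usual
#' gene-major orientation, which is transposed to cells x genes, or a dense
#' CSV with a header row of gene ids and the first column holding cell ids.
#'
#' @param path directory with the Matrix Market triplet, or a `.csv` file.
#' @return An `ExpressionMatrix` with layer `"counts"`.
#' @export
read_counts <- function(path) {
  if (dir.exists(path)) {
    read_counts_mtx(path)
  } else if (file.exists(path)) {
    if (tolower(tools::file_ext(path)) != "csv") {
      format_error("file input must be a dense .csv (or pass a Matrix Market directory)")
    }
    read_counts_csv(path)
  } else {
    format_error(sprintf("no such file or directory: %s", path))
  }
}

read_counts_mtx <- function(dir) {
  mtx <- file.path(dir, c("matrix.mtx", "matrix.mtx.gz"))
  mtx <- mtx[file.exists(mtx)][1]
  if (is.na(mtx)) format_error(sprintf("no matrix.mtx[.gz] under %s", dir))
  barcodes <- file.path(dir, "barcodes.tsv")
  features <- file.path(dir, "features.tsv")
  for (f in c(barcodes, features)) {
    if (!file.exists(f)) format_error(sprintf("missing %s", f))
  }
  m <- Matrix::readMM(mtx)  # genes x cells
  bc <- readLines(barcodes)
  ft <- read.delim(features, header = FALSE, stringsAsFactors = FALSE)[[1]]
  if (ncol(m) != length(bc)) {
    format_error(sprintf("matrix declares %d cells but barcodes.tsv has %d lines",
                         ncol(m), length(bc)))
  }
  if (nrow(m) != length(ft)) {
    format_error(sprintf("matrix declares %d genes but features.tsv has %d lines",
                         nrow(m), length(ft)))
  }
  expression_matrix(Matrix::t(m), cell_ids = bc, gene_ids = ft, layer = "counts")
}

read_counts_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) format_error("dense CSV needs a cell-id column plus gene columns")
  cells <- as.character(df[[1]])
  x <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(x)) data_error("dense CSV has non-numeric entries")
  expression_matrix(x, cell_ids = cells, gene_ids = colnames(df)[-1],
                    layer = "counts")
}

#' Write a count matrix as a Matrix Market triplet directory
#'
#' Emits `matrix.mtx` (genes x cells, the conventional orientation),
#' `barcodes.tsv` and `features.tsv` under `dir`.
#'
#' @param m an `ExpressionMatrix` with layer `"counts"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(m, dir) {
  stopifnot_layer(m, "counts")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(m$X), file.path(dir, "matrix.mtx"))
  writeLines(cell_ids(m), file.path(dir, "barcodes.tsv"))
  writeLines(gene_ids(m), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read gene signatures from a GMT file
#'
#' GMT is tab-separated: set name, description, then gene ids. Duplicate genes
#' within a line are dropped with a warning.
#'
#' @param path GMT file.
#' @return Named list of character vectors (a gene-set collection).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such GMT file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      format_error(sprintf("malformed GMT line (need name, description, >=1 gene): %s",
                           substr(ln, 1, 60)))
    }
    nm <- parts[1]
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': %d duplicate gene(s) dropped",
                      nm, sum(duplicated(genes))))
      genes <- unique(genes)
    }
    if (nm %in% names(sets)) format_error(sprintf("duplicate GMT set name '%s'", nm))
    sets[[nm]] <- genes
  }
  sets
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "metascore", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Validate that a collection holds the required initiation signatures
#'
#' The pipeline needs epithelial, mesenchymal, EMT-driver, stemness,
#' glycolysis and OXPHOS sets; each must be non-empty.
#'
#' @param sets named list from [read_gmt()].
#' @param required set names that must be present.
#' @return `sets`, invisibly.
#' @export
validate_signatures <- function(sets, required = REQUIRED_SETS) {
  missing <- setdiff(required, names(sets))
  if (length(missing)) {
    config_error(sprintf("missing required signature set(s): %s",
                         paste(missing, collapse = ", ")))
  }
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty)) {
    config_error(sprintf("empty signature set(s): %s", paste(empty, collapse = ", ")))
  }
  invisible(sets)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write pipeline result tables
#'
#' Emits `per_cell_scores.tsv`, `cluster_summary.tsv`, `de_table.tsv`,
#' `ora_table.tsv` and a machine-readable `run_report.json` holding the
#' configuration, its hash and all seeds. No timestamps are written, so two
#' identical runs produce byte-identical output.
#'
#' @param result a result list from [run_initiation_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create %s", out_dir), "metascore_io_error")
  write_tsv(result$per_cell, file.path(out_dir, "per_cell_scores.tsv"))
  write_tsv(result$cluster_summary, file.path(out_dir, "cluster_summary.tsv"))
  write_tsv(result$de_table, file.path(out_dir, "de_table.tsv"))
  write_tsv(result$ora_table, file.path(out_dir, "ora_table.tsv"))
  cfg <- result$config
  report <- list(
    package_version = as.character(utils::packageVersion("metascore")),
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    seeds = list(score_seed = cfg$score_seed, louvain_seed = cfg$louvain_seed),
    n_cells_qc = result$n_cells_qc,
    n_genes_qc = result$n_genes_qc,
    n_malignant = result$n_malignant,
    init_threshold = result$init_threshold,
    hybrid_threshold = result$hybrid_threshold,
    integration_weights = as.list(result$model$weights),
    top_cluster = result$top_cluster,
    top_markers = utils::head(result$de_table$gene, 10L)
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
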