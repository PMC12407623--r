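#' Cell x gene expression matrix
#'
#' Light container for a cells x genes expression matrix with a layer tag
#' distinguishing raw counts from log-normalized values. The matrix is stored
#' sparse (`Matrix::dgCMatrix`) with cell ids as row names and gene ids as
#' column names.
#'
#' @param x numeric matrix or Matrix, cells in rows, genes in columns.
#' @param cell_ids character vector of cell identifiers (defaults to rownames).
#' @param gene_ids character vector of gene identifiers (defaults to colnames).
#' @param layer `"counts"` (non-negative integers) or `"lognorm"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `X` (sparse cells x genes matrix) and `layer`.
#' @examples
#' m <- expression_matrix(matrix(0:5, 2, 3), c("c1", "c2"), c("g1", "g2", "g3"))
#' dim(m)
#' @export
expression_matrix <- function(x, cell_ids = rownames(x), gene_ids = colnames(x),
                              layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  if (is.null(cell_ids) || is.null(gene_ids)) {
    format_error("expression_matrix: cell and gene ids are required")
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(x) != length(cell_ids) || ncol(x) != length(gene_ids)) {
    format_error(sprintf(
      "expression_matrix: matrix is %d x %d but %d cell ids and %d gene ids given",
      nrow(x), ncol(x), length(cell_ids), length(gene_ids)))
  }
  if (anyDuplicated(cell_ids)) format_error("duplicate cell ids")
  if (anyDuplicated(gene_ids)) format_error("duplicate gene ids")
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  X <- methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
  vals <- X@x
  if (any(!is.finite(vals))) data_error("expression matrix contains NaN/Inf")
  if (layer == "counts") {
    if (any(vals < 0) || any(vals != round(vals))) {
      data_error("counts layer must be non-negative integers")
    }
  }
  dimnames(X) <- list(cell_ids, gene_ids)
  structure(list(X = X, layer = layer), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$X)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$X)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d cells x %d genes (%.1f%% nonzero)\n",
              x$layer, nrow(x$X), ncol(x$X),
              100 * length(x$X@x) / prod(dim(x$X))))
  invisible(x)
}

#' Cell and gene identifiers
#' @param m an `ExpressionMatrix`.
#' @return Character vector of ids.
#' @export
cell_ids <- function(m) rownames(m$X)

#' @rdname cell_ids
#' @export
gene_ids <- function(m) colnames(m$X)

#' Subset an ExpressionMatrix
#' @param m an `ExpressionMatrix`.
#' @param cells,genes index vectors (logical, integer or character); `NULL`
#'   keeps everything.
#' @return An `ExpressionMatrix` with the same layer.
#' @export
subset_cells <- function(m, cells = NULL, genes = NULL) {
  X <- m$X
  if (!is.null(cells)) X <- X[cells, , drop = FALSE]
  if (!is.null(genes)) X <- X[, genes, drop = FALSE]
  structure(list(X = X, layer = m$layer), class = "ExpressionMatrix")
}

as_dense <- function(m) as.matrix(m$X)

stopifnot_layer <- function(m, layer) {
  if (!inherits(m, "ExpressionMatrix")) {
    format_error("expected an ExpressionMatrix")
  }
  if (m$layer != layer) {
    data_error(sprintf("expected layer '%s' but got '%s'", layer, m$layer))
  }
  invisible(m)
}
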