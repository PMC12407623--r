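#' Per-cell QC metrics
#'
#' @param m an `ExpressionMatrix` with layer `"counts"`.
#' @param mito_prefix gene-id prefix identifying mitochondrial genes.
#' @return `data.frame` with `cell_id`, `n_genes_detected`, `total_counts`,
#'   `mito_frac`.
#' @export
qc_metrics <- function(m, mito_prefix = "MT-") {
  stopifnot_layer(m, "counts")
  X <- m$X
  detected <- Matrix::rowSums(X > 0)
  total <- Matrix::rowSums(X)
  is_mito <- startsWith(gene_ids(m), mito_prefix)
  mito <- if (any(is_mito)) Matrix::rowSums(X[, is_mito, drop = FALSE]) else 0
  data.frame(
    cell_id = cell_ids(m),
    n_genes_detected = as.integer(detected),
    total_counts = as.numeric(total),
    mito_frac = ifelse(total > 0, mito / total, 0),
    stringsAsFactors = FALSE
  )
}

#' Quality-control filtering
#'
#' Removes cells with fewer than `min_genes_per_cell` detected genes or a
#' mitochondrial fraction above `max_mito_frac`, then genes detected in fewer
#' than `min_cells_per_gene` of the retained cells. Order is fixed: cells
#' first, then genes.
#'
#' @param m an `ExpressionMatrix` with layer `"counts"`.
#' @param config a [pipeline_config()].
#' @return List with `matrix` (filtered `ExpressionMatrix`) and `qc`
#'   (the pre-filter QC table with a `kept` column).
#' @export
qc_filter <- function(m, config = pipeline_config()) {
  stopifnot_layer(m, "counts")
  qc <- qc_metrics(m, config$mito_prefix)
  keep_cell <- qc$n_genes_detected >= config$min_genes_per_cell &
    qc$mito_frac <= config$max_mito_frac
  qc$kept <- keep_cell
  if (!any(keep_cell)) data_error("QC removed every cell")
  X <- m$X[keep_cell, , drop = FALSE]
  keep_gene <- Matrix::colSums(X > 0) >= config$min_cells_per_gene
  if (!any(keep_gene)) data_error("QC removed every gene")
  out <- structure(list(X = X[, keep_gene, drop = FALSE], layer = "counts"),
                   class = "ExpressionMatrix")
  list(matrix = out, qc = qc)
}

#' Library-size normalization and log transform
#'
#' Scales each cell to `target_sum` total counts, then applies `log1p`
#' (natural log of 1 + x).
#'
#' @param m an `ExpressionMatrix` with layer `"counts"`.
#' @param target_sum per-cell total after scaling.
#' @return An `ExpressionMatrix` with layer `"lognorm"`.
#' @export
normalize_log1p <- function(m, target_sum = 1e4) {
  stopifnot_layer(m, "counts")
  check_positive(target_sum, "target_sum")
  totals <- Matrix::rowSums(m$X)
  if (any(totals == 0)) {
    data_error("zero-total cell reached normalization; QC must remove it first")
  }
  X <- Matrix::Diagonal(x = target_sum / totals) %*% m$X
  X <- methods::as(X, "CsparseMatrix")
  X@x <- log1p(X@x)
  dimnames(X) <- dimnames(m$X)
  structure(list(X = methods::as(X, "generalMatrix"), layer = "lognorm"),
            class = "ExpressionMatrix")
}

#' Highly variable gene selection by binned dispersion
#'
#' Dispersion is variance/mean per gene on the log-normalized layer. Genes are
#' cut into 20 equal-count bins by mean expression and the dispersion is
#' z-scored within each bin; the top `n_hvg` genes by z-score are returned,
#' ties broken by gene order. Zero-mean genes get dispersion 0; a
#' zero-variance bin gets z-scores 0.
#'
#' @param m an `ExpressionMatrix` with layer `"lognorm"`.
#' @param n_hvg number of genes to select.
#' @param n_mean_bins number of equal-count mean bins.
#' @return Integer vector of selected gene column indices, in gene order.
#' @export
select_hvg <- function(m, n_hvg, n_mean_bins = 20L) {
  stopifnot_layer(m, "lognorm")
  g <- ncol(m$X)
  if (n_hvg > g) config_error(sprintf("n_hvg = %d exceeds gene count %d", n_hvg, g))
  mu <- Matrix::colMeans(m$X)
  ex2 <- Matrix::colMeans(m$X^2)
  v <- (ex2 - mu^2) * nrow(m$X) / max(1, nrow(m$X) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)

  # ties share a bin (min rank) so identical genes always get identical z-scores
  bin <- assign_equal_count_bins(rank(mu, ties.method = "min"), min(n_mean_bins, g))
  z <- numeric(g)
  for (b in unique(bin)) {
    i <- which(bin == b)
    s <- stats::sd(disp[i])
    z[i] <- if (length(i) > 1L && is.finite(s) && s > 0) (disp[i] - mean(disp[i])) / s else 0
  }
  sort(order(-z, seq_len(g))[seq_len(n_hvg)])
}

# split items (given their 1..n ranks) into n_bins near-equal-count bins;
# earlier bins take the remainder
assign_equal_count_bins <- function(ranks, n_bins) {
  n <- length(ranks)
  bounds <- floor(seq(0, n, length.out = n_bins + 1L))
  findInterval(ranks, bounds, left.open = TRUE)
}

#' PCA embedding
#'
#' Genes are mean-centered; scores are the projections onto the leading
#' right singular vectors (equivalently, left singular vectors scaled by the
#' singular values). Each component's sign is fixed so its largest-magnitude
#' gene loading is positive. Requests beyond the numerical rank are truncated
#' with a warning.
#'
#' @param m an `ExpressionMatrix` with layer `"lognorm"` (typically restricted
#'   to highly variable genes).
#' @param n_pcs number of components.
#' @return List of class `Embedding`: `scores` (cells x n_pcs),
#'   `loadings` (genes x n_pcs), `explained_variance` (fractions of total
#'   variance, non-increasing).
#' @export
pca_embed <- function(m, n_pcs) {
  stopifnot_layer(m, "lognorm")
  X <- as_dense(m)
  n <- nrow(X); g <- ncol(X)
  if (n_pcs > min(n - 1L, g)) {
    config_error(sprintf("n_pcs = %d exceeds min(cells - 1, genes) = %d",
                         n_pcs, min(n - 1L, g)))
  }
  Xc <- sweep(X, 2L, colMeans(X))
  if (n >= g) {
    eg <- eigen(crossprod(Xc), symmetric = TRUE)     # g x g
    V <- eg$vectors
    ev <- pmax(eg$values, 0)
  } else {
    eg <- eigen(tcrossprod(Xc), symmetric = TRUE)    # n x n Gram trick
    ev <- pmax(eg$values, 0)
    pos <- ev > 0
    V <- crossprod(Xc, eg$vectors[, pos, drop = FALSE])
    V <- sweep(V, 2L, sqrt(ev[pos]), "/")
    ev <- ev[pos]
  }
  rank_tol <- max(ev) * 1e-12
  r <- sum(ev > rank_tol)
  if (n_pcs > r) {
    warning(sprintf("requested %d PCs but numerical rank is %d; truncating", n_pcs, r))
    n_pcs <- r
  }
  V <- V[, seq_len(n_pcs), drop = FALSE]
  flip <- vapply(seq_len(n_pcs), function(j) {
    lj <- V[, j]
    if (lj[which.max(abs(lj))] < 0) -1 else 1
  }, numeric(1))
  V <- sweep(V, 2L, flip, "*")
  scores <- Xc %*% V
  total_var <- sum(ev)
  rownames(scores) <- rownames(X)
  rownames(V) <- colnames(X)
  structure(list(
    scores = scores,
    loadings = V,
    explained_variance = if (total_var > 0) ev[seq_len(n_pcs)] / total_var
                         else rep(0, n_pcs)
  ), class = "Embedding")
}

#' k-nearest-neighbor graph
#'
#' Euclidean k nearest neighbors per cell in the embedding, symmetrized by
#' union; all edge weights 1; no self-loops.
#'
#' @param embedding an `Embedding` (or a numeric cells x dims matrix).
#' @param k neighbors per cell.
#' @return An undirected `igraph` graph with one vertex per cell.
#' @export
knn_graph <- function(embedding, k) {
  E <- if (inherits(embedding, "Embedding")) embedding$scores else as.matrix(embedding)
  n <- nrow(E)
  if (k >= n) config_error(sprintf("k = %d must be < n_cells = %d", k, n))
  d2 <- as.matrix(stats::dist(E))^2
  diag(d2) <- Inf
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(k)]
    edges[[i]] <- rbind(i, nb)
  }
  ep <- do.call(cbind, edges)
  g <- igraph::graph_from_edgelist(t(ep), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::V(g)$name <- rownames(E) %||% as.character(seq_len(n))
  igraph::E(g)$weight <- 1
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Louvain clustering
#'
#' Multilevel modularity optimization (Louvain) with a resolution parameter;
#' the node sweep order is randomized from `seed`. Cluster ids are relabeled
#' by decreasing size (ties by first occurrence), starting at 0.
#'
#' @param graph an undirected `igraph` graph.
#' @param resolution resolution parameter (1 = classic modularity).
#' @param seed RNG seed for the sweep order.
#' @return Integer vector of cluster ids (0-based), one per vertex.
#' @export
louvain_cluster <- function(graph, resolution = 1.0, seed = 0L) {
  if (igraph::vcount(graph) == 0L) data_error("empty graph")
  memb <- with_local_seed(seed, {
    igraph::membership(igraph::cluster_louvain(graph, resolution = resolution))
  })
  relabel_by_size(as.integer(memb))
}

relabel_by_size <- function(ids) {
  tab <- table(ids)
  ord <- names(tab)[order(-as.integer(tab), as.integer(names(tab)))]
  match(as.character(ids), ord) - 1L
}

#' Flag malignant cells
#'
#' If per-cell labels are supplied they are used unchanged. Otherwise each
#' cluster's mean malignant-signature score (binned-control scoring on the
#' log-normalized layer) is compared with the across-cluster median: clusters
#' strictly above the median are flagged malignant. With all cluster means
#' equal, nothing is flagged.
#'
#' @param m an `ExpressionMatrix` with layer `"lognorm"`.
#' @param clusters integer cluster id per cell.
#' @param malignant_signature character vector of malignant marker genes
#'   (ignored when `labels` is given).
#' @param labels optional logical per-cell malignant labels; overrides scoring.
#' @param config a [pipeline_config()] (scoring parameters).
#' @return Logical vector, `TRUE` for malignant cells.
#' @export
flag_malignant <- function(m, clusters, malignant_signature = NULL,
                           labels = NULL, config = pipeline_config()) {
  n <- nrow(m$X)
  if (!is.null(labels)) {
    if (length(labels) != n) data_error("labels length != number of cells")
    return(as.logical(labels))
  }
  if (is.null(malignant_signature)) {
    config_error("need either per-cell labels or a malignant marker set")
  }
  if (length(clusters) != n) data_error("clusters length != number of cells")
  sc <- score_gene_set(m, malignant_signature, n_bins = config$n_bins,
                       ctrl_size = config$ctrl_size, seed = config$score_seed)
  means <- tapply(sc, clusters, mean)
  flagged_clusters <- names(means)[means > stats::median(means)]
  as.character(clusters) %in% flagged_clusters
}
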