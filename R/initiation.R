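#' Hybrid EMT score
#'
#' The elementwise minimum of the normalized epithelial and mesenchymal
#' scores: a cell is only as hybrid as its weaker program.
#'
#' @param e_hat,m_hat normalized (\[0, 1\]) epithelial and mesenchymal scores.
#' @return Per-cell hybrid score `H = pmin(e_hat, m_hat)`.
#' @export
hybrid_emt <- function(e_hat, m_hat) {
  if (length(e_hat) != length(m_hat)) data_error("score lengths differ")
  pmin(e_hat, m_hat)
}

#' Top-quantile classification
#'
#' The threshold is the `q`-th quantile under linear interpolation of order
#' statistics (index `h = q * (n - 1)`, interpolating between the flooring
#' and ceiling order statistics — R's default type-7 quantile). Cells at or
#' above the threshold are flagged, so ties at the threshold are included.
#'
#' @param x per-cell numeric values.
#' @param q quantile in (0, 1); e.g. `q = 0.75` flags the top 25%.
#' @return List with `flags` (logical) and `threshold`.
#' @export
classify_top_quantile <- function(x, q) {
  if (length(x) == 0L) data_error("cannot classify an empty vector")
  check_fraction(q, "q", open = TRUE)
  t <- unname(quantile(x, probs = q, type = 7, names = FALSE))
  list(flags = x >= t, threshold = t)
}

#' Metabolic reprogramming score
#'
#' The glycolysis-to-OXPHOS ratio on normalized scores, stabilized with a
#' pseudocount: `R = (g_hat + eps) / (o_hat + eps)`. Both scores zero gives
#' exactly 1 (no evidence of a shift either way).
#'
#' @param g_hat,o_hat normalized (\[0, 1\]) glycolysis and OXPHOS scores.
#' @param eps pseudocount, > 0.
#' @return Per-cell ratio `R`.
#' @export
metabolic_ratio <- function(g_hat, o_hat, eps = 0.01) {
  check_positive(eps, "eps")
  if (length(g_hat) != length(o_hat)) data_error("score lengths differ")
  (g_hat + eps) / (o_hat + eps)
}

#' Fit PC1 integration weights
#'
#' Columns of the normalized feature matrix are centered and the first
#' principal component computed. The global sign is flipped if needed so the
#' loading on the first feature (EMT drivers by convention) is non-negative,
#' and the weights are the normalized absolute loadings — convex weights, so
#' the integrated score of \[0, 1\] features stays in \[0, 1\].
#'
#' @param features cells x features numeric matrix with column names, in the
#'   documented order (default `D_hat`, `H`, `S_hat`, `R_hat`, plus any
#'   optional user feature columns).
#' @param eps ratio pseudocount, recorded in the model for provenance.
#' @return List of class `IntegrationModel`: `features` (column order),
#'   `loadings` (signed PC1 loadings), `weights` (non-negative, summing to 1),
#'   `sign_flipped`, `eps`.
#' @export
fit_integration <- function(features, eps = 0.01) {
  F <- as.matrix(features)
  if (is.null(colnames(F))) data_error("feature matrix needs column names")
  if (ncol(F) < 2L) config_error("need at least 2 features")
  if (nrow(F) < 3L) config_error("need at least 3 cells")
  if (any(!is.finite(F))) data_error("non-finite feature values")
  Fc <- sweep(F, 2L, colMeans(F))
  if (all(abs(Fc) < 1e-12)) data_error("all features constant: no principal direction")
  eg <- eigen(crossprod(Fc) / (nrow(F) - 1), symmetric = TRUE)
  loadings <- eg$vectors[, 1]
  flipped <- loadings[1] < 0
  if (flipped) loadings <- -loadings
  w <- abs(loadings) / sum(abs(loadings))
  structure(list(
    features = colnames(F),
    loadings = setNames(loadings, colnames(F)),
    weights = setNames(w, colnames(F)),
    sign_flipped = flipped,
    eps = eps
  ), class = "IntegrationModel")
}

#' Molecular Initiation Score
#'
#' Weighted average `I = F %*% w` of the normalized features under the fitted
#' convex weights; with all features in \[0, 1\], `I` is in \[0, 1\].
#'
#' @param features cells x features matrix with the same column order the
#'   model was fitted on.
#' @param model an `IntegrationModel` from [fit_integration()].
#' @return Per-cell score `I`.
#' @export
initiation_score <- function(features, model) {
  F <- as.matrix(features)
  if (!identical(colnames(F), model$features)) {
    data_error(sprintf("feature order mismatch: model has (%s), input has (%s)",
                       paste(model$features, collapse = ", "),
                       paste(colnames(F), collapse = ", ")))
  }
  as.numeric(F %*% model$weights)
}

#' Cluster-level aggregation of a per-cell score
#'
#' Arithmetic mean per cluster, ranked by decreasing mean (ties broken by
#' cluster id).
#'
#' @param score per-cell numeric score.
#' @param clusters per-cell cluster ids.
#' @return List with `table` (`cluster`, `n_cells`, `mean_score`, `rank`) and
#'   `top_cluster`.
#' @export
aggregate_by_cluster <- function(score, clusters) {
  if (length(score) != length(clusters)) data_error("score/cluster lengths differ")
  ids <- sort(unique(clusters))
  tab <- data.frame(
    cluster = ids,
    n_cells = as.integer(table(factor(clusters, levels = ids))),
    mean_score = as.numeric(tapply(score, factor(clusters, levels = ids), mean)),
    stringsAsFactors = FALSE
  )
  ord <- order(-tab$mean_score, tab$cluster)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  list(table = tab, top_cluster = tab$cluster[1])
}
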