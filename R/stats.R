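#' Two-sided Wilcoxon rank-sum p-value
#'
#' Normal approximation with tie correction and continuity correction; when
#' both groups have at most `exact_max` observations the exact conditional
#' p-value is computed by enumerating all assignments of the observed
#' (mid)ranks, so ties are handled exactly. Two-sided exact p is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y numeric samples.
#' @param exact_max enumerate exactly when `max(n_x, n_y) <= exact_max`.
#' @return Two-sided p-value.
#' @export
wilcox_ranksum_p <- function(x, y, exact_max = 8L) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) data_error("both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  if (max(nx, ny) <= exact_max) {
    return(exact_ranksum_p(r, nx, w))
  }
  n <- nx + ny
  mu <- nx * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)  # all values tied
  z <- w - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
  min(1, 2 * pnorm(-abs(z)))
}

# exact conditional distribution of the rank sum given the observed midranks
exact_ranksum_p <- function(r, nx, w) {
  n <- length(r)
  sums <- utils::combn(n, nx, FUN = function(i) sum(r[i]))
  tol <- 1e-9
  p_le <- mean(sums <= w + tol)
  p_ge <- mean(sums >= w - tol)
  min(1, 2 * min(p_le, p_ge))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up procedure: sort p ascending, `q_i = min_{j >= i} p_j * m / j`,
#' capped at 1, mapped back to the input order. Idempotent.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    data_error("p-values must be finite and in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Rank-sum differential expression between flagged and unflagged cells
#'
#' Per gene: two-sided Wilcoxon rank-sum p-value on the log-normalized layer
#' (exact enumeration when both groups have <= 8 cells), BH q-value, and
#' `log2FC = log2((mean_hi + 1) / (mean_lo + 1))` computed on de-logged
#' (`expm1`) normalized values. Sorted by q, then decreasing |log2FC|.
#'
#' @param m an `ExpressionMatrix` with layer `"lognorm"` (malignant cells).
#' @param flags logical per-cell vector (e.g. high-initiation).
#' @return `data.frame` with `gene`, `stat` (rank sum of the flagged group),
#'   `p`, `q`, `log2fc`, `direction`.
#' @export
rank_sum_de <- function(m, flags) {
  stopifnot_layer(m, "lognorm")
  flags <- as.logical(flags)
  if (length(flags) != nrow(m$X)) data_error("flags length != number of cells")
  n_hi <- sum(flags); n_lo <- sum(!flags)
  if (n_hi == 0L || n_lo == 0L) data_error("both groups must be non-empty")
  X <- as_dense(m)
  hi <- which(flags)
  expd <- expm1(X)
  mean_hi <- colMeans(expd[hi, , drop = FALSE])
  mean_lo <- colMeans(expd[-hi, , drop = FALSE])
  log2fc <- log2((mean_hi + 1) / (mean_lo + 1))

  res <- apply(X, 2L, function(col) {
    r <- rank(col)
    w <- sum(r[hi])
    c(w, wilcox_ranksum_p(col[hi], col[-hi]))
  })
  out <- data.frame(
    gene = gene_ids(m),
    stat = res[1, ],
    p = res[2, ],
    q = bh_fdr(res[2, ]),
    log2fc = log2fc,
    direction = ifelse(log2fc >= 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$q, -abs(out$log2fc), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation analysis
#'
#' Per gene set: upper-tail hypergeometric p-value
#' `P(X >= overlap)` with population = universe size, successes = set
#' intersected with the universe, draws = query size; BH correction across
#' sets. The universe should be the genes actually tested (e.g. the DE table).
#'
#' @param query character vector of genes of interest (intersected with the
#'   universe).
#' @param collections named list of gene sets.
#' @param universe character vector of background genes.
#' @return `data.frame` with `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `q`, sorted by q then p.
#' @export
ora_enrichment <- function(query, collections, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) data_error("empty universe")
  query <- intersect(unique(as.character(query)), universe)
  N <- length(universe)
  n_draw <- length(query)
  rows <- lapply(names(collections), function(nm) {
    set_u <- intersect(collections[[nm]], universe)
    K <- length(set_u)
    ov <- length(intersect(set_u, query))
    p <- if (K == 0L || n_draw == 0L) 1 else
      phyper(ov - 1, K, N - K, n_draw, lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = K, query_size = n_draw,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$q, out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
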