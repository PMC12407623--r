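# Independent oracles: deliberately plain, loop-based reimplementations used
# to cross-check the package. They share only the documented contracts
# (binning rule, seeding protocol), not code, with the implementation.

# brute-force binned-control signature scoring on a dense matrix
oracle_score_gene_set <- function(X, gene_names, signature, n_bins, ctrl_size,
                                  seed) {
  g <- length(gene_names)
  mu <- apply(X, 2, mean)
  rk <- rank(mu, ties.method = "min")
  bounds <- floor(seq(0, g, length.out = min(n_bins, g) + 1L))
  bin <- vapply(rk, function(r) sum(r > bounds), 0L)  # 1..n_bins
  nb <- min(n_bins, g)
  signature <- unique(signature[signature %in% gene_names])
  is_sig <- gene_names %in% signature

  ctrl <- withr::with_seed(as.integer(seed), {
    picked <- character(0)
    for (gene in signature) {
      b <- bin[which(gene_names == gene)]
      width <- 0L
      repeat {
        sel <- which(bin >= b - width & bin <= b + width & !is_sig)
        if (length(sel) >= ctrl_size || (b - width <= 1L && b + width >= nb)) break
        width <- width + 1L
      }
      take <- if (length(sel) > ctrl_size) {
        sel[sample.int(length(sel), ctrl_size)]
      } else sel
      picked <- c(picked, gene_names[take])
    }
    unique(picked)
  })

  out <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    out[i] <- mean(X[i, match(signature, gene_names)]) -
      mean(X[i, match(ctrl, gene_names)])
  }
  out
}

# sort-based interpolated quantile (type-7 convention, written from the
# order-statistic definition)
oracle_quantile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  h <- q * (n - 1)
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  s[lo] + (h - (lo - 1)) * (s[hi] - s[lo])
}

# dense PCA oracle via svd of the centered matrix
oracle_pca <- function(X, n_pcs) {
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  scores <- sv$u[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pcs)], n_pcs)
  ev <- sv$d^2
  list(scores = scores, loadings = sv$v[, seq_len(n_pcs), drop = FALSE],
       explained_variance = ev[seq_len(n_pcs)] / sum(ev))
}

# AUROC by exhaustive pair enumeration
oracle_auroc <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# upper-tail hypergeometric by direct combinatorial summation
oracle_hypergeom_upper <- function(overlap, set_size, universe_size, query_size) {
  ks <- overlap:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(universe_size - set_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# exact two-sided rank-sum p by enumeration over group assignments
oracle_exact_ranksum <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)])
  sums <- apply(utils::combn(n, length(x)), 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(sums <= w_obs + 1e-9), mean(sums >= w_obs - 1e-9)))
}
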