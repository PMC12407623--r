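test_that("QC applies the threshold rules, cells first then genes", {
  # 3 cells with 500/150/300 detected genes out of 600
  X <- matrix(0L, 3, 600)
  X[1, 1:500] <- 1L; X[2, 1:150] <- 1L; X[3, 201:500] <- 1L
  m <- counts_matrix(X)
  cfg <- pipeline_config(min_genes_per_cell = 200, min_cells_per_gene = 0)
  out <- qc_filter(m, cfg)
  expect_identical(rownames(out$matrix$X), c("c001", "c003"))
  expect_identical(out$qc$kept, c(TRUE, FALSE, TRUE))

  # a gene detected in no retained cell is removed at min_cells = 1
  cfg2 <- pipeline_config(min_genes_per_cell = 0, min_cells_per_gene = 1)
  out2 <- qc_filter(m, cfg2)
  expect_equal(ncol(out2$matrix$X), 500)  # genes 501..600 all zero

  # thresholds (0, 0, 1.0) are the identity
  cfg3 <- pipeline_config(min_genes_per_cell = 0, min_cells_per_gene = 0,
                          max_mito_frac = 1.0)
  out3 <- qc_filter(m, cfg3)
  expect_equal(as.matrix(out3$matrix$X), as.matrix(m$X))

  expect_error(qc_filter(m, pipeline_config(min_genes_per_cell = 1000)),
               class = "metascore_data_error")
})

test_that("mitochondrial fraction filter uses the id prefix", {
  X <- matrix(c(5L, 5L, 9L, 1L), 2, 2)
  m <- expression_matrix(X, c("c1", "c2"), c("MT-CO1", "g1"), layer = "counts")
  qc <- qc_metrics(m)
  expect_equal(qc$mito_frac, c(5 / 14, 5 / 6))
  out <- qc_filter(m, pipeline_config(min_genes_per_cell = 0,
                                      min_cells_per_gene = 0,
                                      max_mito_frac = 0.5))
  expect_identical(rownames(out$matrix$X), "c1")
})

test_that("normalization scales to target_sum then log1p", {
  m <- counts_matrix(matrix(c(0L, 2L, 2L), 1, 3))
  ln <- normalize_log1p(m, target_sum = 4)
  expect_equal(as.numeric(ln$X), c(0, log(3), log(3)), tolerance = 1e-12)

  m2 <- counts_matrix(matrix(rep(1L, 4), 1, 4))
  ln2 <- normalize_log1p(m2, target_sum = 4)
  expect_equal(as.numeric(ln2$X), rep(log(2), 4), tolerance = 1e-12)

  # doubling a cell's counts leaves its normalized vector unchanged
  X <- matrix(c(1L, 3L, 0L, 2L), 2, 2)
  d <- normalize_log1p(counts_matrix(X), 10)
  d2 <- normalize_log1p(counts_matrix(2L * X), 10)
  expect_equal(as.matrix(d$X), as.matrix(d2$X), tolerance = 1e-12)

  expect_error(normalize_log1p(counts_matrix(matrix(c(0L, 1L, 0L, 2L), 2, 2)), 4),
               class = "metascore_data_error")
})

test_that("HVG selection ranks by within-bin dispersion z-score", {
  # 6 genes, exactly equal (integer-valued, fp-exact) means; gene 3 has
  # about 10x the variance -> all genes share one mean bin
  base <- c(-20:-1, 1:20)  # sums to 0 exactly
  X <- sapply(1:6, function(j) 50 + base * if (j == 3) 3 else 1)
  m <- lognorm_matrix(X)
  expect_equal(select_hvg(m, 1), 3L)
  # direct dispersion oracle agrees on the full ordering
  disp <- apply(X, 2, var) / colMeans(X)
  expect_equal(select_hvg(m, 2), sort(order(-disp)[1:2]))

  # identical expression vectors get identical z-scores; tie broken by id
  X2 <- cbind(X[, 1], X[, 1], X[, 3])
  expect_equal(select_hvg(lognorm_matrix(X2), 2), c(1L, 3L))

  # a zero-variance gene never beats a positive-variance gene in its bin
  X3 <- cbind(rep(50, 40), X[, 2], X[, 3])
  expect_false(1L %in% select_hvg(lognorm_matrix(X3), 2))

  expect_error(select_hvg(m, 10), class = "metascore_config_error")
})

test_that("PCA matches the dense SVD oracle on all small fixtures", {
  withr::with_seed(5L, {
    shapes <- list(c(5, 4), c(12, 7), c(20, 20), c(8, 15))
    for (sh in shapes) {
      X <- matrix(rnorm(prod(sh)), sh[1], sh[2])
      k <- min(sh[1] - 1, sh[2], 4)
      emb <- pca_embed(lognorm_matrix(X), k)
      orc <- oracle_pca(X, k)
      # agreement up to column sign
      for (j in seq_len(k)) {
        s <- sign(sum(emb$scores[, j] * orc$scores[, j]))
        expect_equal(unname(emb$scores[, j]), s * orc$scores[, j],
                     tolerance = 1e-8)
      }
      expect_equal(emb$explained_variance, orc$explained_variance[seq_len(k)],
                   tolerance = 1e-8)
      # orthogonality and sign convention
      cp <- crossprod(emb$scores)
      expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
      for (j in seq_len(k)) {
        lj <- emb$loadings[, j]
        expect_gte(lj[which.max(abs(lj))], 0)
      }
    }
  })
})

test_that("PCA handles rank-1 data and rank truncation", {
  v <- c(1, 2, 0.5, -1)
  X <- outer(c(0, 1, 2, 3, 4), v)  # points on a line
  emb <- pca_embed(lognorm_matrix(X), 1)
  expect_equal(emb$explained_variance, 1.0, tolerance = 1e-12)
  expect_warning(emb2 <- pca_embed(lognorm_matrix(X), 3), "rank")
  expect_equal(ncol(emb2$scores), 1L)
  expect_error(pca_embed(lognorm_matrix(X), 5), class = "metascore_config_error")
})

test_that("kNN graph follows the hand geometry", {
  pts <- matrix(c(0, 1, 2), 3, 1)  # collinear, equally spaced
  g <- knn_graph(pts, 1)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  expect_equal(sum(adj[2, ]), 2)  # middle connected to both after union
  expect_true(all(diag(adj) == 0))

  withr::with_seed(2L, pts2 <- matrix(rnorm(20), 10, 2))
  g2 <- knn_graph(pts2, 9)
  expect_equal(igraph::ecount(g2), choose(10, 2))  # complete graph
  expect_error(knn_graph(pts2, 10), class = "metascore_config_error")
})

test_that("Louvain recovers planted structure and beats singletons", {
  # two disjoint 5-cliques
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  igraph::E(g)$weight <- 1
  cl <- louvain_cluster(g, 1.0, 0L)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(length(unique(cl[1:5])), 1L)
  expect_equal(length(unique(cl[6:10])), 1L)
  expect_equal(sort(unique(cl)), c(0L, 1L))

  # single node
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  expect_equal(louvain_cluster(g1, 1.0, 0L), 0L)
  expect_error(louvain_cluster(igraph::make_empty_graph(0, directed = FALSE), 1, 0),
               class = "metascore_data_error")

  # modularity of the returned partition >= singleton partition
  withr::with_seed(3L, pts <- matrix(rnorm(120), 60, 2))
  gr <- knn_graph(pts, 5)
  cl2 <- louvain_cluster(gr, 1.0, 0L)
  m_part <- igraph::modularity(gr, cl2 + 1L)
  m_singl <- igraph::modularity(gr, seq_len(60))
  expect_gte(m_part, m_singl)
})

test_that("Louvain recovers two well-separated simulated blobs (ARI >= 0.95)", {
  pc <- small_pipeline_config()
  sim <- simulate_dataset(sim_config(n_cells = 400, n_genes = 300,
                                     program_size = 20, n_clusters = 2,
                                     frac_malignant = 0, effect_size = 3,
                                     seed = 3))
  qc <- qc_filter(sim$counts, pc)
  ln <- normalize_log1p(qc$matrix, pc$target_sum)
  emb <- pca_embed(subset_cells(ln, genes = select_hvg(ln, 250)), 20)
  cl <- louvain_cluster(knn_graph(emb, 15), 1.0, 0L)
  expect_gte(adjusted_rand_index(cl, sim$truth$cluster[qc$qc$kept]), 0.95)
})

test_that("malignant flagging: labels pass through; median rule; tie edge", {
  sim <- simulate_dataset(small_sim_config(seed = 4L))
  labels <- sim$truth$malignant
  ln <- normalize_log1p(qc_filter(sim$counts, pipeline_config())$matrix, 1e4)
  expect_identical(flag_malignant(ln, labels = labels[1:nrow(ln$X)],
                                  clusters = NULL),
                   labels[1:nrow(ln$X)])

  # identical cluster mean scores (constant matrix -> all scores 0): none flagged
  Xc <- matrix(rep(1, 60 * 40), 60, 40)
  mc <- lognorm_matrix(Xc)
  fl <- suppressWarnings(
    flag_malignant(mc, clusters = rep(c(0L, 1L), each = 30),
                   malignant_signature = sprintf("g%03d", 1:5),
                   config = pipeline_config(n_bins = 2, ctrl_size = 5)))
  expect_false(any(fl))

  expect_error(flag_malignant(mc, clusters = rep(0L, 60)),
               class = "metascore_config_error")
})

test_that("median-rule malignant calling matches ground truth >= 95%", {
  # tumor-minority sample with a single malignant EMT state: the regime where
  # a majority-vote-style rule is applicable
  pc <- small_pipeline_config()
  sim <- simulate_dataset(sim_config(n_cells = 400, n_genes = 300,
                                     program_size = 20, n_clusters = 2,
                                     frac_malignant = 0.35, frac_hybrid = 1,
                                     frac_stem = 0, frac_glycolytic = 0,
                                     effect_size = 3, seed = 5))
  qc <- qc_filter(sim$counts, pc)
  ln <- normalize_log1p(qc$matrix, pc$target_sum)
  emb <- pca_embed(subset_cells(ln, genes = select_hvg(ln, 250)), 20)
  cl <- louvain_cluster(knn_graph(emb, 15), 1.0, 0L)
  fl <- flag_malignant(ln, cl, malignant_signature = sim$signatures$malignant,
                       config = pc)
  expect_gte(mean(fl == sim$truth$malignant[qc$qc$kept]), 0.95)
})
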