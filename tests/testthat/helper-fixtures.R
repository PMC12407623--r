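# fixtures are built in code; nothing binary ships with the package

# small lognorm ExpressionMatrix from a dense matrix
lognorm_matrix <- function(X, cells = sprintf("c%03d", seq_len(nrow(X))),
                           genes = sprintf("g%03d", seq_len(ncol(X)))) {
  expression_matrix(X, cells, genes, layer = "lognorm")
}

counts_matrix <- function(X, cells = sprintf("c%03d", seq_len(nrow(X))),
                          genes = sprintf("g%03d", seq_len(ncol(X)))) {
  expression_matrix(X, cells, genes, layer = "counts")
}

# the 50-cell x 100-gene scoring fixture: distinct gene means, fixed seed
scoring_fixture <- function() {
  withr::with_seed(42L, {
    X <- matrix(round(abs(rnorm(5000, 1, 0.5)), 4), 50, 100)
    sweep(X, 2, seq(0.5, 1.5, length.out = 100), "*")
  })
}

# small simulation configs used across tests (desk-scale; generative model
# and pipeline thresholds unchanged)
small_sim_config <- function(seed = 1L, effect_size = 2.0, ...) {
  sim_config(n_cells = 400L, n_genes = 300L, program_size = 20L,
             n_clusters = 2L, effect_size = effect_size, seed = seed, ...)
}

small_pipeline_config <- function(...) {
  pipeline_config(n_hvg = 250L, n_pcs = 20L, ...)
}
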