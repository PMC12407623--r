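#' Per-cell gene-signature score with expression-matched controls
#'
#' Genes are ranked by mean expression across cells and cut into `n_bins`
#' equal-count bins. For each signature gene, `ctrl_size` control genes are
#' drawn uniformly without replacement from its bin, excluding all signature
#' genes; a bin holding fewer than `ctrl_size` eligible genes is merged with
#' its nearest neighbor bins (expanding symmetrically outward) until enough
#' are available. The per-cell score is the mean expression over the
#' signature genes minus the mean expression over the pooled (deduplicated)
#' control genes. The control draw is seeded, so fixed input and seed give
#' bit-identical scores.
#'
#' Signature genes absent from the matrix are dropped with a warning. Because
#' signature and control means shift equally, adding a constant to every
#' matrix entry leaves the score unchanged.
#'
#' @param m an `ExpressionMatrix` with layer `"lognorm"`.
#' @param signature character vector of gene ids.
#' @param n_bins number of expression bins (>= 1).
#' @param ctrl_size control genes drawn per signature gene (>= 1).
#' @param seed RNG seed for the control draws.
#' @return Numeric per-cell score vector (may be negative), named by cell id.
#' @export
score_gene_set <- function(m, signature, n_bins = 25L, ctrl_size = 50L,
                           seed = 0L) {
  stopifnot_layer(m, "lognorm")
  check_count(n_bins, "n_bins")
  check_count(ctrl_size, "ctrl_size")
  genes <- gene_ids(m)
  signature <- unique(as.character(signature))
  present <- intersect(signature, genes)
  if (length(present) == 0L) data_error("no signature gene present in the matrix")
  if (length(present) < length(signature)) {
    warning(sprintf("%d of %d signature genes absent from the matrix; dropped",
                    length(signature) - length(present), length(signature)))
  }
  g <- length(genes)
  n_bins <- min(n_bins, g)
  mu <- Matrix::colMeans(m$X)
  bin <- assign_equal_count_bins(rank(mu, ties.method = "min"), n_bins)
  is_sig <- genes %in% present

  ctrl <- with_local_seed(seed, {
    picked <- character(0)
    for (gene in present) {
      b <- bin[match(gene, genes)]
      width <- 0L
      repeat {
        in_bins <- bin >= b - width & bin <= b + width
        eligible <- genes[in_bins & !is_sig]
        if (length(eligible) >= ctrl_size ||
            (b - width <= 1L && b + width >= n_bins)) break
        width <- width + 1L
      }
      if (length(eligible) == 0L) {
        data_error("control pool empty even after merging all bins")
      }
      take <- if (length(eligible) > ctrl_size) {
        eligible[sample.int(length(eligible), ctrl_size)]
      } else {
        if (length(eligible) < ctrl_size) {
          warning(sprintf(
            "only %d eligible control genes (< ctrl_size = %d) for '%s'; using all",
            length(eligible), ctrl_size, gene))
        }
        eligible
      }
      picked <- c(picked, take)
    }
    unique(picked)
  })

  sig_mean <- Matrix::rowMeans(m$X[, present, drop = FALSE])
  ctrl_mean <- Matrix::rowMeans(m$X[, ctrl, drop = FALSE])
  out <- as.numeric(sig_mean - ctrl_mean)
  names(out) <- cell_ids(m)
  out
}

#' Min-max normalization to \[0, 1\]
#'
#' `(x - min) / (max - min)`; a constant vector maps to all zeros (the
#' documented degenerate rule: no spread means no evidence of activation).
#'
#' @param x finite numeric vector.
#' @return Values in \[0, 1\].
#' @export
minmax_normalize <- function(x) {
  if (length(x) == 0L) data_error("cannot normalize an empty vector")
  if (any(!is.finite(x))) data_error("minmax_normalize: non-finite input")
  rng <- range(x)
  if (rng[1] == rng[2]) return(setNames(rep(0, length(x)), names(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}
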