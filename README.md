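# metascore

Quantifying the metastatic-**initiation** potential of malignant cells from
single-nucleus (or single-cell) RNA-seq.

## The problem

Early metastatic initiation is driven by a small subpopulation of tumor cells
that simultaneously (i) occupy a *hybrid* epithelial/mesenchymal (EMT) state —
co-expressing both programs rather than completing the transition — (ii)
activate cancer-stemness regulators (e.g. the NANOG/SOX2 regulon), and (iii)
shift their metabolism from oxidative phosphorylation (OXPHOS) toward
glycolysis. `metascore` turns these three axes into a per-cell **Molecular
Initiation Score** and asks which cells, and which transcriptional clusters,
carry the highest early invasive potential. It is aimed at computational
biologists analysing malignant compartments of tumor snRNA-seq samples, such
as non-small cell lung cancer biopsies.

## The method

For each curated gene signature *g* (epithelial, mesenchymal, EMT drivers,
stemness, glycolysis, OXPHOS) a per-cell score is computed on the
log-normalized matrix as

    score_c(g) = mean_{j in g} x_cj − mean_{j in ctrl(g)} x_cj

where `ctrl(g)` draws, for every signature gene, `ctrl_size` expression-matched
control genes from the same mean-expression bin (`n_bins` equal-count bins,
signature genes excluded, thin bins merged outward) — the binned-control
module-score construction familiar from Seurat/Scanpy. Raw scores
E, M, D, S, G, O are min–max normalized to [0, 1] across malignant cells
(Ê, M̂, D̂, Ŝ, Ĝ, Ô), and two composite features are derived:

* hybrid EMT: `H = min(Ê, M̂)`, with the top 20 % of cells flagged hybrid;
* metabolic reprogramming: `R = (Ĝ + ε) / (Ô + ε)`, min–max normalized to R̂.

The feature matrix `F = [D̂, H, Ŝ, R̂]` (plus optional user features) is
integrated by the first principal component: with PC1 loadings `v` (sign fixed
so the EMT-driver loading is non-negative), the weights are `w = |v| / Σ|v|`
and the Molecular Initiation Score is the convex combination

    I = F · w  ∈ [0, 1].

Cells in the top 25 % of `I` (threshold = the interpolated 0.75 quantile) are
classified as high initiation potential. Louvain clustering of the malignant
cells maps cell states, and cluster-level means of `I` rank clusters. A
validation layer contrasts high-initiation cells against the rest with
two-sided Wilcoxon rank-sum tests (exact enumeration for tiny groups),
Benjamini–Hochberg correction, and hypergeometric over-representation of the
signature collection among significantly upregulated genes.

A seeded synthetic snRNA-seq generator (negative-binomial counts, log-normal
library sizes, planted malignant/EMT/stemness/metabolic structure with
ground-truth labels) makes every stage testable without any data download.

## Worked example

```r
library(metascore)

cfg <- sim_config(seed = 0)            # 2000 cells x 2000 genes, defaults
sim <- simulate_dataset(cfg)
res <- run_initiation_pipeline(sim$counts, sim$signatures,
                               malignant_labels = sim$truth$malignant)

round(res$model$weights, 3)
#> D_hat     H S_hat R_hat
#> 0.752 0.057 0.165 0.026
round(res$init_threshold, 3)
#> [1] 0.697
sum(res$per_cell$high_init_flag); res$n_malignant
#> [1] 350
#> [1] 1400
head(res$cluster_summary, 3)
#>   cluster n_cells mean_score rank
#> 1       8      86  0.7166219    1
#> 2      10      76  0.7105194    2
#> 3       0     145  0.6799485    3
subset(res$ora_table, q < 0.05)[, c("set", "overlap", "set_size", "q")]
#>           set overlap set_size            q
#> 1 emt_drivers      50       50 3.410470e-53
#> 2  glycolysis      50       50 3.410470e-53
#> 3    stemness      50       50 3.410470e-53
#> 4 mesenchymal      48       50 4.500041e-48

lab <- sim$truth$aggressive[match(res$per_cell$cell_id, sim$truth$cell_id)]
truth_roc(res$per_cell$initiation_score, lab)
#> [1] 0.949
```

Reading: PC1 weighting concentrates on the EMT-driver feature (w = 0.752) with
stemness next; exactly 25 % of malignant cells (350/1400) clear the 0.697
threshold; DE + ORA on high vs rest recover precisely the planted EMT-driver,
stemness and glycolysis programs; and the score ranks the planted aggressive
(hybrid ∧ stem-like ∧ glycolytic) cells with AUROC 0.949.

## Command line

```sh
metascore simulate --config sim.yaml --out simdir
metascore score --counts simdir/counts --signatures simdir/signatures.gmt \
                --labels simdir/ground_truth.tsv --config run.yaml --out outdir
metascore report --in outdir
```

The launcher is installed at
`system.file("cli", "metascore", package = "metascore")`; equivalently call
`metascore_cli(c("simulate", ...))` from R. Counts are accepted as Matrix
Market triplet directories (`matrix.mtx`, `barcodes.tsv`, `features.tsv`) or
dense CSV; signatures as GMT; configs as YAML or JSON. Identical configs give
byte-identical outputs.

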