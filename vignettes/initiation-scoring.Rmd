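---
title: "Scoring metastatic-initiation potential in single-nucleus RNA-seq"
author: "metascore developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring metastatic-initiation potential in single-nucleus RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`metascore` implements a per-cell quantification of early metastatic
("initiation") potential in malignant cells from single-nucleus RNA-seq. The
biological premise: initiation-competent cells co-express epithelial and
mesenchymal programs (a *hybrid EMT* state), activate stemness regulators, and
shift metabolism from oxidative phosphorylation toward glycolysis. The
pipeline scores each of these programs per cell, builds two composite
features, integrates them through first-principal-component (PC1) weights
into a single Molecular Initiation Score in [0, 1], classifies the top
quartile of cells as high-initiation, aggregates by Louvain cluster, and
validates the classification with differential expression and gene-set
over-representation.

This vignette is the package's account of the method: the model and its
assumptions, every tunable parameter and why its default is what it is, what
the synthetic-data generator does and does not emulate, the numerical
conventions, and the design decisions that were genuinely open.

## The scoring model

### Signature scores with expression-matched controls

For a gene set $g$ on the log-normalized matrix $x$,

$$\mathrm{score}_c(g) = \frac{1}{|g|}\sum_{j \in g} x_{cj}
 \;-\; \frac{1}{|C_g|}\sum_{j \in C_g} x_{cj},$$

where the control pool $C_g$ is assembled by ranking all genes by mean
expression, cutting them into `n_bins` equal-count bins (tied means share a
bin), and drawing `ctrl_size` genes — uniformly, without replacement, seeded —
from each signature gene's bin after excluding all signature genes. Bins with
fewer than `ctrl_size` eligible genes are merged symmetrically outward with
their neighbors; if fewer than `ctrl_size` eligible genes exist in the whole
matrix the entire pool is used (with a warning), and an empty pool is an
error. The pooled controls are deduplicated before averaging.

Subtracting an expression-matched background removes the cell-level
depth/complexity component that a plain signature mean would carry. Because
signature and control means shift identically, the score is invariant to
adding a constant to the matrix; raising only a cell's signature genes
strictly raises only that cell's score (the bins are computed from gene
means, so a perturbation small enough not to reorder gene means leaves every
other score bit-identical). Defaults `n_bins = 25`, `ctrl_size = 50` are the
conventional module-score defaults; the draw is governed by `score_seed` so
fixed input and seed give bit-identical scores.

### Composite features

Raw scores E (epithelial), M (mesenchymal), D (EMT drivers), S (stemness),
G (glycolysis), O (OXPHOS) are min–max normalized across the malignant cells
(hatted symbols). Two composites follow:

* **Hybrid EMT** $H = \min(\hat E, \hat M)$ — a cell is only as hybrid as its
  weaker program, so pure epithelial or pure mesenchymal cells score low.
  Cells at or above the `q_hybrid = 0.80` quantile of $H$ are flagged hybrid
  (the top-20% rule).
* **Metabolic reprogramming** $R = (\hat G + \varepsilon)/(\hat O +
  \varepsilon)$ with $\varepsilon = 0.01$. Raw signature scores can be zero
  or negative, so the ratio is taken on normalized scores with a pseudocount;
  $\hat G = \hat O = 0$ gives exactly 1 (no evidence either way). $R$ is
  min–max normalized to $\hat R$ before integration, keeping every feature on
  the same 0–1 scale.

### PC1 integration

The feature matrix $F = [\hat D, H, \hat S, \hat R]$ (fixed column order;
optional user-supplied normalized features, e.g. a genetic-alteration burden,
are appended) is column-centered and its first principal component computed.
The global sign of the loadings $v$ is fixed by requiring $v_{\hat D} \ge 0$,
and the integration weights are the normalized absolute loadings
$w = |v| / \sum |v|$. The score

$$I = F w \in [0, 1]$$

is therefore a convex combination of [0, 1] features. Two interpretations of
"PC1 provides the weights" exist — signed projections onto PC1 (which can
leave [0, 1] and depend on an arbitrary sign) or convex absolute-loading
weights. The convex reading is used here: it is scale-stable, keeps $I$ in
[0, 1] (consistent with published per-cell score ranges lying inside [0, 1]),
and makes $I$ monotone in every feature. An all-constant feature matrix has
no principal direction and is an error; a single constant feature simply
receives weight 0.

PC1 weighting has a consequence worth stating plainly: it rewards features by
their share of the dominant covariance axis. Features uncorrelated with that
axis get near-zero weight *even if they carry real signal*. The method is
therefore only sensible when the initiation programs actually co-vary across
cells — which is its biological premise — and the synthetic generator plants
exactly that structure (below).

### Classification, aggregation, validation

The high-initiation threshold $t$ is the `q_init = 0.75` quantile of $I$
under linear interpolation of order statistics (index $h = q(n-1)$,
interpolate between the flooring and ceiling order statistics — R's type-7
default). Flags are $I \ge t$, so ties at the threshold are included; with
all-distinct values and integer $(1-q)\,n$ the flagged fraction is exact.

Malignant cells are re-clustered (HVG → PCA → kNN → Louvain) and the
arithmetic mean of $I$ per cluster ranks clusters (ties by cluster id).
Differential expression contrasts high-initiation cells against the rest per
gene with a two-sided Wilcoxon rank-sum test: a tie-corrected,
continuity-corrected normal approximation, switching to exact enumeration
over all group assignments of the observed midranks when both groups have at
most 8 cells. Exhaustive enumeration of the tie-free 8-vs-8 null shows the
approximation is within 0.011 of the exact p uniformly (0.046 without the
continuity correction), which is why the correction is on. Fold change is
`log2((mean_hi + 1)/(mean_lo + 1))` on de-logged (`expm1`) normalized values.
"Significant" means Benjamini–Hochberg q < `alpha` (0.05). Over-representation
of each signature among significantly upregulated genes uses the upper-tail
hypergeometric test with the DE-tested genes as universe, BH-corrected across
sets. Note the standard BH step-up is *not* idempotent on already-adjusted
values (e.g. q = (0.02, 0.5) re-adjusts to (0.04, 0.5)); the tests check the
procedure against an independent implementation instead.

## Preprocessing chain

Order is fixed: QC (cells, then genes) → library-size normalization →
`log1p` → HVG selection → PCA → kNN graph → Louvain. Parameters, defaults and
rationale:

| parameter | default | meaning / rationale |
|---|---|---|
| `min_genes_per_cell` | 200 | drop near-empty nuclei; community default |
| `min_cells_per_gene` | 3 | drop all-but-unobserved genes |
| `max_mito_frac` | 0.2 | damaged-cell filter; mito genes by id prefix `MT-` (configurable — the convention is organism/annotation dependent) |
| `target_sum` | 10⁴ | counts-per-10k before `log1p`; community default |
| `n_hvg` | 2000 | binned-dispersion HVG count |
| `n_pcs` | 50 | embedding dimensions |
| `knn_k` | 15 | neighbors; union-symmetrized, weight-1 edges |
| `louvain_resolution` | 1.0 | classic modularity |
| `louvain_seed` | 0 | node-sweep order; pinned for reproducibility |

HVG selection computes dispersion = variance/mean per gene, z-scores it
within 20 equal-count mean bins, and takes the top `n_hvg` (ties by gene
order). Tied means share a bin, so genes with identical expression always
receive identical z-scores; a zero-variance bin z-scores to 0. PCA centers
genes and computes scores via the eigendecomposition of the smaller Gram or
covariance matrix (numerically equivalent to SVD scores, tested against a
dense SVD oracle at 1e-8); each component's sign is fixed so its
largest-magnitude loading is positive, and requests beyond the numerical
rank (relative tolerance 1e-12) truncate with a warning. Louvain is
igraph's multilevel implementation with the resolution parameter, sweep
order seeded; returned ids are relabeled by decreasing cluster size from 0.

### Malignant-cell isolation

If per-cell labels are supplied (`--labels` / `malignant_labels`) they are
authoritative — matching how such analyses usually inherit malignant calls
from upstream annotation or CNV inference. Otherwise a placeholder rule is
applied: clusters whose mean malignant-signature score strictly exceeds the
median of cluster means are flagged. The strict median rule can, by
construction, flag at most half the clusters, so it is only applicable to
tumor-minority samples whose malignant compartment is concentrated in few
clusters; with all cluster means equal nothing is flagged. This limitation
is inherent to the rule (the original procedure is unspecified), documented
here rather than papered over: for tumor-rich samples, supply labels.

## The synthetic-data generator

`simulate_dataset()` emulates a malignant epithelial tumor sample at the
level of statistical structure the scoring model assumes:

* **Counts**: gene baselines are log-normal(0, 1); cell $c$'s expected
  profile multiplies the baseline by $e^{\mathrm{effect}}$ on every program
  the cell carries, is normalized to proportions, and scaled by a log-normal
  library size (natural-scale mean `lib_size_mean` = 5000, typical snRNA-seq
  depth; `lib_size_sigma` = 0.35). Counts are negative-binomial with
  inverse-dispersion `dispersion` = 2 (strong overdispersion).
* **Programs**: pairwise-disjoint gene blocks of `program_size` = 50 for the
  six signatures, a malignant marker program, and one identity program per
  planted cluster — so the configuration is rejected unless
  `(7 + n_clusters) * program_size <= n_genes`.
* **States**: 70% of cells are malignant (tumor-rich biopsy). Among them,
  20% are hybrid EMT (the published top-20% convention), the rest split
  evenly into epithelial and mesenchymal; 20% are stem-like; 30% glycolytic
  (the rest oxidative). Hybrid cells carry both EMT programs at half effect
  (intermediate co-expression); mesenchymal and hybrid cells carry the EMT
  drivers; non-malignant cells are epithelial, oxidative, non-stem.
* **Co-occurrence**: the hybrid, stem-like and glycolytic flags are cut from
  a shared latent standard-normal propensity mixed with independent noise
  (`state_correlation` = 0.6), so marginal fractions are exact while the
  programs co-occur. This is deliberate and load-bearing: with independent
  flags the feature covariance is near-diagonal, PC1 collapses onto a single
  feature, and the integration step cannot be exercised meaningfully. The
  *aggressive* ground-truth label is the conjunction hybrid ∧ stem-like ∧
  glycolytic — a harness convention operationalizing initiation-competent
  cells, not a biological claim.

One RNG stream per dataset, seeded from `config$seed`: identical configs are
bit-identical. With `effect_size = 0` every multiplier is 1 and all labels
are independent of the counts, giving the null world used for calibration.

What the generator does **not** emulate: doublets, ambient RNA, batch
effects, spatial structure, gene-gene correlation beyond the planted
programs, zero inflation beyond NB sampling, or realistic gene-length/GC
biases. A green recovery test therefore establishes that the pipeline
recovers planted structure under idealized noise — not that it is robust to
artifacts real snRNA-seq carries.

## Numerical conventions and degenerate inputs

* Min–max normalization maps a constant vector to all zeros (no spread = no
  evidence of activation).
* The top-quantile rule flags $x \ge t$: a totally tied vector flags every
  cell (documented edge).
* Exact rank-sum two-sided p is `min(1, 2·min(P(W≤w), P(W≥w)))` over the
  conditional distribution of the observed midranks, so heavy ties are exact.
* Signature genes absent from the matrix are dropped with a counted warning;
  gene identity is by case-sensitive symbol string.
* All result files are written without timestamps; identical runs are
  byte-identical (verified by hashing in the test suite), with provenance via
  a config hash, seeds, and package version in `run_report.json`.

## Calibration and recovery (computed by the tests)

The test suite and `scripts/acceptance.R` — not this document — establish:
exact 25%/20% flag fractions on distinct scores; agreement of the scoring,
PCA, and quantile implementations with independent brute-force oracles
(1e-10 / 1e-8); the exact combinatorial values (2/70, 0.04, 3003/184756);
full-pipeline AUROC against the planted aggressive label at
2000 cells × 2000 genes with all planted markers BH-significant; ~0.5 mean
AUROC and ~5% type-I error across 20 null seeds (the type-I check uses a
random balanced split: flags derived from the score are functions of the same
matrix, so conditioning on them would measure selection, not calibration);
and byte-identical repeated runs. Null-calibration and cluster-recovery
simulations run at reduced size (~400 cells × 300 genes) purely for runtime;
the generative model and all thresholds are unchanged.

## Known limitations

* The published per-sample headline numbers for the original NSCLC tumor
  (score mean/range, threshold, cell and cluster counts) require that
  specific dataset, which has no public accession; they are reproducible in
  procedure, not in value, and are asserted nowhere.
* Which gene lists constitute each signature is user input; the package
  ships only the simulator's planted sets. Real analyses should supply
  curated collections (e.g. hallmark EMT/glycolysis/OXPHOS lists) as GMT.
* PC1 weighting ignores initiation axes uncorrelated with the dominant one;
  inspect `res$model$weights` before interpreting the score.
* The median-rule malignant caller is a placeholder for unlabeled
  tumor-minority samples only.
* Dissemination and colonization phases of the metastatic cascade, imaging
  and histology-derived features, and cross-level ensembles beyond the
  molecular/cellular features above are out of scope; a genetic-alteration
  feature can only enter as a user-supplied per-cell covariate.
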