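# lincell

Parameter-free linear pipelines for single-cell transcriptomics.

Single-cell RNA-seq benchmarks — cell-type annotation, cross-species label
transfer, disease-state identification, TF–target association — are
increasingly approached with large pretrained models. `lincell` implements
the opposing baseline: carefully normalized, almost parameter-free linear
methods, built so their claims are testable end to end on synthetic data
with planted ground truth. It is aimed at computational biologists who want
a strong, interpretable, cheaply reproducible baseline (or a null model for
benchmarking representation-learning claims).

## What's inside

At the core is a per-cell rank normalization: with *G* genes, the gene at
average within-cell rank *r* scores

    z = Φ⁻¹( r / (G + 1) )

so a gene at the 50th within-cell percentile gets *z* = 0 and one at the
84th percentile *z* ≈ 1. Scores depend only on within-cell ranks, so
library size and batch-level monotone distortions cancel and cells never
share information.

On top of that:

* **scTOP projection classifier** — cell types as pseudo-bulk basis vectors
  *B*; a cell *x* gets coefficients solving `(BᵀB) a = Bᵀx` and the label of
  its largest coefficient. No fitted parameters.
* **Cross-species transfer** (`classify_transfer`, `transfer_experiment`)
  over one-to-one ortholog maps, scored by macro F1.
* **Similarity structure** (`celltype_similarity`, `species_similarity`,
  `distance_correlation`) — cosine similarities of pseudo-bulk vectors and
  their Spearman association with evolutionary distance.
* **Denoising classifier** (`run_tissue_pipeline`) — ANOVA gene selection,
  gene-wise standardization, PCA, ridge logistic regression, five-fold CV;
  all statistics fitted on training data only.
* **Cluster-local disease classifier** (`run_disease_pipeline`) — Leiden
  clustering in PCA space (blind to disease labels), one class-weighted
  classifier per cluster, pooled macro F1 against a global-model baseline.
* **TF–target enrichment** (`enrichment_screen`) — PMI-style conditional
  co-expression score, permutation-null z, Benjamini–Hochberg FDR,
  optional validation against an interaction reference.
* **Geometry diagnostic** (`linearity_score`, `embed_2d`) — Pearson
  correlation between kNN-graph geodesic and Euclidean distances as a
  function of *k*; near 1 means the data occupy a near-linear subspace.
* **Synthetic generator** (`synthetic_config`, `generate_synthetic`,
  `benchmark_suite`) — seeded NB counts with dropout, batch factors,
  species divergence as Brownian drift on log-programs, cluster-local
  infection effects, planted TF edges; ground truth returned alongside.

A thin command-line wrapper (`inst/cli/lincell.R`, subcommands `simulate`,
`normalize`, `sctop`, `transfer`, `similarity`, `classify`, `disease`,
`enrich`, `geometry`) exposes the same functions on MatrixMarket-directory
datasets.

## Worked example

Simulate two species sharing three cell-type programs (the second species
diverged), transfer human labels to mouse, and inspect the normalization:

```r
library(lincell)

sim <- generate_synthetic(synthetic_config(
  n_genes    = 300,
  cell_types = data.frame(name = c("alpha", "beta", "gamma"),
                          n_cells = c(100, 100, 100)),
  species    = data.frame(name = c("human", "mouse"),
                          divergence = c(0, 0.5)),
  seed = 1))

res <- classify_transfer(sim$datasets$human, sim$datasets$mouse,
                         omap = sim$omaps[[1]])
round(res$macro_f1, 3)
#> [1] 1
res$projection
#> ProjectionResult: 300 cells, 3 types
#> alpha  beta gamma
#>   100   100   100

round(normalize_cell(c(0, 1, 2, 3, 4)), 4)
#> [1] -0.9674 -0.4307  0.0000  0.4307  0.9674
```

The macro F1 of 1 means every mouse cell was assigned its true type from
the human basis after ortholog harmonization — at this modest divergence
the conserved rank structure of the programs fully determines the labels
(larger divergences degrade it; see `transfer_experiment`). The normalized
vector shows the rank-to-z mapping: five distinct counts map to the normal
quantiles of 1/6 … 5/6, with the median count at exactly 0.

The methods vignette (`vignettes/linear-pipelines.Rmd`) documents the
models, defaults, numerical conventions and the generator's scope.

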