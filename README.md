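# cellattn

Interpretable additive-attention classification of single-cell RNA-seq.

Single-cell analyses constantly need to answer *which genes made the model
call this cell (or this cluster) what it is*. `cellattn` trains a compact
neural classifier on a raw cells × genes count matrix X ∈ ℝ^{C×N} whose core
is an explicit attention tensor: a linear map of each cell's expression row
produces per-gene logits, a row softmax turns them into attention weights

    A_ij = exp(L_ij) / Σ_j' exp(L_ij'),      Γ = A ⊙ X,

and the gene scores Γ flow through k = 2 projection blocks (h = 4 parallel
linear branches, concatenation, an N→128→N ReLU subnetwork, a residual from
Γ, LayerNorm) into a linear configuration head with a Leaky ReLU that emits
the class logits. The model is trained once with cross-entropy (Adam,
lr 1e-4, 50 epochs, exponential decay γ = 0.95 from epoch 10 every 5
epochs) against true labels or cluster pseudo-labels; the trained attention
tensor A then drives every downstream task without retraining:

- **Global marker selection** — genes ranked by mean attention, evaluated by
  KNN weighted F1 and fraction of variance explained for top-n gene sets
  (`global_markers`, `feature_curve`);
- **Per-cluster markers and unsupervised annotation** — top attentive genes
  per cluster, queried against a GMT gene-set library with one-sided
  hypergeometric tests and Benjamini–Hochberg correction
  (`cluster_markers`, `enrich`, `annotate_clusters`);
- **Attention-correlation analysis** — Pearson correlation of per-class
  mean attention profiles (`attention_correlation`);
- **Transfer learning** — freeze the attention and projection modules,
  replace or warm-start the head, and fine-tune it on 20% of a query
  dataset (`freeze_feature_modules`, `replace_head`, `align_genes`,
  `fine_tune`).

The package also ships the standard scaffolding: QC filtering and
highly-variable-gene selection (`filter_counts`, `select_hvg`), a
negative-binomial simulator with planted per-type markers
(`simulate_counts`, `make_transfer_pair`), MatrixMarket/CSV/GMT readers and
writers, a versioned binary checkpoint format, and a command-line interface
(`inst/cli/cellattn-cli.R`) with `simulate`, `qc`, `train`, `markers`,
`annotate`, `evaluate` and `transfer` subcommands. The whole stack is plain
R; no deep-learning framework is required, and gradients are verified
against finite differences in the test suite.

## A worked example

```r
library(cellattn)

sim <- simulate_counts(simulation_config(
  n_cells = 2000, n_genes = 200, n_types = 5, markers_per_type = 10,
  marker_fold = 8, seed = 11))
fit <- cellattn(sim$data, config = train_config(epochs = 50, seed = 11))
fit
#> Additive-attention cell classifier
#>   genes: 200  classes: 5  blocks: 2  branches: 4  bottleneck: 128
#>   trained 50 epochs (1600 train / 400 validation cells)
#>   final: loss 0.0080, validation accuracy 0.998, weighted F1 0.997
```

The validation weighted F1 of 0.997 says the five planted types are
essentially perfectly recognized on the 400 held-out cells. The attention
tensor now identifies the genes behind those calls:

```r
A <- predict(fit, sim$data, type = "attention")
cm <- cluster_markers(A, sim$data$labels, top_n = 10)
head(cm$type1$gene, 5)
#> [1] "GENE0008" "GENE0006" "GENE0003" "GENE0004" "GENE0005"
```

Genes 1–10 are the markers planted for type 1, and the type's top attentive
genes are exactly drawn from them. Querying each cluster's top-50 attentive
genes against the simulation's gene-set library annotates every cluster
correctly:

```r
annotate_clusters(A, sim$data$labels, sim$gmt)
#> Cluster annotation (top enrichment call per cluster):
#>   type1 -> type1 (adjusted p = 2.29e-06)
#>   type2 -> type2 (adjusted p = 2.29e-06)
#>   type3 -> type3 (adjusted p = 2.29e-06)
#>   type4 -> type4 (adjusted p = 2.29e-06)
#>   type5 -> type5 (adjusted p = 2.29e-06)
```

The adjusted p-values are the Benjamini–Hochberg-corrected upper-tail
hypergeometric probabilities of each cluster's marker overlap with its
called gene set. Since the five types share no markers, their attention
profiles are mutually uncorrelated:

```r
round(attention_correlation(A, sim$data$labels)[1:2, 1:2], 3)
#>        type1  type2
#> type1  1.000 -0.095
#> type2 -0.095  1.000
```

See `vignettes/attention-methods.Rmd` for the model, its assumptions, and
every tunable parameter.

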