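# scmoa — cell subtype classification from single-cell multi-omics with omics-level attention

Parallel single-cell assays measure gene expression, DNA methylation and
chromatin accessibility in the same cells, but most automated cell-type
annotation uses RNA alone. `scmoa` is for computational biologists who
have such co-assayed data (or want to study the method itself): it anchors
all three omics to genes, integrates them with a per-omics self-attention
network, classifies cells into subtypes, and reads the learned attention
back out as ranked marker-gene candidates.

## The model

Each omics layer is first reduced to a gene-anchored matrix:
library-normalised `log1p` expression per gene, the mean beta of the CpG
sites within 2 kb of each TSS (a *CpG cluster*, mean-imputed across
cells), and the summed peak signal over each gene body (*gene activity*).
Only genes present in every layer are kept, and expression/accessibility
are min–max scaled to `[0, 1]`.

Within one omics, a cell's feature *j* with value $x^{(j)}$ is embedded
with a trainable random vector $e_j$ and read by two heads:

$$\hat x^{(j)} = e_j x^{(j)}, \qquad
  \bar x^{(j)} = \tanh(W_1 \hat x^{(j)} + b_1), \qquad
  s^{(j)} = W_3^\top \tanh(W_2 \hat x^{(j)} + b_2)$$

$$\alpha = \operatorname{softmax}(s), \qquad
  c = \textstyle\sum_j \alpha^{(j)} \bar x^{(j)}$$

The attention-pooled context $c$ (one per omics, standardised per
dimension) is concatenated across omics and classified by a two-layer
softmax head trained with cross-entropy (Adam, 300 epochs, batch 128,
dropout 0.2). The per-feature mean of $\alpha$ ranks marker candidates;
the top 30 per omics are validated by one-way ANOVA across subtypes at
p < 0.01. A `use_attention = FALSE` ablation and all omics-combination
ablations are built in, as is a synthetic multi-omics generator with
planted markers so everything is testable without external data.

## Worked example

```r
library(scmoa)
sim <- sim_config(n_cells = 300, n_genes = 60, n_subtypes = 3,
                  markers_per_omics = 6, seed = 42)
raw <- generate_multiomics(sim)
mats <- preprocess_multiomics(expr = raw$expression, meth = raw$methylation,
                              acc = raw$accessibility, ann = raw$annotation)
dataset <- intersect_by_gene(mats) |> align_labels(raw$labels)

cfg <- attention_config(epochs = 100, seed = 7)
model <- train_attention(dataset, cfg)
run_cv(dataset, cfg, k = 3, seed = 7)
#> <cv_result> 3-fold CV, 300 cells
#>   accuracy     0.9800 +/- 0.0100
#>   auc          0.9995 +/- 0.0005
#>   f1_weighted  0.9800 +/- 0.0100
#>   mcc          0.9701 +/- 0.0150

rep <- marker_report(dataset, model, top_k = 10)
head(rep$markers[, c("omics", "feature_id", "mean_attention", "rank",
                     "p_value", "significant")], 5)
#> # A tibble: 5 × 6
#>   omics         feature_id  mean_attention  rank  p_value significant
#> 1 accessibility gene014_act         0.0182     1 1.39e-40 TRUE
#> 2 accessibility gene013_act         0.0182     2 3.07e-61 TRUE
#> 3 accessibility gene018_act         0.0178     3 1.04e-38 TRUE
#> 4 accessibility gene025_act         0.0175     4 8.58e- 2 FALSE
#> 5 accessibility gene022_act         0.0172     5 1.38e- 1 FALSE
```

The cross-validated metrics say the three integrated layers recover the
planted subtype structure almost perfectly on held-out cells; in the
marker table, features ranked by mean attention that correspond to
planted markers carry vanishing ANOVA p-values (subtype-specific
abundance), while high-attention noise features are correctly left
unflagged. In this run all 6 planted expression markers appear in the
expression top-10 list.

`tidy()`, `glance()` and `autoplot()` methods are provided for fitted
models, cross-validation results and attention reports; `run_pipeline()`
(or the `inst/scripts/scmoa` wrapper) chains
simulate → preprocess → select → train → cv → markers over files with a
reproducibility manifest.

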