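# pathnn — pathway-primed neural networks for single-cell RNA-seq

Identifying and annotating cell types is a central task in single-cell
RNA-seq analysis, and deep classifiers do it well — at the price of
interpretability. `pathnn` implements a knowledge-masked feed-forward
network for analysts who want both: a classifier whose first hidden layer
has one node per biological gene set (a KEGG-style pathway, a PPI cluster, a
regulon), with the gene→node weight fixed to exactly zero whenever the gene
is not a member of the node's set. The network

$$x^i = a\,(W^i x^{i-1} + b^i), \qquad p = \mathrm{softmax}(W^{out} x^{L} + b^{out})$$

is trained supervised on cell-type labels by minimising the cross-entropy
$-\sum_c y_{o,c}\log p_{o,c}$, and then reused unsupervised:

* **encoding** — the last hidden layer's activations, a low-dimensional cell
  representation for K-Means clustering, nearest-neighbour retrieval and
  t-SNE/PCA visualisation;
* **pathway activities** — the first hidden layer's activations, one
  interpretable score per pathway and cell;
* **interpretation** — top-weighted pathways per cell type, and
  hypergeometric gene-set enrichment with Benjamini–Hochberg FDR control.

The masking makes the model roughly ten times smaller than an equally wide
dense network (0.01 M vs 0.95 M effective parameters at mouse-compendium
scale) while keeping every hidden node mapped to a named biological
function.

The package also ships the full validation methodology — repeated
stratified holdout, leave-P-groups-out clustering validation scored with six
external indices (homogeneity, completeness, V-measure, ARI, AMI,
Fowlkes–Mallows), k-nearest-neighbour retrieval scored by mean average
precision, and hyperband hyperparameter search — plus a negative-binomial
synthetic data generator with known pathway-driven ground truth, so the
whole pipeline is testable without any downloads.

## Worked example

```r
library(pathnn)

## synthetic data with known truth: 5 cell types x 200 cells, 2000 genes,
## 20 disjoint pathways of 40 genes, 3 active pathways per type
ds <- generate_dataset(synthetic_config(seed = 1))

## restrict to pathway genes, build the mask, standardise per gene
inter <- intersect_gene_space(ds$expression, ds$gene_sets, "biological_only")
mask  <- build_mask(colnames(inter$expression), inter$collection)
pp    <- preprocess_expression(inter$expression, "zscore")

## one masked hidden layer (20 pathway nodes), softmax over 5 types
cfg   <- network_config(colnames(inter$expression), n_classes = 5, seed = 1)
model <- train_network(build_network(cfg, mask), pp$expression, ds$labels,
                       training_config(seed = 1))
model
#> pathnn_model: 800 -> 20 -> 5 (tanh hidden, softmax output), trained
#>   first layer: 20 biological node(s), 0 dense node(s); 800 unmasked gene->node weights
#>   classes: type01, type02, type03, type04, type05

## supervised reuse
mean(predict_proba(model, pp$expression)$predicted == ds$labels)
#> [1] 1

## unsupervised reuse: encode, cluster, compare with the true types
enc <- encode(model, pp$expression)          # 1000 cells x 20 dims
cm  <- clustering_metrics(ds$labels, kmeans_cluster(enc, K = 5, seed = 1))
c(ari = cm$ari, ami = cm$ami, v = cm$v_measure)
#>  ari  ami    v
#>    1    1    1

## interpretation: top pathways per type recover the generative truth
top_nodes_per_class(model, n = 3)$type01
#>   node    weight
#> 1 PW04 -1.581599
#> 2 PW05 -1.560051
#> 3 PW07  1.044213
ds$truth$type01
#> [1] "PW04" "PW05" "PW07"

count_effective_parameters(cfg, mask)
#> [1] 925
```

The encoding clusters the five types perfectly (all six clustering indices
reach 1.0) and the three top-weighted nodes of each class are exactly the
pathways the generator activated for that type. Note the weights are ranked
by magnitude: with a tanh layer the sign of an output weight is arbitrary
(flipping a hidden node's incoming and outgoing weights is an exact network
symmetry), so strongly negative pathways are just as decisive.

A command-line interface wrapping the same functions is installed at
`inst/cli/pathnn`, with subcommands `simulate`, `train`, `encode`,
`holdout`, `lpgo`, `retrieve`, `tune` and `interpret`, each driven by one
YAML config (see `?pathnn_main`).

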