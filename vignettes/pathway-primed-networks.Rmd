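---
title: "Pathway-primed neural networks: model, validation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-primed neural networks: model, validation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathnn)
```

## The model

`pathnn` trains a feed-forward classifier on cell-type labels and then reuses
its internals for unsupervised work. The network propagates a cell's
expression profile $x^0$ through one or two hidden layers,

$$x^i = a\,(W^i x^{i-1} + b^i),$$

with an elementwise activation $a$ (tanh by default; relu, sigmoid and linear
are available) and a softmax output over the $M$ cell types. Training
minimises the multiclass cross-entropy
$-\sum_{c=1}^{M} y_{o,c}\log p_{o,c}$, averaged over the cells $o$ of each
mini-batch.

What makes the model interpretable is the *prior mask*. Each node of the
first hidden layer is tied to one gene set (a KEGG-style signaling pathway,
a PPI cluster, a regulon — anything expressible as a GMT line), and the
weight from gene $g$ to node $j$ is fixed at exactly zero unless $g$ belongs
to set $j$. Two consequences follow:

* the first hidden layer's activations are *pathway activities* — each node
  can only ever read its own genes;
* the network is sparse. A dense hidden layer of 100 nodes over 9437 genes
  costs about 0.95 M parameters; a 92-pathway masked layer over the same
  data costs about 0.01 M. `count_effective_parameters()` reports this free
  weight + bias count for any configuration.

After training, `encode()` detaches the output layer and returns the last
hidden layer's activations as a low-dimensional cell representation used for
clustering, retrieval and 2-D visualisation; `pathway_activities()` stops at
the first hidden layer instead.

Masking is enforced twice: gradients into masked positions are zeroed before
every update, and the weight matrix is re-multiplied by the mask after every
optimizer step. The second pass is defensive — with plain SGD/momentum/Adam
on exactly-zero weights and zero gradients it is a no-op, but it guarantees
the invariant against any future update rule that perturbs zeros.

Hybrid first layers concatenate unconstrained dense nodes before the
biological nodes; dense nodes see every input gene. Only the first hidden
layer may carry a mask; deeper layers are dense.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| activation | `tanh` | works best with standardised inputs; `relu` pairs naturally with `log1p` data |
| epochs | 100 | no early stopping; the final-epoch model is returned |
| batch size | 10 | mini-batch SGD |
| SGD learning rate / momentum / decay | 0.01 / 0.9 / 0 | decay uses the classic `lr / (1 + decay * step)` schedule over global steps |
| Adam learning rate | 0.001 | standard $\beta_1 = 0.9$, $\beta_2 = 0.999$ |
| retrieval `k` | 100 | euclidean neighbours; clamped to the reference size with a warning |
| enrichment $\alpha$ | 0.05 | BH-adjusted q-value threshold |

All random draws (Glorot initialisation, epoch shuffling, splits, K-Means
restarts, t-SNE initialisation) are seeded, and protocol repeats derive
their seeds as `base_seed + repeat`, so any single repeat can be re-run in
isolation from the persisted report.

## Preprocessing

Expression matrices are preprocessed per gene with one of `log1p`, `zscore`,
`minmax_sym` (affine map of the training range onto $[-1, 1]$, test values
clipped) or `none`. "Normalisation" is implemented as per-gene z-scoring —
the most common reading for tanh networks — and is the default throughout
the protocols; the alternatives remain one keyword away. Statistics are
always fit on the training fold and reused on held-out data; the protocol
reports record a checksum of the fitted statistics so leakage is testable.
Zero-variance genes map to 0 under both `zscore` and `minmax_sym`.

## Validation protocols

**Repeated stratified holdout** (default 100 repeats, test fraction 0.30)
measures plain supervised performance: accuracy, balanced accuracy, and
precision/recall/F1 under macro, micro and weighted averaging. Per-class
test counts use largest-remainder apportionment, which reproduces exact
proportional splits and guarantees each class keeps a training cell.

**Leave-P-groups-out (LPGO)** simulates unseen cell types: all cells of P
randomly drawn types form the test fold, the network trains on the
complementary types, the held-out cells are encoded, K-Means clusters the
encodings, and six external indices (homogeneity, completeness, V-measure,
ARI, AMI, Fowlkes-Mallows) compare clusters with the never-seen labels.
K equals P — the number of distinct held-out types — since that is the only
choice that makes the comparison with supervised labels meaningful. K-Means
uses 10 seeded restarts. Entropy-based indices use natural logarithms and
AMI uses arithmetic-mean normalisation.

**Retrieval** trains on a full learning set, encodes both the learning and a
disjoint retrieval set, and scores each query by the average precision of
same-class matches among its k = 100 nearest reference encodings (euclidean,
distance ties broken by ascending reference index). AP normalises by the
number of relevant neighbours within the top k; with a fixed k and widely
varying class sizes this keeps per-class scores comparable, and
total-relevant normalisation is available via `total_relevant`. The table's
mean is unweighted over query classes. Query classes absent from the
reference score 0 by definition. Because the two sets are disjoint, no
self-match exclusion is needed; `exclude_self` exists for self-retrieval
runs.

**Hyperband** searches the SGD learning rate (log-uniform), momentum
(uniform) and decay (log-uniform) with standard successive-halving brackets
($s_{max} = \lfloor \log_\eta R \rfloor$; bracket $s$ starts
$\lceil \frac{s_{max}+1}{s+1}\eta^s \rceil$ configurations at $R/\eta^s$
epochs). The objective is evaluated on an internal stratified 80/20 split of
the learning data, so any external evaluation set is never touched; models
are retrained from scratch at each rung's budget.

## Interpretation

`top_nodes_per_class()` ranks biological nodes per cell type by the weight
connecting them to that type's output node. Ranking uses weight *magnitude*
by default. The reason is a symmetry argument: with an odd activation such
as tanh and a sign-symmetric initialisation, flipping the sign of a hidden
node's incoming weight column and its outgoing weights leaves the network's
function unchanged, so the sign of an individual output weight carries no
information — a pathway strongly *negatively* wired to a class is exactly as
decisive as a positively wired one. In practice signed ranking misses about
half of the truly class-driving pathways on synthetic data with known truth,
while magnitude ranking recovers them reliably; signed ordering is still
available with `use_abs = FALSE`. For two-hidden-layer designs there is no
single canonical notion of "the" node-to-class weight, so both options are
exposed: the default scores first-layer node $j$ for class $c$ by
$\sum_h |W^2_{jh} W^3_{hc}|$, and `strategy = "output"` ranks the
last-hidden (dense) nodes literally.

Gene lists from top-ranked pathways feed `hypergeometric_enrichment()`: a
one-sided upper-tail hypergeometric test per annotation term with
Benjamini-Hochberg adjustment at $\alpha = 0.05$. The universe defaults to
the model's input gene space — the genes the network could possibly have
used — rather than a whole genome, and zero-overlap terms are kept at
p = 1 so the BH divisor equals the number of tested terms.

## The synthetic generator

`generate_dataset()` emulates the one property everything above depends on:
cell types that differ through the activity of designated gene sets. Genes
are partitioned into disjoint pathways (20 × 40 genes by default) plus 20%
unstructured background; each of 5 types activates 3 random pathways; counts
are negative binomial (mean 2, dispersion 0.5 on the
$\mathrm{var} = \mu + \alpha\mu^2$ scale) with a +2 log-mean shift on
active-pathway genes; 20% of entries are then zeroed to mimic dropout.
These defaults produce a clearly but not trivially separable dataset —
raw per-gene signal is heavily diluted by dropout and NB noise, yet 1000
cells suffice for the network to recover the structure.

What it deliberately does *not* emulate: library-size variation, batch
effects, overlapping pathways (an overlap between sets can be introduced by
editing the returned collection), gene–gene correlation beyond the pathway
blocks, and realistic mean–variance trends. Tests passing on this generator
therefore demonstrate that the machinery is correct and that pathway-driven
signal is recovered when present; they do not certify performance on real
tissue atlases.

The test suite and the acceptance script run this generator at its default
size (1000–1200 cells × 2000 genes) for the headline checks and at roughly
a tenth of that for unit tests — sizes chosen so the whole suite stays
interactive while the headline runs still train 100-epoch networks on
realistic dimensionalities.

## Numerical choices

* Probabilities are clipped to $[10^{-12}, 1]$ before logs; softmax is
  max-shifted.
* Argmax ties in prediction break toward the lowest class index; class
  order is the lexicographic sort of training labels.
* Glorot-uniform limits $\sqrt{6/(fan_{in}+fan_{out})}$; biases start at 0.
  The full first-layer matrix is drawn before masking, so an all-ones mask
  reproduces the dense network bit for bit under a shared seed.
* relu's derivative at 0 is taken as 0 (subgradient convention).
* K-Means degenerates gracefully: K equal to the number of cells returns
  singletons directly.
* t-SNE is an exact implementation (dense affinities): per-point bandwidth
  by 50-step bisection to the target perplexity (clamped to
  $(n-1)/3$), early exaggeration ×4 for 100 iterations, momentum 0.5→0.8,
  learning rate 200. Suitable for the few thousand cells an encoding holds.
* The model serialises to a single JSON file at full double precision;
  a round trip reproduces predictions to numerical precision.

## Known limitations

* Training is plain R matrix code: fast for masked architectures of the
  size pathways induce (~10² nodes, ~10³–10⁴ genes), but not meant for
  genome-wide dense layers on 10⁵ cells.
* Only the first hidden layer may carry biological structure.
* No dropout layers, early stopping or class reweighting — the training
  recipe is deliberately the simple one described above, and imbalanced
  data will show the usual minority-class degradation in the per-class
  tables.
* Gene identifiers match by exact string equality (after whitespace
  stripping); symbol aliasing is a data-preparation concern upstream of
  this package.
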