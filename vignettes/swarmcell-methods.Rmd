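---
title: "Decentralized cell-type classification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decentralized cell-type classification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Cell-type annotation of single-cell RNA-seq data is typically manual,
irreproducible, and hard to scale across laboratories; privacy constraints on
human data make pooling raw count matrices across institutions difficult.
Swarm learning addresses this by training one classifier collaboratively:
each peer (study/institution) keeps its data private, trains a local model
replica, and periodically merges model *parameters* — never data — with the
other peers. `swarmcell` implements the complete workflow in-process: a
synthetic multi-study data generator, per-study preprocessing, a
seed-deterministic multilayer-perceptron (MLP) classifier, a deterministic
simulator of the swarm protocol, the local-vs-swarm experiment grid, and the
evaluation battery. The central scientific question the package makes
testable is whether decentralized training costs predictive performance
relative to training on pooled data. On its synthetic benchmark the answer,
as in the decentralized-learning literature, is that it does not (the paired
weighted-F1 gap is well under 0.05).

# Preprocessing model

Each study is preprocessed independently; **no batch correction is performed
anywhere**, because in a decentralized setting no peer can see another's
data.

**Quality control.** Four per-cell metrics are computed: `log1p` total
counts, `log1p` number of detected genes, the percentage of counts in the
cell's 20 most expressed genes, and the percentage of counts on
mitochondrial (`MT-`) genes. A cell is removed iff any metric lies more than
5 unscaled median absolute deviations (MADs) from the study median, or its
mitochondrial percentage *strictly exceeds* 8% (a cell at exactly 8% is
kept), or it has zero counts. Two deliberate readings: the MAD carries no
1.4826 normal-consistency factor (the common convention in single-cell QC),
and the rule is two-sided via the absolute deviation. Because the MAD
margins are data-dependent, QC is *not* idempotent; the pipeline applies it
exactly once per study.

**Normalization.** Counts are scaled to 10,000 per cell and transformed with
`log(1 + x)`. All-zero cells map to all-zero rows and the zero pattern is
preserved.

**Feature selection.** Per study, the 2,000 most highly variable genes
(HVGs) are selected. No specific HVG flavor is canonical, so the package
fixes one precisely so results are reproducible: per-gene dispersion
(variance/mean) on the normalized log1p matrix, z-scored within 20
equal-frequency mean-expression bins (bins with fewer than two genes fall
back to the raw dispersion), ties broken lexicographically by gene id. The
choice to compute dispersions after normalization (rather than on raw
counts, where library size dominates) is configurable via
`use_normalized = FALSE`.

**Union feature space.** The shared feature set is the sorted set-union of
the per-study HVG lists. By default the union is taken over *training*
studies only, so no information about the test study's gene variability
leaks into the model's feature space; `include_test = TRUE` restores a union
over all studies. Each study's matrix is projected onto the union,
zero-filling genes it lacks.

# The classifier

A multilayer perceptron with two hidden layers of 128 and 32 units, `tanh`
activations, softmax output, and mean cross-entropy loss, trained with Adam
(learning rate `1e-3`, no weight decay) at batch size 128 for a fixed 100
epochs. A stratified 10% validation split is carved per peer for monitoring
only — there is no early stopping, so the whole fit is a pure function of
(data, hyperparameters, seed). Design points the architecture leaves open
and how the package fixes them:

* **Initialization**: Glorot-uniform weights (appropriate for `tanh`), zero
  biases, seeded.
* **Argmax ties** at prediction are broken by the lowest class index, making
  confusion matrices reproducible.
* **Class vocabulary** is the union of labels over the collection's studies;
  classes absent from the training data simply receive no gradient.
* Alternative configurations (ReLU/LeakyReLU, dropout, AdamW-style decoupled
  weight decay, inverse-frequency class weights, other batch sizes) are
  expressible through `mlp_hyperparams()`; the package asserts they run but
  makes no claim about their relative performance.

The implementation is plain R matrix code rather than a deep-learning
framework: the protocol under study requires bit-reproducible optimizer
state and externally mergeable parameters, which a ~50k-parameter MLP on
tabular input does not need a framework for.

# The swarm protocol, simulated

The real deployment runs on a blockchain-coordinated network (node identity,
encrypted parameter exchange, leader election). Those are infrastructure,
not learning dynamics; the package simulates the protocol deterministically
in-process and the sync log stands in for the ledger:

1. All peers start from the **same seeded initialization** — averaging
   early-training weights from unrelated initializations is meaningless.
2. Training proceeds in lockstep rounds; at each round every peer consumes
   one minibatch from its own seeded shuffle. Peers with fewer batches per
   epoch wrap to a new local epoch, the deterministic equivalent of peers
   proceeding at their own pace.
3. After every `sync_interval_batches` rounds, peer weights and biases are
   replaced by their weighted average, with weights proportional to dataset
   size (per-event normalization). **Adam moments are kept per-peer** — the
   protocol exchanges weights and biases only.
4. Total rounds are `epochs * max_i ceiling(n_i / batch_size)`; a final
   merge always produces the unified model.

Two implementation details matter for exactness. Peer RNG streams are
derived by hashing the global seed with the peer *identifier* (not its list
position): this makes a one-peer swarm bitwise identical to the pooled local
fit, makes the no-sync swarm exactly the weighted average of independently
trained peers, and makes results invariant to peer-list order. And merge
weights are normalized to sum to one before combining (multiplying by 1.0 is
exact in floating point, `x * n / n` is not), so merging a single model is a
bitwise identity.

# Experiment grid and evaluation

With four studies, each choice of held-out test study combines with every
subset of the remaining studies: 12 `Local_1`, 12 `Local_2` and 4 `Local_3`
experiments (28 in total), plus 4 `Swarm_3` runs. Per-design seeds are
derived by hashing the global seed with the design, so adding designs never
perturbs existing ones; grids are resumable from per-design result files.
Test cells whose true label never occurs in the training data are excluded
from metrics and reported as reduced coverage.

Evaluation uses per-class precision/recall/F1 with zeros substituted on
zero denominators (so never-predicted rare classes drag the weighted F1 down
instead of silently vanishing), the support-weighted, macro (over classes
with nonzero test support) and micro F1 (equal to accuracy for single-label
classification), and row-normalized confusion matrices.

**Rarity.** The rarity of a class is quantified as the mean over studies of
`1 - prevalence`: it is monotone increasing in rarity, which is the stated
direction of the index used in this literature ("higher values are rarer").
The binary Gini impurity `2p(1-p)` is *not* monotone in rarity — it peaks at
`p = 0.5` — so it is offered only as a comparison flavor
(`flavor = "gini_binary"`), and the package asserts the direction of the
F1-vs-rarity relationship (negative slope) under its own monotone index.
The regression is ordinary least squares of per-class mean F1 on rarity,
treating the per-(class, test study) means as independent observations; the
slope p-value is the two-sided t-test with `n - 2` degrees of freedom.

**Between-setting comparisons** use the two-sided Mann-Whitney U test: exact
enumeration for small tie-free samples (`n_a + n_b <= 12`), the
tie-corrected normal approximation otherwise.

# The synthetic data generator

The generator produces multi-study collections with the statistical
structure the pipeline assumes:

* counts are negative-binomial with `Var = mu + mu^2 / theta`
  (mean/inverse-dispersion parameterization, `theta = nb_dispersion`) — the
  parameterization is stated because "negative binomial" alone is ambiguous;
* each cell type has a disjoint private marker-gene set up-weighted by
  `exp(marker_log_fold_change)`; subtypes perturb their parent profile on a
  smaller private marker set with half the fold change, mirroring two-level
  annotations;
* per-study, per-gene log-normal batch factors (`batch_sigma`), log-normal
  library sizes, a designated `MT-` gene subset carrying a fixed fraction of
  each cell's expected mass;
* per-study composition differences, including rare types and a type with
  zero prevalence in one study (emulating classes some centers never
  observed);
* a planted fraction of low-quality cells, corrupted either by raising the
  expected mitochondrial mass to 30% or by scaling the library size by
  25-fold up or down — each violating one of the QC rules by a wide margin,
  with ground truth recorded.

Donor structure is not modelled (the experiments split by study, not
donor), and neither are doublets or ambient RNA. The generator makes no
attempt to fit real atlases. Consequently, passing benchmarks demonstrate
that the *pipeline and protocol* behave as specified under controlled,
favorable signal structure; they do not certify performance on real tissue
atlases, where label noise, nested subtypes and uneven quality dominate.

# Benchmark problem sizes

The package's end-to-end benchmark (`swarm_benchmark()`, also driven by
`scripts/acceptance.R`) uses 4 studies of 500 cells, 500 genes, 8 cell types
(two rare, one absent from one study), marker log-fold-change 2, batch sigma
0.2, dispersion 2, 5% planted low-quality cells, top-200 HVGs per study,
20 training epochs, and sync interval 5 — all fixed a priori as the
package's study conditions. Three considerations set the scale: 500-cell
studies keep a full multi-seed grid in the minutes range on one CPU; 20
epochs at 4 batches/epoch gives the same order of optimizer steps per cell
as the reference configuration does at atlas scale; and a sync interval of 5
preserves the qualitative regime of *many merge events per training run*
(at atlas scale, a sync interval of 100 batches means many syncs per epoch;
an interval of 100 at 80 total rounds would degenerate to one-shot
averaging, a different algorithm). Epoch-scale quantities, not these
specific sizes, drive the conclusions; the benchmark exposes all of them as
arguments.

# Known limitations

* The swarm simulation is synchronous and failure-free: no stragglers,
  dropouts, or partial participation (real protocols merge "at least two"
  peers per event).
* Cryptographic aspects of HVG-list sharing (private set union) are out of
  scope; the plain union is computed.
* The two annotation levels are trained as independent tasks; no
  ontology-aware hierarchical classifier.
* The Mann-Whitney comparison on 4-per-setting grids has little power;
  paired gaps are the more informative parity measure at this scale.
* `qc_filter()` is intentionally single-pass; iterating it would remove
  further cells as the MAD margins shrink.
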