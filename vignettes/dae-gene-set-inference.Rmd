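---
title: "Gene-set inference from expression compendia with denoising autoencoder ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-set inference from expression compendia with denoising autoencoder ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daeprobe)
```

## The method

Bacterial expression compendia — hundreds of RNA-seq experiments over
thousands of genes, as logTPM — contain the footprints of coordinated
regulation: operons, regulons and pathways whose members move together
across conditions. `daeprobe` infers such co-regulated gene sets without
supervision by training ensembles of *denoising autoencoders* (DAEs) and
interrogating their bottleneck layer.

A DAE here is a feed-forward network `input -> N1 -> ... -> NB -> ... ->
N1 -> output` written in the compact notation `N1-N2-...-(NB)`, where
`NB` is the bottleneck width. Three structural commitments define the
model family:

* **Tied weights.** Decoder weight matrices are the transposes of the
  encoder's, applied in reverse order; only the decoder's bias vectors
  are free. The tie halves the parameter count and means each weight
  matrix receives gradient from both of its uses.
* **Sigmoid activations** at every layer (bottleneck and output always;
  hidden layers optionally ReLU), with Glorot-uniform initial weights
  (`U(-b, b)`, `b = sqrt(6/(fan_in + fan_out))`) and zero initial biases.
* **Masking noise.** At every training step, a fixed fraction (default
  10%) of each input vector's entries is set to zero; the reconstruction
  target stays clean. Denoising forces the bottleneck to exploit
  between-gene dependence instead of memorising inputs.

Training minimises mean squared reconstruction error with Adam on
experiments split 80/10/10 into train/validation/test, min–max scaled to
[0, 1] within each split, with batch shuffling and early stopping on the
validation loss (best-validation weights are restored).

### Probing the bottleneck

After training, each bottleneck node `j` is probed through the decoder:

```
delta_y_j = decode(e_j) - decode(0)
```

with `e_j` the unit activation of node `j`. `delta_y_j` is the per-gene
change in predicted expression the node encodes — positive entries are
genes the node *activates*, negative ones genes it *suppresses*. Genes
are ranked by `delta_y_j` (ties broken lexicographically by ID) and the
two tails tested for gene-set enrichment.

Because a single network is unstable under re-initialisation, many
networks are trained and their bottleneck nodes pooled. When the
bottleneck width changes, the ensemble is resized to keep the pooled
node count constant (e.g. 5000 nodes as 100×50 or 200×25), so
architectures stay comparable.

### Enrichment and error control

The primary test is hypergeometric: the top `k` (default 50) and bottom
`k` genes of each node's ranking are intersected with every gene set
(capped at 40 in-universe genes, so broad categories are never tested),
p-values are BH-adjusted within the node, and a set is **recovered**
when its adjusted value falls below the threshold. The default threshold
is deliberately severe, `1e-8`: across a full ensemble of 5000 nodes and
~1444 gene sets the expected number of false discoveries is then
`5000 × 1444 × 1e-8 ≈ 0.07 < 1`, so any recovery on permuted data would
be surprising. A preranked GSEA track (weighted Kolmogorov–Smirnov
running sum, weight exponent 1, gene-label permutation null) is
available as a secondary annotation; permutation p-values cannot resolve
`1e-8` at feasible permutation counts, so recovery summaries use the
hypergeometric track only.

### From nodes to conditions

Passing each experiment `x_i` through a network's encoder gives node
activations `z_j(x_i)`. Node responses combine almost additively in
trained networks (the package's linearity score measures the departure
as an L1 norm between the joint two-node response and the sum of the
single-node responses), which licenses the *gene-set response*

```
phi(x_i) = sum_j z_j(x_i) * mean_{g in set}(delta_y_j[g])
```

— the network's predicted average expression change of a gene set under
condition `x_i`. The RMS of all phi values for one experiment summarises
how selectively an architecture explains that condition: 0 means no gene
set responds at all, and fewer responding sets mean a lower RMS.
Condition-specific nodes are those with activation strictly above 0.5
for every experiment of a target group and strictly below 0.5 elsewhere;
averaging their `delta_y` and keeping the top 100 genes yields a *de
novo* gene set for that condition, validated by z-scores against the
whole compendium and by group-wise log fold changes.

## The synthetic benchmark

Real compendia come with no ground truth, so the package ships a
generator that plants known structure. Each gene has a uniform baseline
in a logTPM interval (default 2–8); each of the default 10 modules
(10–20 genes, disjoint) shifts its members by ±`effect_size` (default
1.5 logTPM, 90% of modules activating, 10% repressed) whenever active;
each experiment activates 1–3 modules; Gaussian noise (default sd 0.3)
is added. Two planted features exercise the condition machinery: an
*inverse pair* of modules that are never co-active, and a
*group-specific* module active in every experiment of exactly one
condition group and nowhere else. The group-specific module is always an
induced (activating) one: it models a condition-specific expression
program — genes upregulated during, say, infection — which is the
situation the specificity procedure is designed to detect; a repressed
group marker would make the planted truth ill-posed for a rule that
looks for nodes switching *on* in the target group. A per-gene permutation control
reshuffles every gene row independently, preserving marginal
distributions while destroying co-expression.

The default benchmark used throughout the tests and the acceptance
script is 300 genes × 200 experiments with those defaults, ensembles of
10 networks with architecture `100-(10)` for recovery and specificity,
and 5 networks per arm for architecture comparisons. These sizes were
chosen as the smallest at which recovery statistics are stable; the
generator's defaults are fixed, not tuned per experiment.

What the generator does *not* emulate: count noise and library-size
effects (values are logTPM by construction), hierarchical regulatory
overlap (modules are disjoint by default; 10% overlap is available via
`overlap_fraction`), realistic condition ontologies, and the sheer scale
of a real compendium (thousands of genes, hundreds of heterogeneous
conditions). Passing the benchmark therefore demonstrates that the
machinery — training, probing, enrichment, error control, condition
association — is correct, not that results on any real compendium will
match it.

## Numerical and design choices

* **Training defaults** (`train_config()`): learning rate `3e-3`, batch
  32, up to 1000 epochs, patience 60, per-gene min–max scaling. These
  came from a local search over learning rate and patience using
  validation loss as the metric. Two observations drove them: sigmoid
  networks on compendium-like data pass through a long plateau where
  they reconstruct only per-gene means — patience must outlast it, or
  training stops with an empty bottleneck; and with one global min–max
  per split, genes with high baselines compress into a narrow band of
  the [0, 1] range, which leaves deep sigmoid networks unable to escape
  that plateau at all. Per-gene scaling gives every gene the full unit
  interval and makes all depths trainable; `scaling = "global"` remains
  available.
* **Corruption count** is exact — `round(fraction × n_genes)` entries
  per sample, resampled each step — rather than Bernoulli per entry;
  exactness makes the operation testable to the count.
* **Validation loss** is computed on clean (uncorrupted) inputs, so
  early stopping tracks reconstruction of the data rather than of a
  random mask.
* **The probe baseline** is `decode(0)`: zero is the natural "off" state
  of a sigmoid bottleneck probed at its "on" value 1. Whether decoder
  outputs should be baseline-subtracted before ranking is a judgement
  call; subtraction makes the two tails symmetric.
* **phi sums over all nodes** of a network, not only the set-associated
  ones: that is the only reading that yields one phi per (set, network,
  condition) triple. Restricting to associated nodes is available via
  the enrichment results.
* **Strictness at 0.5** for condition-specific nodes means an untrained
  (zero-weight) network, whose activations are all exactly 0.5, never
  qualifies — degenerate models are excluded by construction.
* **Ties and degenerate inputs:** gene rankings break ties by ID so
  reruns are bit-identical; constant gene rows scale to 0 (guarded
  division); zero-variance genes yield `NA` z-scores, and genes missing
  from a stratum report `NA` log fold changes, never silent zeros.
* **Serialisation** stores all numeric payload (weights, biases, scaling
  records) as little-endian binary doubles, making save/load round trips
  bit-exact; JSON carries only structure and metadata.

## Known limitations

* On the synthetic benchmark the depth advantage reported for real
  compendia does not reproduce: planted modules are disjoint and
  additive, so a shallow network is already a sufficient model, and
  deep and shallow ensembles recover statistically indistinguishable
  per-network counts at full convergence. The depth comparison machinery
  (one-sided rank-sum across fixed seeds) is implemented and exercised,
  but on this data it reports no consistent advantage in either
  direction. Observing the real-data effect requires data with
  hierarchical, overlapping structure that the generator deliberately
  does not fabricate.
* Deep sigmoid networks remain slow to train on small data even with
  per-gene scaling; the mean-reconstruction plateau is a real feature of
  the loss landscape, and configurations with aggressive early stopping
  will underfit silently. Inspect `model$training$val_loss` when in
  doubt.
* GSEA permutation p-values are bounded below by `1/(n_perm + 1)` and
  cannot certify discoveries at the hypergeometric track's `1e-8`
  threshold; the two tracks are complementary, not interchangeable.
* The generator's condition groups are balanced and i.i.d.; real
  compendia have strongly unbalanced, correlated condition structures,
  and specificity calls on such data deserve more caution than the
  benchmark suggests.
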