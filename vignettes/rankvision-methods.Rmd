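---
title: "Multilevel taxonomic image classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel taxonomic image classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankvision)
```

## The problem

Wildlife images come with labels arranged in the biological taxonomy: every
photograph of a species also determines its genus, family, order, class,
phylum and kingdom. A *flat* classifier predicts only the finest label and
must learn, independently, features that thousands of visually similar
species share. A *multilevel* classifier predicts one category per rank, so
coarse, widely shared features (body plan, habitat context) support the
coarse heads while fine heads concentrate on the residual distinctions.
`rankvision` implements this model family, the data balancing and
augmentation regimes usually trained with it, three ensemble schemes, and a
per-rank evaluation protocol, all exercised on a fully synthetic image
generator so that the complete stack is testable on a laptop CPU.

## Model

A backbone $f_\theta$ maps an RGB image $x \in [0,1]^{H \times W \times 3}$
to a feature vector $f_\theta(x) \in \mathbb{R}^d$. For a taxonomy with $L$
ranks of sizes $K_1, \dots, K_L$, the multilevel head attaches $L$ parallel
fully connected layers to the *same* feature vector; head $\ell$ produces
logits $z^{(\ell)} = W_\ell^\top f_\theta(x) + b_\ell \in \mathbb{R}^{K_\ell}$
and class probabilities through the softmax

$$\sigma(z)_i = \frac{e^{z_i}}{\sum_{j=1}^{K} e^{z_j}},$$

computed with max subtraction for numerical stability. The flat variant is
the special case of a single head over the finest rank. The training loss is
the unweighted sum over ranks of the categorical cross-entropy
$-\log p^{(\ell)}_{y_\ell}$; equal weighting is the minimal reading when no
per-rank weights are prescribed, and `trainConfig(levelWeights=)` exposes
the knob. The heads are independent at inference time, so their argmax
labels need not form a tree path; `isConsistentPrediction()` quantifies
cross-rank agreement as a diagnostic.

### Backbone contract and the default trunk

Any feature extractor can stand behind the `Backbone` contract (name, input
resolution, feature dimension, `forward`). The default `tinyBackbone()` is
three 3×3-convolution + ReLU + 2×2 average-pool blocks with fixed,
He-initialised, seeded random filters, summarised by global average *and*
global max pooling of the final maps. Two choices deserve justification:

* **Frozen filters, trainable heads.** With the trunk fixed, training
  reduces to a convex multinomial fit of the softmax heads by Adam. This is
  the standard frozen-trunk transfer regime (replace the top layer of a
  pretrained network, train the replacement), it keeps the full test suite
  in CPU-seconds, and it satisfies every behavioural contract of the
  training loop (loss decreases under a gradient step, early stopping, best
  checkpoint return, determinism under a fixed seed). Full-scale trainable
  backbones plug in behind the same contract.
* **Average + max pooling.** Global averages capture frame-wide attributes
  (background, overall colour); global maxima preserve small localised
  activations. Fine-grained categories that differ only in a small marking
  are exactly the case where pure average pooling loses the signal.

Features are standardised with the training-split mean and standard
deviation (stored in the model) before the heads, which conditions the Adam
fit without affecting the contract.

### Optimiser, loop, early stopping

The optimiser is Adam with $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\varepsilon = 10^{-7}$ and a default learning rate of $10^{-4}$; an
AMSGrad toggle is provided because the published description of the update
rule is ambiguous between the two variants. Data are reshuffled every
epoch. The monitor split is evaluated every `testIntervalEpochs` (default
10) epochs; training halts once `patienceTests` (default 10) consecutive
evaluations fail to beat the best monitored finest-rank top-1 by more than
`minDelta` (default 0 — "significant improvement" is deliberately a knob),
and the best checkpoint is returned. Monitoring the *test* split during
training reproduces the reference protocol, which has no validation split;
this leaks model selection into the test metric, so `monitorSplit` can be
pointed at any split and the ensemble machinery measures its weights on a
held-out carve-out of train by default. The desk-scale experiments in the
test suite use a learning rate of 0.05, full convergence in under 300
epochs on 30–80 images; the defaults remain the reference values.

## Augmentation and balancing

Three regimes, in increasing order of aggressiveness:

* **standard** — a random subset (at least one) of horizontal flip, vertical
  flip, per-channel colour shift (±0.1), brightness (±0.2), contrast
  (×0.8–1.2), additive Gaussian noise (sd 0–0.05) and Gaussian blur
  (σ 0–1.5 px), applied in a fixed canonical order (geometric → photometric
  → noise → blur) with parameters drawn per record. The operator ranges are
  package choices (the regime's source does not state them) and are
  serialised with every run configuration so they are auditable.
* **central_crop** — a centred window of 0.8 of each linear dimension,
  taken *before* resizing, plus the standard operators. The 80% figure is
  read as a side fraction (not an area fraction) for consistency with the
  multiscale range phrasing.
* **multiscale_crop** — three centred crops with side fractions drawn
  uniformly from [0.5, 0.8], each a new record, plus the standard
  operators.

`balanceDataset()` equalises finest-rank training counts to the pre-balance
maximum by adding augmented copies of under-represented classes (crop
records are added first in the crop regimes, and the equalisation runs on
the resulting counts). Copies are *lazy*: each added record stores its
source path, transform name and transform seed, and `loadImage()` replays
the pipeline deterministically, so a balanced manifest of 353 500 records
costs a table, not a directory of images. The test split is never touched.

## Ensembles

* **Boosting** (accuracy-weighted voting): each member's per-rank
  probability vector is scaled by its measured top-1 accuracy
  ($\hat d_x = \sum_i y_i \cdot w_i$), summed and renormalised. Weights are
  taken per rank by default (each rank's combination uses that rank's
  accuracy); a single global weight per member is a switch, since the
  source phrasing is ambiguous. Ties break towards the lowest category id,
  everywhere.
* **Stacking**: a single fully connected layer with one softmax group per
  rank, fitted on the concatenated per-rank *log*-probabilities of all
  members. Log-probability inputs make the identity initialisation
  reproduce a single member exactly, which pins the meta-model's semantics
  and gives the fit a sensible starting point. The meta-layer is trained on
  a held-out stratified carve-out of the training split (10% by default),
  never on member-training data, to avoid leakage.
* **Cascade**: a router predicts the routing rank (Phylum in the reference
  taxonomy: 4 categories); one specialist per routing category, trained
  only on that category's records with label spaces reindexed to its
  subtree, predicts all finer ranks. Finer-rank probability mass outside
  the routed subtree is exactly zero; ranks coarser than the routing rank
  are derived from the taxonomy (in a tree they are determined by the
  routed category), so routing errors propagate exactly — with perfect
  specialists, finest-rank accuracy equals routing accuracy.

## Evaluation

Per rank: top-1 and top-5 accuracy (ties inside the top-k boundary resolve
towards the lowest id; `k` is capped at the rank size). At the finest rank:
one-vs-rest precision/recall/F1 per class with the support-weighted mean F1
(zero-support classes excluded), macro one-vs-rest ROC AUC over classes
with at least one positive and one negative (computed by the rank-sum
statistic, ties counted half), and a normal fit $(\mu, \sigma)$ to the
per-class F1 distribution with the *empirical* fractions of classes within
$\mu \pm \sigma$ and $\mu \pm 2\sigma$. The fit uses the population
standard deviation (divide by $n$) as its descriptive convention, with the
sample convention behind a flag. Reported coverages are empirical because
a published coverage pair for such a fit (65.2%/95.4%) is internally
inconsistent with a normal distribution's 68.3%/95.4%.

## The synthetic generator

`syntheticSpec()` + `generateDataset()` produce a procedural benchmark in
which the visual signal is *rank-nested by construction*: the coarsest rank
sets the background hue (most pixels), intermediate ranks set the subject
silhouette, fill texture and stroke from fixed alphabets indexed by
category id, and the finest rank controls only a small central marking on
the subject. Categories under one parent therefore share all coarse
attributes — the property that makes multilevel classification sensible.
Degradations emulate field imagery: subject scale drawn from
`subjectScaleRange` (default 0.3–0.95 of the frame, covering
"fills the frame" to "small patch"), random position, low-contrast
background clutter rectangles, additive Gaussian noise (default sd 0.05)
and occasional blur (default probability 0.25). All randomness flows
through one seed with counter-based per-sample splitting, so generation
order never changes content and two runs are byte-identical.

What the generator does *not* emulate: photographic texture statistics,
within-class pose/age/sex variation, occlusion, or label noise. Passing
tests on this benchmark demonstrate that the machinery is correct (the
optimisation reaches the separable optimum, rank-nested signal is
exploited, ensembles compose as specified) — not that any particular
backbone would reach a particular accuracy on real wildlife photographs.

### Problem sizes and fixture choices in the test suite

The suite's core fixtures are deliberate:

* *Trainability fixture*: 2 ranks (branching 2×2), 40 noiseless images,
  subjects filling the frame. Full-frame subjects keep class-coding pixels
  aligned, which makes a raw-pixel nearest-centroid classifier exact (the
  separability oracle the trainability claim rests on); the trained model
  reaches 1.0 top-1 at both ranks there.
* *Noise ordering*: because coarse attributes occupy more pixels by
  construction, heavy noise degrades finest-rank separability first; the
  suite checks coarse ≥ fine accuracy across checkpoints over three seeds
  (tolerance 0.02).
* *Augmentation direction*: measuring whether standard augmentation helps
  requires a baseline below the ceiling, so that experiment uses strong
  noise (sd 0.25), blur (p 0.3), subjects at 35–85% of the frame and rare
  classes of 5–6 samples; the mean finest-rank gain over three seeds is
  asserted positive. On a saturated baseline the question is unanswerable,
  which is a measurement constraint, not a result.

## Numerical choices and degenerate inputs

* Softmax uses max subtraction; cross-entropy clamps probabilities at
  $10^{-12}$.
* Bilinear resize is corner-aligned (output corners reproduce input
  corners); non-square images resize anisotropically to the square input.
* Central-crop offsets follow $\lfloor (1-f) \cdot \text{side} / 2 \rfloor$
  with a $10^{-9}$ guard against floating-point representation of $1-f$.
* Category ids are dense, 0-based, assigned per rank in C-collation
  lexicographic order of display names — rebuilding a taxonomy from the
  same labels always yields the same ids, with no external id files.
* Argmax and top-k ties break towards the lowest category id,
  deterministically, in every component.
* Degenerate cases are errors, not warnings: empty logits, crop windows of
  zero size, truth ids out of range, empty splits, a routing category with
  no training records (named in the message), AUC at a single-class rank.

## Limitations

* The shipped backbone is not trainable end-to-end; claims about full-scale
  architectures (ResNet, EfficientNet, …) require plugging them in behind
  the `Backbone` contract with an external deep-learning runtime.
* The taxonomy model is a strict tree: one parent per category, full paths,
  no DAGs, no partial rank annotations.
* The annotation reader targets the 2019 competition JSON dialect only.
* Balanced manifests replay augmentations lazily; pipelines that need
  materialised augmented images must write them out themselves.
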