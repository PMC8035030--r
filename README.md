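# rankvision

Multilevel taxonomic image classification in R: one softmax head per
biological rank (Kingdom → Species) on top of a shared convolutional
feature extractor, with the data-balancing/augmentation regimes, ensemble
schemes and per-rank evaluation protocol that go with it.

## What it is for

Wildlife image collections (e.g. the iNaturalist competition datasets) label
every image with its full taxonomic path. Instead of a flat classifier over
the 1010 species of the 2019 competition, a *multilevel* classifier predicts
one category per rank — for the 2019 taxonomy, seven parallel heads of
widths 3/4/9/34/57/72/1010 fed by the same backbone features. Per-rank
probabilities come from the softmax

    σ(z)_i = exp(z_i) / Σ_j exp(z_j)

and the training loss is the sum over ranks of the categorical
cross-entropy, optimised by Adam (lr 1e-4 by default) with an evaluation
every 10 epochs and early stopping after 10 non-improving evaluations.

The package provides, behind S4 classes with accessors:

* **taxonomy** — build/validate/query the rank hierarchy (`buildTaxonomy`,
  `ancestorPath`, `isConsistentPrediction`, JSON serialisation);
* **dataio** — the iNaturalist-competition annotation dialect
  (`readINatAnnotations`), CSV manifests, corner-aligned bilinear image
  loading;
* **synthdata** — a procedural hierarchical image generator whose visual
  signal is rank-nested by construction (`syntheticSpec`,
  `generateDataset`), so everything is testable without downloads;
* **augment** — standard / central-crop / multiscale-crop regimes and class
  balancing to the most represented category (`augmentPolicy`,
  `balanceDataset`);
* **model** — backbone contract, flat or multilevel heads, Adam training
  loop, early stopping (`buildClassifier`, `trainModel`, `earlyStopper`);
* **ensemble** — accuracy-weighted boosting (`boostCombine`), a stacked
  fully connected meta-classifier (`fitStacking`), and a Phylum-routed
  cascade of specialists (`buildCascade`, `cascadePredict`);
* **evaluate** — per-rank top-k, per-class F1 and weighted F1, macro
  one-vs-rest AUC, and a normal fit to the per-class F1 distribution
  (`evaluateModel`, `fitF1Normal`);
* **run/CLI** — YAML-configured end-to-end runs (`runSynth`, `runTrain`,
  `runEval`, `runEnsemble`) and a thin command-line dispatcher in
  `inst/scripts/rankvision`.

## Worked example

Generate a small synthetic dataset (2 coarse categories × 3 leaves each),
train the two-head classifier, evaluate per rank:

```r
library(rankvision)

runSynth(resolveRunConfig(branching = c(2L, 3L), samplesPerLeaf = 12L,
                          imageSize = 32L, noiseSigma = 0.05, blurProb = 0.2,
                          outputDir = "demo_ds", seed = 42L))
#> synth: 2 levels (2/6), 6 leaves, 72 images (60 train / 12 test) -> demo_ds

runTrain(resolveRunConfig(dataset = "demo_ds", resolution = 32L,
                          learningRate = 0.05, maxEpochs = 200L,
                          batchSize = 16L, outputDir = "demo_run", seed = 42L))
#> train: 2 head(s) (2/6), 11 evaluations, best test top-1 0.750

rep <- runEval(resolveRunConfig(dataset = "demo_ds",
                                checkpoint = "demo_run/checkpoint.rds",
                                outputDir = "demo_eval", seed = 42L))
#> eval: 12 samples, finest top-1 0.750
rep
#> EvalReport
#>   level top1 top5         loss
#>  level0 1.00    1 4.141296e-05
#>  level1 0.75    1 7.027980e-01
#> weighted F1: 0.7389  macro AUC: 0.95
```

Reading the output: the coarse rank (background-level signal, most pixels)
is solved perfectly, while the finest rank — distinguished only by a small
subject marking under noise and blur — reaches 0.75 top-1; its true class
is always within the top 5. This coarse ≥ fine ordering is a structural
property of rank-nested signal, and the per-rank report is exactly what the
multilevel head layout buys over a flat classifier.

The `vignettes/rankvision-methods.Rmd` vignette documents the model, the
augmentation operators and their ranges, the ensemble semantics, and what
the synthetic benchmark does and does not emulate.

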