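---
title: "Methods: label-free sperm morphology analysis for imaging flow cytometry"
author: "ifcmorph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free sperm morphology analysis for imaging flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Morphological assessment of bull spermatozoa is a core fertility indicator,
but routine practice is manual: stained smears under light microscopy, a few
hundred cells per ejaculate, subjective category calls. Imaging flow
cytometry (IFC) instead captures a brightfield image of every cell passing
the flow cell — tens of thousands of label-free single-cell frames per
sample — which makes automated, objective morphology classification
feasible, with convolutional networks as the natural classifier family.

`ifcmorph` implements this analysis end to end as a reusable, tested
pipeline: a synthetic single-cell image generator with the acquisition
hierarchy and domain structure the statistics assume; quality control and
image standardization; stratified labeling, splitting and class-balanced
sampling; linear-probe (LP) and linear-probe-plus-fine-tuning (LP-FT)
training of a compact CPU-scale CNN; and the evaluation machinery —
leave-one-breed-out (LOBO) folds, labeled-data-fraction learning curves,
cross-condition/cross-breed generalization matrices with percentage-point
gap arithmetic, and hierarchical cluster bootstrap confidence intervals.

## Class taxonomy and label precedence

Every frame receives exactly one of ten categories: eight biological
morphology classes — normal (NM), irregular head shape (IHS), twisted or
elongated head (TEH), abnormal midpiece (AM), abnormal tail (AT), proximal
and distal cytoplasmic droplet (PCD, DCD), coiled tail and midpiece (CTM) —
plus two residual dataset-hygiene categories: MULTI (more than one cell in
frame) and DEBRIS. Cells frequently carry several co-existing
abnormalities, so `assign_label()` reduces a defect set to one label through
a fixed total priority order:

```
DEBRIS > MULTI > CTM > AT > TEH > IHS > AM > PCD > DCD > NM
```

Annotation practice fixes two of these comparisons explicitly (coiling
supersedes a plain abnormal tail; a twisted/elongated head supersedes other
head irregularities); the remaining order is a package design choice, chosen
once so that labelling is deterministic and auditable for any defect
combination. Head defects outrank droplets on the grounds that head
anomalies are the more consequential finding; swapping those ranks would
only relabel genuinely ambiguous multi-defect cells.

MULTI and DEBRIS participate in training and in the 10-way confusion
matrix, but are excluded from biological morphology profiles
(`profile_predictions()` tallies them separately as `n_excluded`).

## The synthetic data generator

Real IFC campaigns of this kind are not publicly deposited, so the package
ships a generator that emulates the *statistical structure* the analysis
depends on, at desk scale:

* **Acquisition hierarchy.** `hierarchy_spec()` defaults to 6 bulls
  (4 Kazakh Whitehead, 1 Simmental, 1 Auliekol), two fresh ejaculates
  (spring, fall) and one frozen ejaculate (summer) per bull, two recorded
  files per sample and 50,000 events per file — 1.8 million events in
  total. Bull- and ejaculate-level lognormal random effects (SD 0.05 and
  0.03 on the log scale) perturb the morphometry means, so images within a
  bull are dependent; this is the dependence the hierarchical bootstrap is
  designed to respect, and it is what the intra-bull-correlation tests
  check.
* **Cell rendering.** Each frame is a 96×96 8-bit grayscale image: head as
  a filled rotated ellipse with edge darkening, midpiece as a thick
  segment, tail as a quadratic spline (a spiral for CTM), droplets as
  near-saturated discs with a dark rim, debris as 1–4 irregular blobs,
  multiplets as two overlapping cells, over a bright background with
  additive Gaussian noise. Cells are oriented along the flow axis
  (Gaussian wobble, SD 12°, either end leading), as cells in a flow cell
  are; this matters, because it is what makes the classes linearly
  separable at the image scale the compact backbone uses.
* **Class mixture.** The default per-sample mixture is a realistic
  post-gating composition (45% NM, head/tail/droplet defects 5–10% each,
  4% each MULTI/DEBRIS). Labeling campaigns then use `quota_sample()`
  exactly because raw mixtures are imbalanced.
* **Domain shifts.** Breeds shift morphometry by ±10% (SIM larger, AUL
  smaller). The frozen condition images noisier (noise ×1.5) and at lower
  contrast (×0.85), and — because cryodamage alters the cells themselves,
  most visibly as more strongly bent and coiled tails — it also shifts
  morphometry: tail curvature ×1.4 and head dimensions ×0.95 across
  classes. The morphometry component is essential: noise and contrast
  alone mostly change how *hard* a test set is, which can make a
  noise-trained model look better on cleaner foreign data; shifting the
  class-conditional geometry is what produces the symmetric in-domain >
  cross-domain ordering that real fresh/frozen preparations show.
* **Determinism.** One root seed; every image draws from a stream derived
  by a stable counter scheme (`seed_stream()`), so manifests and images are
  byte-identical across runs and robust to chunking.

What the generator does *not* emulate: instrument optics and focus
variation, real chromatin/acrosome texture, staining, motility, or the
IDEAS gating feature set. Passing tests on synthetic data therefore
demonstrate that the pipeline's statistics and orderings are implemented
correctly and recoverable under the assumed structure — not that any
particular accuracy level transfers to real instrument data.

## Preprocessing

* `center_crop_square()` crops to the shorter edge, centred, floor-based
  offsets for odd margins.
* `qc_filter()` discards rows whose shorter edge is strictly below 50 px
  (the default; an image at exactly 50 px is kept). Frames below this
  scale are mostly debris without usable morphological cues.
* `to_model_input()` resizes to 224×224 (bilinear), replicates the gray
  channel to three identical channels, divides by 255 and standardizes
  with fixed constants (mean 0.5, SD 0.25). The constants are fixed rather
  than per-image so that domain contrast differences remain visible to the
  model, and so train and test time transforms are identical.
* `augment()` (training split only) applies, in fixed order: horizontal
  flip (p = 0.5), rotation uniform on ±10° with bilinear resampling and
  out-of-frame pixels filled with the border-median background (black
  corners are alien to brightfield), then a random resized crop retaining
  80–100% of area with up to ±10% centre translation. All draws come from
  the policy's stated ranges and a per-image derived seed.

## Sampling

* `quota_sample()` draws exactly N (default 200) rows per
  class × breed × condition stratum; a shortfall is an error by default,
  because silently under-filled strata would bias class balance.
* `stratified_split()` fixes train/val/test = 80/10/10 per stratum with
  largest-remainder rounding (deterministic, sums exactly).
* `lobo_folds()` holds out each breed once; the remainder is split 80/20
  into train/validation, stratified by class.
* `fraction_subsets()` returns nested class-stratified subsets at
  f ∈ {0.1, 0.2, 0.5, 1}. Nesting is a deliberate choice: learning-curve
  differences then reflect data volume only, not resampling noise.
* `balanced_batches()` draws classes uniformly and images within class
  with replacement (minority oversampling), after applying optional
  per-class/per-breed/per-bull caps to the epoch pool. Cap values are
  deliberately required configuration — there is no hidden default other
  than uncapped.

## Training

The built-in backbone (`compact-cnn`) is a CPU-scale network: a fixed,
parameter-free stem (channel mean, then 7×7 average pooling: 224×224×3 →
32×32) followed by four convolution blocks (5×5 stride 1 then three 3×3
stride 2; 8/16/32/64 channels; ReLU) and a linear head on the flattened
4×4×64 feature map. Convolutions are im2col gathers plus dense matrix
products, with an exact sparse-matrix backward pass (verified against
numerical gradients in the test suite).

* **LP (linear probing).** The convolutional stack is frozen — for this
  backbone, frozen at its seed-fixed random initialization, the package's
  stand-in for a pretrained feature extractor — and only the head is
  trained. Head optimization runs on per-feature standardized activations
  (train-split mean/SD), and the affine reparameterization is folded back
  into the head weights at checkpoint time, so the stored model is a plain
  linear head on raw features. Without centring, the shared positive mean
  of ReLU features dominates the gradient and convergence is an order of
  magnitude slower. The head starts at zero (symmetric start; ties broken
  by the first gradient step).
* **LP-FT.** Fine-tuning continues from the probe checkpoint with all
  parameters trainable at the reduced rate `lr_ft` (a warning is issued if
  it is not reduced). The incoming checkpoint is the initial best
  candidate, so LP-FT validation accuracy never ends below the probe's.
* **Optimization.** AdamW (decoupled weight decay 1e-4), cross-entropy,
  batch size 64, learning rates 1e-3 (LP) and 1e-4 (FT), epoch budgets 30
  + 30 by default, early stopping with patience 5 on validation accuracy,
  best checkpoint = highest validation accuracy with ties to the earliest
  epoch. Everything is seed-deterministic on CPU; predictions are
  batch-size invariant.
* **Named ImageNet backbones** (MobileNetV3-Large, EfficientNetV2-S,
  ResNet-50, ConvNeXt-Tiny) are configuration hooks only: they require
  externally obtained pretrained weights and GPU-scale budgets, and no
  package workflow depends on them.

## Evaluation statistics

* `confusion()` counts true × predicted over the fixed class order;
  `metrics()` derives accuracy, per-class precision/recall, F1 =
  2PR/(P+R) (0 when P+R = 0) and macro-F1 as the unweighted mean over the
  evaluated class list. On class-balanced test sets with uniform per-class
  behaviour macro-F1 tracks accuracy closely (asserted within 2 pp in the
  tests).
* `hier_bootstrap()` is a percentile cluster bootstrap respecting
  bulls → ejaculates → images: bulls with replacement (as many as
  observed), then ejaculates within each drawn bull, then images within
  each drawn ejaculate; B = 5,000 by default, 95% percentile interval.
  Percentile (not BCa) and observed-count resampling are the standard
  cluster-bootstrap choices. With one bull and one ejaculate it reduces
  exactly to a flat image bootstrap. On clustered simulations (6 bulls,
  between-bull SD 0.05) its empirical coverage is near nominal while the
  flat bootstrap's collapses — the package's justification for the extra
  machinery.
* `significant_difference()` bootstraps an accuracy difference (shared
  cluster/image indices in paired mode; independent resampling otherwise)
  and declares significance when the CI excludes 0.
* `generalization_run()` trains one model per domain on stratified 80/10/10
  splits with the per-class training budget equalized across domains
  (each class truncated to the smallest per-class count), then fills every
  train × test cell; `gap()` returns signed percentage-point differences
  between test domains for a fixed training domain. CIs pool the
  per-image records across seeds.
* `learning_curve()` runs LOBO × fraction × seed; the summary takes the
  mean over seeds within fold and mean/SD across folds.

## Numerical and reproducibility choices

* All stochastic operations take explicit seeds; per-item streams derive
  from a root seed via a fixed linear-congruential counter scheme, keeping
  results independent of generation order.
* Quantiles use `stats::quantile()` defaults (type 7).
* Split rounding uses largest remainder; checkpoint ties break to the
  earliest epoch; `max.col` ties break to the first class in the fixed
  class order.
* Degenerate inputs error early and loudly: empty images, empty record
  sets, unknown class codes or defect tags, strata too small to split,
  single-group LOBO, B < 1.

## Problem sizes used by the shipped experiments

The test-suite and acceptance-script experiments use desk-scale versions
of the study design, chosen as the smallest sizes at which the orderings
of interest are stable: a 2,000-image class-balanced benchmark
(200/class, one breed, fresh) for the LP vs LP-FT comparison at equal
epoch budget (24 vs 12+12, three seeds); an 1,800-image three-breed pool
(60/class/breed) for the LOBO fraction sweep; 2 × 1,000 images
(100/class/condition) for the cross-condition generalization matrix; and
500 replicates × B = 1,000 for the bootstrap coverage simulation. The
acquisition-arithmetic checks run at the full 1.8-million-event scale at
metadata level (no rendering).

## Known limitations

* The compact backbone's frozen features are random projections, not
  pretrained representations; LP accuracy is therefore far below what
  ImageNet-pretrained backbones reach on real data, and the LP→LP-FT gain
  is modest at desk scale. Only orderings, not absolute accuracies, are
  meaningful on synthetic data.
* Generator morphometry is a parametric stand-in; head/tail dimensions are
  plausible pixel values at 40× rather than calibrated measurements.
* Augmentation is implemented and tested but disabled in the shipped
  experiment runners' featurization by default (`policy = NULL`): with the
  stem's aggressive downsampling, warp-resample augmentation costs more
  than it helps at these problem sizes.
* The hierarchical bootstrap treats seed-to-seed training variation as
  fixed; seeds can be added as an extra stratum by the caller but the
  shipped runners pool per-image records across seeds.
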