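---
title: "Tile-based tumor localization in Mohs frozen sections: models and methods"
author: "mohsmap"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Tile-based tumor localization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Mohs micrographic surgery removes nonmelanoma skin cancer in stages, with
the entire excision margin examined intraoperatively on H&E-stained frozen
sections. `mohsmap` implements a tile-based deep-learning pipeline that
localizes tumor regions in single microscope field-of-view (FMV) captures
of such sections: the image is decomposed into square tiles, a tile
classifier estimates the probability that each tile contains tumor, and
overlapping sliding-window predictions are assembled into a probability
(saliency) map whose quality is scored against expert segmentation masks.

Because clinical FMV images cannot be redistributed, the package ships a
synthetic frozen-section generator with exactly known tumor masks; every
stage of the pipeline is exercised and tested against it.

# Tiling and the labeling rule

Images are decomposed on a 0-based, row-major grid of square
`tileSize` x `tileSize` windows (default 224 px, the classifier's input
size). Windows are half-open pixel blocks. When the stride does not divide
the image, one extra origin per axis is snapped to `dim - tileSize`, so
border content is tiled exactly once more (overlapping its neighbor) rather
than discarded — margins are the point of margin surgery, so dropping them
would be the wrong default.

A tile is labeled **positive** when tumor occupies at least 10 percent of
its area (inclusive boundary), otherwise **control**
(`labelTile()`, threshold 0.10). Fully supervised training sets
(`buildTrainingSet()`) tile every annotated target-class image and add all
tiles of other-diagnosis and normal images as extra controls; training uses
disjoint tiles (stride = tile size) while inference overlaps.

# The tile classifier

The architecture contract is a convolutional feature extractor topped by
exactly three dense layers and a final softmax, trained with categorical
cross-entropy. Production backbones (EfficientNet-B0 / MobileNetV2 scale)
are pluggable through externally supplied weights; they are never
downloaded. The bundled `"small"` backbone is a from-scratch extractor
designed to train on one CPU in seconds:

* a 4x mean-pooling stem, then three blocks of 3x3 convolution + ReLU +
  2x2 mean pooling (channels 3 → 8 → 16 → 32);
* convolution filters are drawn once from a seeded Gaussian and
  orthogonalized per block (QR), then kept **fixed**; only the dense head is
  trained. Fixed random convolutional features are a long-standing
  lightweight approach for texture discrimination, and keeping them fixed
  makes training exactly reproducible. This is a deliberate departure from
  full fine-tuning, which would require a backpropagation engine through
  the convolutions for no benefit at this scale;
* per-channel spatial pooling of the final response map collects the mean,
  standard deviation, maximum and upper-quartile mean — the order
  statistics respond to a small tumor focus inside a mostly benign tile,
  which plain averaging dilutes — and the same statistics of the
  stem-pooled color channels are appended, so the stain-density signal does
  not depend on the random filter draw.

The head (default widths 256-64-16, then a softmax layer) is trained by
Adam (batch 32, learning rate 1e-3, decoupled weight decay 1e-3) on
categorical cross-entropy. The training-protocol constraints are enforced:
augmentation (dihedral flips/rotations plus bounded brightness jitter, four
variants per tile), early stopping on validation loss with best-weight
restoration, and a hard 200-epoch cap. The internal validation split is
grouped by patient and stratified by whether a patient contributes positive
tiles; when all positives come from a single patient a grouped split cannot
place positives on both sides and a stratified tile split is used instead.

Two training-stability choices deserve explanation:

* **Burn-in for early stopping** (`earlyStoppingBurnIn`, default 10):
  best-checkpoint tracking starts only after the burn-in. On small tile
  sets the epoch-1 validation loss occasionally undercuts everything that
  follows purely through initialization transients; restoring it would
  return an untrained model. The "restored checkpoint reproduces the
  minimum recorded validation loss" contract therefore holds relative to
  the post-burn-in window.
* **Orientation-averaged inference**: `predictTiles()` averages the softmax
  outputs over the eight dihedral views of each tile. The fixed filters are
  not rotation invariant, and single-view predictions carry orientation
  noise that dominated map quality; the deterministic eight-view ensemble
  removes it without any stochastic test-time augmentation.

# Weakly supervised training

`trainWsl()` implements the two-stage procedure. Stage 1 trains on tiles
labeled with the image-level diagnosis only: every tile of a target-class
image is positive, every control-image tile is control, masks are never
consulted. Stage 2 keeps a positive tile iff its stage-1 target-class
probability is at least the filtering threshold `t` (default 0.5,
inclusive), keeps all control tiles unconditionally, and retrains a freshly
initialized classifier on the survivors. Re-initialization (rather than
continuing stage-1 weights) avoids confirmation bias; exactly one filtering
round is performed.

Stage 1's positive class carries the weak-supervision noise — in a typical
synthetic cohort roughly half of the weak positives contain no tumor — so
its default schedule is gentler (learning rate 3e-4, stronger weight decay,
early-stopping patience 30). With the default schedule the noisy validation
loss is overfit within a few epochs and filtering degenerates.

# Saliency maps

`slidingWindowProbabilityMap()` classifies every window of the edge-snapped
grid and assembles cell values on a prediction grid whose cells are
`stride` x `stride` blocks anchored at the origin (the last row/column may
be truncated at the border). A window's probability is credited to every
cell it fully covers; overlapping contributions are combined by the
arithmetic mean (max available via `aggregation`). The default inference
stride is half the tile (112 px): overlap is what grades the map near tumor
contours. With stride = tile size the map reduces exactly to the per-tile
probabilities arranged on the grid.

Cross-magnification inference resizes by the magnification ratio (40x to
100x is exactly 2.5). Images are resampled bilinearly via EBImage — EBImage
offers bilinear and nearest-neighbour kernels, and bilinear is adequate for
the smooth upsampling involved — masks by nearest neighbour to preserve
binarity. `renderOverlay()` produces pixel-level heat-map overlays for
visual QC only; no metric consumes them.

# Evaluation

Metrics are computed at grid level: the ground-truth mask is reshaped to
the prediction grid (`reshapeMaskToGrid()`, each cell labeled tumor when
its pixel fraction reaches the majority threshold 0.5), cells are flattened
to score/label sequences, and four metrics are computed. A pixel-level mode
(map upsampled to pixels, raw mask) is available but off by default; both
conventions are defensible readings of mask-to-map reshaping, and the grid
mode matches the prediction geometry.

* **Average precision (AUPRC)** uses the step-wise, non-interpolated
  definition over all prediction thresholds; tied scores collapse to one
  operating point. It errs (rather than returning 0) without positives.
* **AUROC** is the rank statistic — the probability that a random positive
  cell outscores a random negative one, ties counted one half.
* **Highest Dice** maximizes 2TP / (2TP + FP + FN) over a threshold grid of
  all distinct map values plus 0 and 1 (exact maximum; a 101-point grid is
  the fallback for very large inputs), reporting the smallest maximizing
  threshold.
* **Folds enrichment of precision (FEP)** is AUPRC divided by the positive
  cell fraction — the precision gain over a random locator; the identity
  FEP x positive fraction = AUPRC holds to numerical precision by
  construction.

An image is **eligible** for cross-validated summaries when at least 10
percent of its grid cells are non-tumor (inclusive) and at least one cell
is tumor; the second clause is needed because every ranking metric here is
undefined on all-negative images, so it is made explicit.

# Validation statistics

* **Patient-level LOOCV** (`patientLoocvFolds()`): one fold per patient
  with at least one annotated, metric-eligible image; the test fold holds
  all of that patient's eligible images, the training set every other
  annotated patient. Folds are deterministic (sorted by patient id).
* **Bootstrap CIs** (`bootstrapCi()`): ordinary bootstrap, default 10,000
  iterations, percentile interval (BCa via `method = "bca"`); the default
  summarized statistic is the across-image median, resampling images, which
  matches per-image metric reporting. Patient-level resampling can be had
  by aggregating per patient before calling.
* **Paired Wilcoxon** (`pairedWilcoxon()`): signed-rank on per-image
  differences, zeros dropped, ties mid-ranked, exact null for untied
  n <= 50. The large-sample branch uses the continuity-corrected normal
  approximation *plus an Edgeworth fourth-cumulant term* computed from the
  mid-ranks (which also subsumes the tie correction): the plain normal
  approximation deviates from the exact null by up to ~0.017 in mid-range
  p-values around n = 10, the corrected one by ~0.0015. Significance is
  declared at the study's type I error rate of 0.01, two-sided.
* **Fleiss' kappa** (`fleissKappaMasks()`): each rater's mask is tiled into
  50 x 50 px blocks (edge-snapped), binarized at >= 5 percent tumor
  (inclusive), and kappa is computed over items = tiles, categories =
  tumor / non-tumor. Multiple images pool their tiles into one item list by
  default (`mode = "perImage"` averages per-image kappas instead); pooling
  is the reading consistent with a single agreement coefficient over a
  fixed image set.

# The synthetic generator

`generateSpecimen()` emulates the statistical structure of H&E frozen
section FMVs, not their appearance: the background is an eosin-pink base
with smoothed colored noise (stroma); tumor texture is a field of dark
elliptical nuclei whose density and color contrast scale linearly with a
`separability` parameter in [0, 1] — at 0 the tumor region's texture is
drawn from the background process itself, at 1 the textures are maximally
distinct. Tumor geometry is analytic: random ellipses, with a mask pixel
positive iff its center lies inside a planted ellipse, so the mask and the
rendered texture coincide exactly and no anti-aliased half-pixels blur the
ground truth. Control images come in four kinds: other-class tumor texture,
follicle-like rings, inflammation speckle, and plain background — the
distractors a practitioner actually confuses with tumor. Every image draws
its randomness from a counter-based substream of one cohort seed, so
per-image content is order-independent and byte-reproducible.

Default geometry: one tumor ellipse with semi-axes uniform in 120-160 px in
a 448 x 448 image (about 25-35 percent tumor area). Two considerations fix
this choice. First, in clinical FMV material the tumor typically forms one
large contiguous focus occupying a substantial share of the field —
folds-enrichment values in the 2-4 range at near-perfect precision
correspond to tumor burdens of roughly 25-40 percent — rather than
scattered flecks. Second, an oracle analysis (scoring grid cells from
the *true* window tumor fractions through a calibrated response curve,
i.e. no trained model) shows that at the 224/112 inference geometry,
recovery of the cell labels is only well-posed when the tumor region's
diameter is about two windows: much larger regions leave border cells with
no tumor-free covering window to distinguish them, and much smaller ones
leave no interior cells at all. The default therefore sits where the
localization task is informative — the point of a synthetic benchmark is
that a correct pipeline can demonstrably solve it.

The reference study conditions used by `runDemo()` and the acceptance
script are 12 patients x 4 images at 448 x 448 px ("100x" tag),
separability 0.9, patient diagnosis mix BCC 0.68 / SCC 0.12 / actinic
keratosis 0.10 / normal 0.10 (tumor patients in an 85:15 BCC:SCC ratio,
plus a control share that supplies the extra-control images), and 30
percent of patients held out as the validation split. These sizes are the
package's chosen reference scale: large enough that the validation split
contains several annotated patients, small enough to run in about a minute.

What the generator does **not** emulate: staining variation, air bubbles
and freezing artifacts, tissue folds, real chromatin texture, or the
long-tailed morphology of real tumors. Passing the packaged experiments
demonstrates that the pipeline's mechanics — tiling, labeling, training,
filtering, map assembly, scoring, cross-validation — are correct and
self-consistent; it says nothing about clinical performance on real frozen
sections, which calls for ImageNet-scale backbones and clinical training
data.

# Numerical and degenerate-input conventions

* Thresholds stated as "at least" are inclusive everywhere (tile label
  0.10, WSL t, mask cell 0.5, eligibility 0.10, kappa 0.05).
* `averagePrecision()`, `bestDice()` and AUROC error on single-class input
  rather than fabricating a value; `selectConfidentTiles()` signals an
  empty surviving positive set; `pairedWilcoxon()` signals all-zero
  differences; `fleissKappaMasks()` signals a single-category table.
* Bootstrap on constant data collapses to a point interval.
* All stochastic routines take explicit seeds and restore the caller's RNG
  state; identical seeds give byte-identical outputs.

# Known limitations

* The bundled backbone is a texture classifier, not a morphology model; it
  is the test vehicle for the pipeline, while production use is expected to
  plug in externally trained feature extractors.
* Grid-level evaluation quantizes localization to stride-sized cells;
  sub-cell boundary accuracy is invisible to the metrics by design (the
  mask is deliberately reshaped to the prediction boundaries).
* The two-stage weak supervision assumes control images are reliably
  tumor-free; label noise on the control side is not modeled.
* `runLoocv()` retrains one model per fold and is intended for small
  cohorts; large-scale cross-validation should parallelize externally.
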