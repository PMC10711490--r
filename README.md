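# mohsmap

Tile-based localization of nonmelanoma skin cancer in microscope
field-of-view (FMV) images of Mohs frozen sections.

Mohs micrographic surgery excises skin cancer in stages, examining the
entire margin on H&E frozen sections during the operation. `mohsmap`
implements the full pipeline for highlighting tumor regions in single FMV
captures:

* **Tiling and labeling** — images are split into 224 × 224 px tiles; a
  tile is labeled *positive* when tumor occupies ≥ 10 % of its area,
  otherwise *control*, with extra controls drawn from images of other
  diagnoses (the other tumor class, actinic keratosis, normal skin).
* **Tile classifier** — a convolutional feature extractor topped by three
  dense layers and a softmax, trained with categorical cross-entropy,
  augmentation, early stopping and a 200-epoch cap. A small from-scratch
  backbone is bundled; externally trained backbones are pluggable.
* **Weak supervision** — a two-stage procedure that needs no expert masks:
  stage 1 trains on image-level diagnoses, stage 2 retrains on the positive
  tiles whose stage-1 probability is ≥ t (default t = 0.5), with control
  tiles kept unchanged.
* **Saliency maps** — overlapping sliding-window inference (default stride
  = half tile) assembled into a per-cell tumor probability map, including
  40× → 100× cross-magnification application (2.5× resampling).
* **Evaluation** — the ground-truth mask is reshaped to the prediction
  grid and scored by average precision (AUPRC), AUROC, the highest Dice
  coefficient over thresholds, and folds enrichment of precision
  (FEP = AUPRC / positive fraction), with the ≥ 10 % non-tumor eligibility
  rule.
* **Validation statistics** — patient-level leave-one-out cross-validation,
  10,000-iteration ordinary bootstrap CIs, paired Wilcoxon comparisons at
  α = 0.01, and Fleiss' kappa interrater agreement on segmentation masks
  (50 × 50 px tiles, ≥ 5 % tumor rule).
* **Synthetic histology** — a generator of frozen-section-like images with
  exactly known tumor masks (analytic ellipse geometry, texture
  separability dial, distractor control kinds), so the whole pipeline is
  testable without clinical data.

## Worked example

The reference experiment simulates a 12-patient cohort (4 images each,
448 × 448 px, texture separability 0.9), trains the bundled backbone fully
supervised on the development split, and scores saliency maps on the
held-out validation patients:

```r
library(mohsmap)
demo <- runDemo(seed = 1)
#> generating synthetic cohort: 12 patients x 4 images, 448x448 px, separability 0.90, seed 1
#> building fully supervised training set (tile 224 px, stride 224, positive >= 0.10)
#> training on 128 tiles (34 positive)
#> evaluating validation split (inference stride 112, aggregation mean)
#> median AUPRC 1.000 (95% CI 0.688-1.000), AUROC 1.000, Dice 1.000, FEP 6.00 over 8 eligible images

head(demo$results[, c("image_id", "patient_id", "auprc", "auroc",
                      "dice_max", "fep", "eligible")], 4)
#>   image_id patient_id  auprc     auroc  dice_max  fep eligible
#> 1  img0009     pat003 1.0000 1.0000000 1.0000000 8.00     TRUE
#> 2  img0010     pat003 1.0000 1.0000000 1.0000000 4.00     TRUE
#> 3  img0011     pat003 1.0000 1.0000000 1.0000000 8.00     TRUE
#> 4  img0012     pat003 0.8875 0.9583333 0.8888889 3.55     TRUE
```

Each row scores one held-out image: `auprc` is the area under the
precision–recall curve over the map's grid cells against the reshaped
mask (1.0 = the ranking separates tumor from non-tumor cells perfectly),
`auroc` the corresponding rank statistic, `dice_max` the best achievable
overlap over all map thresholds, and `fep` how many times more precise the
map is than a random locator (8.00 on an image with 12.5 % tumor cells is
the maximum possible). `eligible` marks images with ≥ 10 % non-tumor area,
the inclusion rule for cross-validated summaries.

Individual objects print concise summaries:

```r
img <- cohortImages(demo$cohort)[["img0009"]]
img
#> SpecimenImage 'img0009' (448 x 448 px, 100x, BCC, patient pat003)

map <- slidingWindowProbabilityMap(demo$model, img)
map
#> ProbabilityMap: 4 x 4 cells, values in [0.008, 0.998], model 100x on 100x image

evaluateImage(map, cohortMasks(demo$cohort)[["img0009"]])
#> ImageEvalResult: AUPRC 1.000, AUROC 1.000, best Dice 1.000 (t=0.997), FEP 8.00, 12.5% positive
```

Weakly supervised training on the same cohort, with the survival and
enrichment bookkeeping of the confidence filter:

```r
w <- trainWsl(demo$cohort, "BCC", "100x", tileSize = 224, stride = 224)
w$report$survivalRate      # fraction of weak-positive tiles kept at t = 0.5
```

A thin command-line front end covers the same pipeline
(`inst/cli/mohsmap.R`; subcommands `simulate`, `tile`, `train`,
`train-wsl`, `predict`, `evaluate`, `crossval`, `compare`, `agreement`,
`demo`).

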