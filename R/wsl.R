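# Two-stage weakly supervised training: stage 1 trains on tiles labeled
# with the image-level diagnosis only; stage 2 retrains from scratch on the
# positive tiles whose stage-1 inferred target-class probability is >= t
# (inclusive), with control tiles kept unconditionally.

#' Construct a weakly-supervised-learning configuration
#'
#' @param filteringThreshold t in [0, 1]; positive tiles survive to stage 2
#'   iff their stage-1 target-class probability is >= t (default 0.5).
#' @param stage1,stage2 [trainConfig()] objects for the two stages. Stage 1
#'   defaults to a gentler schedule (learning rate 3e-4, stronger weight
#'   decay, early-stopping patience 30): its labels carry the
#'   weak-supervision noise, which makes the monitored validation loss
#'   non-monotone and easy to overfit early in training.
#' @return validated list of class `"mohsmapWslConfig"`.
#' @export
wslConfig <- function(filteringThreshold = 0.5,
                      stage1 = trainConfig(seed = 11L,
                                           earlyStoppingPatience = 30L,
                                           learningRate = 3e-4,
                                           weightDecay = 1),
                      stage2 = trainConfig(seed = 12L)) {
  stopIfNot01(filteringThreshold, "filteringThreshold")
  cfg <- list(filteringThreshold = filteringThreshold,
              stage1 = stage1, stage2 = stage2)
  class(cfg) <- "mohsmapWslConfig"
  cfg
}

#' Weakly label tiles from image-level diagnoses
#'
#' Every tile of a target-class image is labeled positive regardless of
#' actual tumor extent; every tile of an other-diagnosis image is labeled
#' control. Segmentation masks are not consulted and `tumor_fraction`
#' remains unknown (`NA`).
#'
#' @inheritParams buildTrainingSet
#' @return a [TileDataset-class].
#' @export
weakLabelTiles <- function(cohort, targetClass = "BCC",
                           magnification = "100x", tileSize = 224L,
                           stride = tileSize, split = "development") {
  stopifnot(is(cohort, "CohortDataset"))
  info <- cohort@info
  if (!is.null(split)) info <- info[info$split == split, , drop = FALSE]
  info <- info[info$magnification == magnification, , drop = FALSE]
  targetIds <- info$image_id[info$diagnosis == targetClass]
  if (length(targetIds) == 0)
    stop("no ", targetClass, " images at ", magnification)
  ctlIds <- info$image_id[info$diagnosis != targetClass]
  tileOne <- function(id, label) {
    tl <- splitIntoTiles(cohort@images[[id]], tileSize, stride)
    tl$tumor_fraction <- NA_real_
    tl$label <- label
    tl
  }
  tiles <- rbind(
    do.call(rbind, lapply(targetIds, tileOne, label = "positive")),
    if (length(ctlIds))
      do.call(rbind, lapply(ctlIds, tileOne, label = "control")))
  rownames(tiles) <- NULL
  new("TileDataset", tiles = tiles,
      images = cohort@images[c(targetIds, ctlIds)],
      targetClass = targetClass, magnification = magnification)
}

#' Filter weakly labeled tiles by stage-1 confidence
#'
#' Keeps a positive-labeled tile iff the stage-1 model's target-class
#' probability is at least `t` (inclusive); control tiles are kept
#' unconditionally and never relabeled. The returned dataset's tile table
#' gains a `stage1_prob` column (NA for controls).
#'
#' @param stage1Model a trained [TileClassifier-class] (or a stub function,
#'   see [predictTiles()]).
#' @param weakDataset the [TileDataset-class] from [weakLabelTiles()].
#' @param t filtering threshold in [0, 1].
#' @param probabilities optional precomputed target-class probabilities for
#'   every tile of `weakDataset` (skips prediction).
#' @return a [TileDataset-class] of surviving tiles.
#' @export
selectConfidentTiles <- function(stage1Model, weakDataset, t = 0.5,
                                 probabilities = NULL) {
  stopifnot(is(weakDataset, "TileDataset"))
  stopIfNot01(t, "t")
  tiles <- weakDataset@tiles
  pos <- tiles$label == "positive"
  if (is.null(probabilities)) {
    P <- predictTiles(stage1Model, weakDataset)
    probabilities <- P[, "positive"]
  }
  stopifnot(length(probabilities) == nrow(tiles))
  keep <- !pos | probabilities >= t
  if (!any(pos & keep))
    stop("no positive tiles survive the filtering threshold t = ", t)
  tiles$stage1_prob <- ifelse(pos, probabilities, NA_real_)
  out <- tiles[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("TileDataset", tiles = out,
      images = weakDataset@images[unique(out$image_id)],
      targetClass = weakDataset@targetClass,
      magnification = weakDataset@magnification)
}

#' Two-stage weakly supervised training
#'
#' Runs [weakLabelTiles()], trains a stage-1 classifier on the weak labels,
#' filters positive tiles by stage-1 confidence with
#' [selectConfidentTiles()], and retrains a freshly initialized stage-2
#' classifier on the surviving tiles.
#'
#' @inheritParams weakLabelTiles
#' @param config a [wslConfig()] object.
#' @param spec an [ArchitectureSpec-class] used for both stages.
#' @param seed integer seed for model initialization (training randomness is
#'   governed by the per-stage train configs).
#' @return list with elements `model` (stage-2 trained classifier),
#'   `stage1Model`, `report` (tile counts, survival rate, threshold, and the
#'   kept/discarded positive-tile tables), and the two training histories.
#' @export
trainWsl <- function(cohort, targetClass = "BCC", magnification = "100x",
                     config = wslConfig(), tileSize = 224L,
                     stride = tileSize, spec = architectureSpec(),
                     seed = 1L, split = "development") {
  stopifnot(inherits(config, "mohsmapWslConfig"))
  weak <- weakLabelTiles(cohort, targetClass, magnification, tileSize,
                         stride, split = split)
  m1 <- buildModel(spec, seed = substreamSeed(seed, 21L),
                   inputSize = tileSize)
  s1 <- trainClassifier(m1, weak, config$stage1)
  probs <- predictTiles(s1$model, weak)[, "positive"]
  filtered <- selectConfidentTiles(s1$model, weak,
                                   t = config$filteringThreshold,
                                   probabilities = probs)
  pos <- weak@tiles$label == "positive"
  keptPos <- pos & probs >= config$filteringThreshold
  m2 <- buildModel(spec, seed = substreamSeed(seed, 22L),
                   inputSize = tileSize)
  s2 <- trainClassifier(m2, filtered, config$stage2)
  report <- list(
    threshold = config$filteringThreshold,
    nWeakPositive = sum(pos),
    nKeptPositive = sum(keptPos),
    nControls = sum(!pos),
    survivalRate = sum(keptPos) / sum(pos),
    keptTiles = weak@tiles[keptPos, c("image_id", "patient_id", "row",
                                      "col", "size")],
    discardedTiles = weak@tiles[pos & !keptPos,
                                c("image_id", "patient_id", "row", "col",
                                  "size")])
  list(model = s2$model, stage1Model = s1$model, report = report,
       stage1History = s1$history, stage2History = s2$history)
}
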