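#' Accessors for mohsmap objects
#'
#' Small accessor functions exposing slots of the package's S4 containers;
#' user code should use these rather than `@`.
#'
#' @param x an object of the documented class.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
setMethod("pixelData", "SpecimenImage", function(x) x@pixels)

#' @rdname accessors
setMethod("imageId", "SpecimenImage", function(x) x@imageId)

#' @rdname accessors
setMethod("imageId", "TumorMask", function(x) x@imageId)

#' @rdname accessors
setMethod("patientId", "SpecimenImage", function(x) x@patientId)

#' @rdname accessors
setMethod("magnification", "SpecimenImage", function(x) x@magnification)

#' @rdname accessors
setMethod("magnification", "TileDataset", function(x) x@magnification)

#' @rdname accessors
setMethod("diagnosis", "SpecimenImage", function(x) x@diagnosis)

#' @rdname accessors
setMethod("maskData", "TumorMask", function(x) x@mask)

#' @rdname accessors
setMethod("positiveFraction", "TumorMask", function(x) mean(x@mask))

#' @rdname accessors
setMethod("positiveFraction", "ImageEvalResult", function(x) x@positiveFraction)

#' @rdname accessors
setMethod("imageInfo", "CohortDataset", function(x) x@info)

#' @rdname accessors
setMethod("cohortImages", "CohortDataset", function(x) x@images)

#' @rdname accessors
setMethod("cohortMasks", "CohortDataset", function(x) x@masks)

#' @rdname accessors
setMethod("tileInfo", "TileDataset", function(x) x@tiles)

#' @rdname accessors
setMethod("nTiles", "TileDataset", function(x) nrow(x@tiles))

#' @rdname accessors
setMethod("classOrder", "TileClassifier", function(x) x@classOrder)

#' @rdname accessors
setMethod("mapValues", "ProbabilityMap", function(x) x@values)

#' @rdname accessors
setMethod("mapCounts", "ProbabilityMap", function(x) x@counts)

#' @rdname accessors
setMethod("gridGeometry", "ProbabilityMap", function(x) x@grid)

#' @rdname accessors
setMethod("gridGeometry", "GridMask", function(x) x@grid)

#' @rdname accessors
setMethod("cellLabels", "GridMask", function(x) x@labels)

#' @rdname accessors
setMethod("cellFractions", "GridMask", function(x) x@cellFractions)

#' @describeIn accessors one-row data.frame of a per-image evaluation.
#' @export
#' @method as.data.frame ImageEvalResult
as.data.frame.ImageEvalResult <- function(x, ...) {
  data.frame(auprc = x@auprc, auroc = x@auroc, dice_max = x@diceMax,
             dice_threshold = x@diceThreshold, fep = x@fep,
             positive_fraction = x@positiveFraction, eligible = x@eligible)
}

setMethod("show", "SpecimenImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SpecimenImage '%s' (%d x %d px, %s, %s, patient %s)\n",
              object@imageId, d[1], d[2], object@magnification,
              object@diagnosis, object@patientId))
})

setMethod("show", "TumorMask", function(object) {
  cat(sprintf("TumorMask for image '%s' (%d x %d px, %.1f%% tumor)\n",
              object@imageId, nrow(object@mask), ncol(object@mask),
              100 * mean(object@mask)))
})

setMethod("show", "CohortDataset", function(object) {
  info <- object@info
  cat(sprintf(
    "CohortDataset: %d images, %d patients, %d annotated; %d development / %d validation\n",
    nrow(info), length(unique(info$patient_id)), length(object@masks),
    sum(info$split == "development"), sum(info$split == "validation")))
  print(table(diagnosis = info$diagnosis))
})

setMethod("show", "TileDataset", function(object) {
  cat(sprintf("TileDataset (%s, %s): %d tiles from %d images\n",
              object@targetClass, object@magnification,
              nrow(object@tiles), length(unique(object@tiles$image_id))))
  print(table(label = object@tiles$label))
})

setMethod("show", "ArchitectureSpec", function(object) {
  cat(sprintf(
    "ArchitectureSpec: backbone '%s', dense head %s -> softmax(%d)%s\n",
    object@backboneId, paste(object@denseWidths, collapse = "-"),
    object@nClasses, if (object@pretrained) " [pretrained]" else ""))
})

setMethod("show", "TileClassifier", function(object) {
  trained <- isTRUE(object@parameters$trained)
  cat(sprintf("TileClassifier (%s) on %d x %d tiles, classes: %s\n",
              if (trained) "trained" else "initialized",
              object@inputSize, object@inputSize,
              paste(object@classOrder, collapse = ", ")))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d x %d cells of %d px (tile %d px) over a %d x %d image\n",
    object@nRows, object@nCols, object@stride, object@tileSize,
    object@imageHeight, object@imageWidth))
})

setMethod("show", "ProbabilityMap", function(object) {
  cat(sprintf(
    "ProbabilityMap: %d x %d cells, values in [%.3f, %.3f], model %s on %s image\n",
    nrow(object@values), ncol(object@values), min(object@values),
    max(object@values), object@modelMagnification,
    object@imageMagnification))
})

setMethod("show", "ImageEvalResult", function(object) {
  cat(sprintf(
    "ImageEvalResult: AUPRC %.3f, AUROC %.3f, best Dice %.3f (t=%.3f), FEP %.2f, %.1f%% positive%s\n",
    object@auprc, object@auroc, object@diceMax, object@diceThreshold,
    object@fep, 100 * object@positiveFraction,
    if (object@eligible) "" else " [ineligible]"))
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("Bootstrap %s: %.4f, %g%% CI [%.4f, %.4f] (%d iterations, %s)\n",
              object@statisticName, object@pointEstimate,
              100 * object@level, object@ciLow, object@ciHigh,
              object@nIterations, object@method))
})
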