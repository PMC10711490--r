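#' @import methods
NULL

.MAGNIFICATIONS <- c("40x", "100x")

#' Parameters for the synthetic frozen-section generator
#'
#' Bundles the knobs of the synthetic histology generator: image geometry,
#' magnification tag, the number and size of planted tumor blobs, the
#' texture separability between tumor and background, and the density of
#' distractor structures.
#'
#' @slot imageWidth,imageHeight image size in pixels.
#' @slot magnification magnification tag, `"40x"` or `"100x"`.
#' @slot nTumorBlobs number of planted elliptical tumor regions (>= 0).
#' @slot blobRadiusRange length-2 numeric, min/max blob semi-axis in pixels.
#' @slot separability real in [0, 1]; 0 makes tumor and background textures
#'   identically distributed, 1 maximizes nucleus density and color contrast.
#' @slot distractorDensity non-negative density multiplier for incidental
#'   structures (follicle rings, inflammation speckle) in control kinds.
#' @slot seed integer seed; all per-image randomness is derived from it
#'   through counter-based substreams.
#' @export
setClass("SynthesisParams", representation(
  imageWidth = "integer", imageHeight = "integer",
  magnification = "character",
  nTumorBlobs = "integer", blobRadiusRange = "numeric",
  separability = "numeric", distractorDensity = "numeric",
  seed = "integer"
))

setValidity("SynthesisParams", function(object) {
  msg <- character()
  if (object@imageWidth < 1L || object@imageHeight < 1L)
    msg <- c(msg, "image dimensions must be positive")
  if (!object@magnification %in% .MAGNIFICATIONS)
    msg <- c(msg, "magnification must be one of '40x', '100x'")
  if (object@nTumorBlobs < 0L)
    msg <- c(msg, "nTumorBlobs must be >= 0")
  if (length(object@blobRadiusRange) != 2L ||
      any(object@blobRadiusRange <= 0) ||
      object@blobRadiusRange[1] > object@blobRadiusRange[2])
    msg <- c(msg, "blobRadiusRange must be increasing positive (min, max)")
  halfDiag <- sqrt(object@imageWidth^2 + object@imageHeight^2) / 2
  if (object@nTumorBlobs > 0L && object@blobRadiusRange[2] > halfDiag)
    msg <- c(msg, "max blob radius exceeds the image half-diagonal")
  if (object@separability < 0 || object@separability > 1)
    msg <- c(msg, "separability must lie in [0, 1]")
  if (object@distractorDensity < 0)
    msg <- c(msg, "distractorDensity must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A microscope field-of-view image
#'
#' One focused microscope view (FMV): an 8-bit RGB pixel grid together with
#' its patient, magnification and diagnosis metadata.
#'
#' @slot pixels integer array height x width x 3, values in 0..255.
#' @slot patientId,imageId opaque identifiers.
#' @slot magnification `"40x"` or `"100x"`.
#' @slot diagnosis diagnosis label (e.g. `"BCC"`, `"SCC"`, `"AK"`, `"normal"`).
#' @export
setClass("SpecimenImage", representation(
  pixels = "array", patientId = "character", imageId = "character",
  magnification = "character", diagnosis = "character"
))

setValidity("SpecimenImage", function(object) {
  d <- dim(object@pixels)
  msg <- character()
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "pixels must be a height x width x 3 array")
  r <- range(object@pixels)
  if (r[1] < 0 || r[2] > 255)
    msg <- c(msg, "pixel values must lie in [0, 255]")
  if (!object@magnification %in% .MAGNIFICATIONS)
    msg <- c(msg, "magnification must be one of '40x', '100x'")
  if (length(msg)) msg else TRUE
})

#' A binary tumor segmentation mask
#'
#' Per-pixel ground-truth tumor annotation aligned pixel-for-pixel with one
#' [SpecimenImage-class].
#'
#' @slot mask logical matrix, `TRUE` = tumor.
#' @slot imageId identifier of the annotated image.
#' @export
setClass("TumorMask", representation(mask = "matrix", imageId = "character"))

setValidity("TumorMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (anyNA(object@mask)) return("mask must not contain NA")
  TRUE
})

#' A cohort of specimen images with optional masks
#'
#' Holds a collection of [SpecimenImage-class] objects, a partial mapping
#' from image id to [TumorMask-class], and a development/validation split
#' tag per image. Patients are always assigned whole to one split.
#'
#' @slot images named list of `SpecimenImage` (names = image ids).
#' @slot masks named list of `TumorMask` for the annotated subset.
#' @slot info data.frame with columns image_id, patient_id, split,
#'   magnification, diagnosis.
#' @export
setClass("CohortDataset", representation(
  images = "list", masks = "list", info = "data.frame"
))

setValidity("CohortDataset", function(object) {
  msg <- character()
  ids <- vapply(object@images, function(x) x@imageId, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate image ids")
  if (!identical(sort(names(object@images)), sort(unname(ids))))
    msg <- c(msg, "images list names must equal image ids")
  if (length(object@masks) &&
      !all(names(object@masks) %in% names(object@images)))
    msg <- c(msg, "every mask's image id must exist among the images")
  need <- c("image_id", "patient_id", "split", "magnification", "diagnosis")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, paste("info must have columns:", paste(need, collapse = ", ")))
  else {
    if (!setequal(object@info$image_id, names(object@images)))
      msg <- c(msg, "info rows must match the images")
    if (!all(object@info$split %in% c("development", "validation")))
      msg <- c(msg, "split must be 'development' or 'validation'")
    bad <- tapply(object@info$split, object@info$patient_id,
                  function(s) length(unique(s)) > 1L)
    if (any(unlist(bad)))
      msg <- c(msg, "each patient must belong to exactly one split")
  }
  for (id in names(object@masks)) {
    m <- object@masks[[id]]@mask
    p <- object@images[[id]]@pixels
    if (!identical(dim(m), dim(p)[1:2])) {
      msg <- c(msg, sprintf("mask for image '%s' does not match its image size", id))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' A dataset of labeled square tiles
#'
#' Tiles are stored as window references (grid origin + size) into their
#' source images; pixel content is read from the source image at access
#' time through [tilePixels()].
#'
#' @slot tiles data.frame with columns image_id, patient_id, row, col, size,
#'   tumor_fraction (NA when unknown), label ("positive"/"control").
#' @slot images named list of source [SpecimenImage-class] objects.
#' @slot targetClass the tumor type this dataset trains (e.g. "BCC").
#' @slot magnification shared magnification of all tiles.
#' @export
setClass("TileDataset", representation(
  tiles = "data.frame", images = "list",
  targetClass = "character", magnification = "character"
))

setValidity("TileDataset", function(object) {
  t <- object@tiles
  need <- c("image_id", "patient_id", "row", "col", "size",
            "tumor_fraction", "label")
  if (!all(need %in% names(t)))
    return(paste("tiles must have columns:", paste(need, collapse = ", ")))
  if (!all(t$image_id %in% names(object@images)))
    return("every tile must reference a stored image")
  if (!all(t$label %in% c("positive", "control", "unlabeled")))
    return("labels must be 'positive', 'control' or 'unlabeled'")
  known <- !is.na(t$tumor_fraction)
  if (any(t$tumor_fraction[known] < 0 | t$tumor_fraction[known] > 1))
    return("tumor_fraction must lie in [0, 1]")
  TRUE
})

#' Architecture contract for the tile classifier
#'
#' A convolutional feature extractor topped by exactly three dense layers
#' and a final softmax layer.
#'
#' @slot backboneId feature extractor identifier; `"small"` is the bundled
#'   from-scratch extractor, any other id requires externally supplied
#'   weights.
#' @slot denseWidths exactly three positive integers, the hidden dense
#'   layer widths before the softmax output layer.
#' @slot nClasses number of output classes (>= 2).
#' @slot pretrained whether externally supplied backbone weights are used.
#' @export
setClass("ArchitectureSpec", representation(
  backboneId = "character", denseWidths = "integer",
  nClasses = "integer", pretrained = "logical"
))

setValidity("ArchitectureSpec", function(object) {
  msg <- character()
  if (length(object@denseWidths) != 3L || any(object@denseWidths < 1L))
    msg <- c(msg, "exactly three positive dense layer widths are required")
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (length(msg)) msg else TRUE
})

#' A (possibly trained) tile classifier
#'
#' @slot architecture the [ArchitectureSpec-class].
#' @slot parameters opaque list of extractor filters, head weights and
#'   feature standardization statistics.
#' @slot classOrder ordered class labels; prediction columns follow it.
#' @slot inputSize expected square tile side in pixels.
#' @export
setClass("TileClassifier", representation(
  architecture = "ArchitectureSpec", parameters = "list",
  classOrder = "character", inputSize = "integer"
))

#' Geometry of the prediction grid
#'
#' Cells are stride x stride pixel blocks anchored at (0, 0); the last row
#' and column of cells may be truncated at the image border so that every
#' pixel belongs to exactly one cell.
#'
#' @slot tileSize,stride window size and stride in pixels; cell size equals
#'   the stride.
#' @slot nRows,nCols number of grid cells per axis.
#' @slot imageHeight,imageWidth image size in pixels.
#' @export
setClass("GridSpec", representation(
  tileSize = "integer", stride = "integer",
  nRows = "integer", nCols = "integer",
  imageHeight = "integer", imageWidth = "integer"
))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (object@stride < 1L || object@tileSize < 1L)
    msg <- c(msg, "tileSize and stride must be >= 1")
  if (object@stride > object@tileSize)
    msg <- c(msg, "stride must not exceed tileSize")
  if (object@nRows != ceiling(object@imageHeight / object@stride) ||
      object@nCols != ceiling(object@imageWidth / object@stride))
    msg <- c(msg, "grid shape inconsistent with image size and stride")
  if (length(msg)) msg else TRUE
})

#' A tumor probability (saliency) map on the prediction grid
#'
#' @slot grid the [GridSpec-class] geometry.
#' @slot values matrix nRows x nCols of tumor probabilities in [0, 1].
#' @slot counts integer matrix of the number of sliding windows that
#'   contributed to each cell (>= 1 everywhere).
#' @slot modelMagnification,imageMagnification magnification tags of the
#'   model and the (possibly resized) image it was applied to.
#' @export
setClass("ProbabilityMap", representation(
  grid = "GridSpec", values = "matrix", counts = "matrix",
  modelMagnification = "character", imageMagnification = "character"
))

setValidity("ProbabilityMap", function(object) {
  g <- object@grid
  msg <- character()
  if (!identical(dim(object@values), c(g@nRows, g@nCols)) ||
      !identical(dim(object@counts), c(g@nRows, g@nCols)))
    msg <- c(msg, "values/counts shape must match the grid")
  if (any(object@values < 0 | object@values > 1))
    msg <- c(msg, "map values must lie in [0, 1]")
  if (any(object@counts < 1))
    msg <- c(msg, "every cell must receive at least one prediction")
  if (length(msg)) msg else TRUE
})

#' A ground-truth mask reshaped to a prediction grid
#'
#' @slot grid the [GridSpec-class] geometry.
#' @slot labels binary (0/1) matrix of cell labels.
#' @slot cellFractions matrix of per-cell tumor-area fractions.
#' @export
setClass("GridMask", representation(
  grid = "GridSpec", labels = "matrix", cellFractions = "matrix"
))

#' Per-image evaluation result
#'
#' @slot auprc,auroc,diceMax,fep,positiveFraction metric values; `fep`
#'   (folds enrichment of precision) is `auprc / positiveFraction`.
#' @slot diceThreshold smallest threshold achieving `diceMax`.
#' @slot eligible TRUE when the image has >= 10\% non-tumor cells and at
#'   least one tumor cell, the eligibility rule for cross-validation.
#' @export
setClass("ImageEvalResult", representation(
  auprc = "numeric", auroc = "numeric", diceMax = "numeric",
  diceThreshold = "numeric", fep = "numeric",
  positiveFraction = "numeric", eligible = "logical"
))

#' A bootstrap confidence interval
#'
#' @slot statisticName name of the resampled statistic.
#' @slot pointEstimate statistic on the observed sample.
#' @slot ciLow,ciHigh interval endpoints.
#' @slot level confidence level.
#' @slot nIterations number of bootstrap resamples.
#' @slot method "percentile" or "bca".
#' @export
setClass("BootstrapResult", representation(
  statisticName = "character", pointEstimate = "numeric",
  ciLow = "numeric", ciHigh = "numeric", level = "numeric",
  nIterations = "integer", method = "character"
))
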