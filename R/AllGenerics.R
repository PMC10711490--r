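#' @rdname accessors
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))

#' @rdname accessors
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))

#' @rdname accessors
#' @export
setGeneric("positiveFraction", function(x) standardGeneric("positiveFraction"))

#' @rdname accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname accessors
#' @export
setGeneric("magnification", function(x) standardGeneric("magnification"))

#' @rdname accessors
#' @export
setGeneric("diagnosis", function(x) standardGeneric("diagnosis"))

#' @rdname accessors
#' @export
setGeneric("imageInfo", function(x) standardGeneric("imageInfo"))

#' @rdname accessors
#' @export
setGeneric("cohortImages", function(x) standardGeneric("cohortImages"))

#' @rdname accessors
#' @export
setGeneric("cohortMasks", function(x) standardGeneric("cohortMasks"))

#' @rdname accessors
#' @export
setGeneric("tileInfo", function(x) standardGeneric("tileInfo"))

#' @rdname accessors
#' @export
setGeneric("nTiles", function(x) standardGeneric("nTiles"))

#' @rdname accessors
#' @export
setGeneric("classOrder", function(x) standardGeneric("classOrder"))

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname accessors
#' @export
setGeneric("mapCounts", function(x) standardGeneric("mapCounts"))

#' @rdname accessors
#' @export
setGeneric("gridGeometry", function(x) standardGeneric("gridGeometry"))

#' @rdname accessors
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname accessors
#' @export
setGeneric("cellFractions", function(x) standardGeneric("cellFractions"))

#' Predict class probabilities for tiles
#'
#' Returns one softmax probability vector per tile, order-aligned with the
#' input. The method for plain functions lets a user-supplied
#' `function(listOfTilePixelArrays) -> numeric` stand in as a classifier
#' (its return is interpreted as the target-class probability and completed
#' to a two-column softmax matrix), which is convenient for stubs and
#' oracles.
#'
#' @param model a [TileClassifier-class] or a function.
#' @param tiles a [TileDataset-class], or a list of integer pixel arrays
#'   (height x width x 3, 0..255).
#' @param ... passed to methods.
#' @return numeric matrix, one row per tile, columns named by
#'   [classOrder()]; rows sum to 1.
#' @export
setGeneric("predictTiles", function(model, tiles, ...)
  standardGeneric("predictTiles"))
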