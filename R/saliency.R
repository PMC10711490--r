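# Sliding-window saliency-map assembly. The prediction grid is the set of
# stride x stride cells anchored at (0, 0) (last row/column truncated at the
# border); every edge-snapped tile window is classified and its target-class
# probability is credited to each cell it fully covers, then cell values are
# aggregated (mean by default, max available).

#' Construct a prediction-grid geometry
#'
#' @param imageHeight,imageWidth image size in pixels.
#' @param tileSize sliding-window size in pixels.
#' @param stride window step, which is also the cell size.
#' @return a [GridSpec-class].
#' @export
gridSpec <- function(imageHeight, imageWidth, tileSize = 224L,
                     stride = tileSize %/% 2L) {
  new("GridSpec", tileSize = as.integer(tileSize), stride = as.integer(stride),
      nRows = as.integer(ceiling(imageHeight / stride)),
      nCols = as.integer(ceiling(imageWidth / stride)),
      imageHeight = as.integer(imageHeight),
      imageWidth = as.integer(imageWidth))
}

# cells (0-based) fully covered by a window starting at `origin`
coveredCells <- function(origin, tileSize, stride, dimLen, nCells) {
  crMin <- max(0L, as.integer(ceiling(origin / stride)))
  if (crMin > nCells - 1L) return(integer(0))
  crs <- crMin:(nCells - 1L)
  ends <- pmin((crs + 1L) * stride, dimLen)
  crs[crs * stride >= origin & ends <= origin + tileSize]
}

#' Assemble a tumor probability map by sliding-window inference
#'
#' Classifies every tile window of the edge-snapped grid and aggregates the
#' overlapping target-class probabilities per grid cell. Overlap (stride <
#' tileSize, default tileSize/2) is the point of the technique: it grades
#' the map near tumor contours instead of committing to one tiling.
#'
#' @param model a trained [TileClassifier-class], or a stub function (see
#'   [predictTiles()]).
#' @param image a [SpecimenImage-class], at the model's magnification (use
#'   [resizeForMagnification()] first for cross-magnification inference).
#' @param tileSize,stride window geometry; `stride <= tileSize`.
#' @param aggregation `"mean"` (default) or `"max"` over the windows
#'   covering a cell.
#' @param targetClass prediction column to map (default `"positive"`).
#' @param modelMagnification recorded tag; defaults to the image's.
#' @return a [ProbabilityMap-class].
#' @export
slidingWindowProbabilityMap <- function(model, image, tileSize = 224L,
                                        stride = tileSize %/% 2L,
                                        aggregation = c("mean", "max"),
                                        targetClass = "positive",
                                        modelMagnification = NULL) {
  aggregation <- match.arg(aggregation)
  stopifnot(is(image, "SpecimenImage"))
  d <- dim(image@pixels)
  if (tileSize > min(d[1:2])) stop("image smaller than the tile size")
  if (stride > tileSize) stop("stride must not exceed tileSize")
  g <- gridSpec(d[1], d[2], tileSize, stride)
  rows <- tileOrigins(d[1], tileSize, stride)
  cols <- tileOrigins(d[2], tileSize, stride)
  wins <- expand.grid(col = cols, row = rows)
  px <- lapply(seq_len(nrow(wins)), function(i)
    image@pixels[(wins$row[i] + 1L):(wins$row[i] + tileSize),
                 (wins$col[i] + 1L):(wins$col[i] + tileSize), ,
                 drop = FALSE])
  P <- predictTiles(model, px)
  probs <- P[, targetClass]
  acc <- matrix(if (aggregation == "mean") 0 else -Inf, g@nRows, g@nCols)
  cnt <- matrix(0L, g@nRows, g@nCols)
  for (i in seq_len(nrow(wins))) {
    cr <- coveredCells(wins$row[i], tileSize, stride, d[1], g@nRows) + 1L
    cc <- coveredCells(wins$col[i], tileSize, stride, d[2], g@nCols) + 1L
    if (aggregation == "mean")
      acc[cr, cc] <- acc[cr, cc] + probs[i]
    else
      acc[cr, cc] <- pmax(acc[cr, cc], probs[i])
    cnt[cr, cc] <- cnt[cr, cc] + 1L
  }
  vals <- if (aggregation == "mean") acc / pmax(cnt, 1L) else acc
  new("ProbabilityMap", grid = g, values = vals, counts = cnt,
      modelMagnification = if (is.null(modelMagnification))
        image@magnification else modelMagnification,
      imageMagnification = image@magnification)
}

.MAG_VALUE <- c("40x" = 40, "100x" = 100)

#' Resize an image (and optionally its mask) across magnifications
#'
#' Rescales by the magnification ratio (40x to 100x is exactly 2.5) with
#' bilinear interpolation for the image and nearest-neighbour for the mask,
#' preserving mask binarity.
#'
#' @param image a [SpecimenImage-class].
#' @param targetMag target magnification tag.
#' @param mask optional paired [TumorMask-class].
#' @return the resized [SpecimenImage-class], or a list `(image, mask)`
#'   when a mask is supplied.
#' @export
resizeForMagnification <- function(image, targetMag, mask = NULL) {
  stopifnot(is(image, "SpecimenImage"))
  src <- image@magnification
  if (!src %in% names(.MAG_VALUE) || !targetMag %in% names(.MAG_VALUE))
    stop("unknown magnification pair ", src, " -> ", targetMag)
  if (src == targetMag)
    return(if (is.null(mask)) image else list(image = image, mask = mask))
  f <- .MAG_VALUE[[targetMag]] / .MAG_VALUE[[src]]
  d <- dim(image@pixels)
  nh <- as.integer(round(d[1] * f)); nw <- as.integer(round(d[2] * f))
  res <- EBImage::resize(image@pixels / 255, w = nh, h = nw,
                         filter = "bilinear")
  out <- new("SpecimenImage", pixels = quantize255(res),
             patientId = image@patientId, imageId = image@imageId,
             magnification = targetMag, diagnosis = image@diagnosis)
  if (is.null(mask)) return(out)
  mres <- EBImage::resize(maskData(mask) * 1, w = nh, h = nw,
                          filter = "none")
  list(image = out,
       mask = new("TumorMask", mask = mres > 0.5, imageId = mask@imageId))
}

#' Render a probability-map overlay for visual QC
#'
#' Upsamples the grid to pixel resolution, colors it with a blue-to-red
#' ramp, and alpha-blends it over the image. For inspection only; metrics
#' never consume overlays.
#'
#' @param map a [ProbabilityMap-class] whose grid matches the image.
#' @param image the underlying [SpecimenImage-class].
#' @param alpha blend weight in [0, 1]; 0 returns the image unchanged.
#' @param colors colormap anchor colors passed to [grDevices::colorRamp()].
#' @return integer RGB array with the image's dimensions.
#' @export
renderOverlay <- function(map, image, alpha = 0.5,
                          colors = c("#00204D", "#00A0A0", "#FFD700",
                                     "#C00000")) {
  stopifnot(is(map, "ProbabilityMap"), is(image, "SpecimenImage"))
  g <- map@grid
  d <- dim(image@pixels)
  if (g@imageHeight != d[1] || g@imageWidth != d[2])
    stop("map geometry does not match the image")
  stopIfNot01(alpha, "alpha")
  if (alpha == 0) return(image@pixels)
  rowCell <- pmin(g@nRows, (seq_len(d[1]) - 1L) %/% g@stride + 1L)
  colCell <- pmin(g@nCols, (seq_len(d[2]) - 1L) %/% g@stride + 1L)
  vals <- map@values[rowCell, colCell, drop = FALSE]
  ramp <- grDevices::colorRamp(colors)
  rgb <- ramp(as.vector(vals)) / 255
  out <- image@pixels
  for (ch in 1:3) {
    col <- matrix(rgb[, ch], d[1], d[2])
    out[, , ch] <- as.integer(round((1 - alpha) * image@pixels[, , ch] +
                                      alpha * 255 * col))
  }
  out
}
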