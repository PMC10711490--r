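# Square-tile decomposition. Coordinates are 0-based, row-major, top-left
# origin; a tile window is the half-open block [row, row+size) x
# [col, col+size). When the stride does not divide the image, one extra
# origin per axis is appended at (dim - size) so the border is tiled exactly
# once more (overlapping the previous tile) instead of being discarded.

#' Tile origins along one axis
#'
#' @param dim axis length in pixels.
#' @param size tile size in pixels (<= dim).
#' @param stride step between origins (>= 1).
#' @return integer vector of 0-based origins, ending exactly at `dim - size`.
#' @export
tileOrigins <- function(dim, size, stride) {
  if (size > dim) stop("tile size exceeds image dimension")
  if (stride < 1) stop("stride must be >= 1")
  o <- seq.int(0L, dim - size, by = stride)
  if (o[length(o)] != dim - size) o <- c(o, dim - size)
  as.integer(o)
}

#' Split an image into fixed-size square tiles
#'
#' Enumerates the edge-snapped tile grid in row-major order. Tiles are
#' window references; use [tilePixels()] to read their pixel content.
#'
#' @param image a [SpecimenImage-class].
#' @param tileSize square tile side in pixels (default 224).
#' @param stride grid step in pixels (default `tileSize`, disjoint tiles).
#' @return data.frame with columns image_id, patient_id, row, col, size
#'   (0-based origins), one row per tile.
#' @export
splitIntoTiles <- function(image, tileSize = 224L, stride = tileSize) {
  stopifnot(is(image, "SpecimenImage"))
  d <- dim(image@pixels)
  rows <- tileOrigins(d[1], tileSize, stride)
  cols <- tileOrigins(d[2], tileSize, stride)
  g <- expand.grid(col = cols, row = rows)   # row-major ordering
  data.frame(image_id = image@imageId, patient_id = image@patientId,
             row = g$row, col = g$col, size = as.integer(tileSize),
             stringsAsFactors = FALSE)
}

#' Tumor-area fraction of one tile window
#'
#' @param mask a [TumorMask-class] or logical matrix.
#' @param row,col 0-based window origin.
#' @param size window side in pixels.
#' @return mean of the mask over the half-open window, in [0, 1].
#' @export
tileTumorFraction <- function(mask, row, col, size) {
  m <- if (is(mask, "TumorMask")) mask@mask else mask
  if (row < 0 || col < 0 || row + size > nrow(m) || col + size > ncol(m))
    stop("tile window out of mask bounds")
  mean(m[(row + 1L):(row + size), (col + 1L):(col + size)])
}

#' Label a tile from its tumor-area fraction
#'
#' A tile is `"positive"` when tumor occupies at least `positiveThreshold`
#' of its area (inclusive boundary), otherwise `"control"`.
#'
#' @param tumorFraction numeric vector of fractions in [0, 1].
#' @param positiveThreshold labeling threshold (default 0.10).
#' @return character vector of labels.
#' @export
labelTile <- function(tumorFraction, positiveThreshold = 0.10) {
  stopIfNot01(tumorFraction, "tumorFraction")
  ifelse(tumorFraction >= positiveThreshold, "positive", "control")
}

#' Read the pixel content of one tile
#'
#' @param dataset a [TileDataset-class].
#' @param i tile index (row of `tileInfo(dataset)`).
#' @return integer array size x size x 3.
#' @export
tilePixels <- function(dataset, i) {
  t <- dataset@tiles[i, ]
  px <- dataset@images[[t$image_id]]@pixels
  px[(t$row + 1L):(t$row + t$size), (t$col + 1L):(t$col + t$size), ,
     drop = FALSE]
}

#' Build a fully supervised tile training set
#'
#' Tiles annotated target-class images and labels each tile by the
#' tumor-area rule; optionally adds every tile of other-diagnosis and
#' normal images at the same magnification as extra controls.
#'
#' @param cohort a [CohortDataset-class].
#' @param targetClass tumor type to train (e.g. `"BCC"`).
#' @param magnification images to use (`"40x"` or `"100x"`).
#' @param tileSize,stride tiling geometry (defaults 224 / disjoint).
#' @param includeExtraControls add all tiles of non-target-class images as
#'   controls (default TRUE).
#' @param positiveThreshold tumor-area labeling threshold (default 0.10).
#' @param split restrict to one split tag (`"development"`,
#'   `"validation"`) or `NULL` for all images.
#' @return a [TileDataset-class].
#' @export
buildTrainingSet <- function(cohort, targetClass = "BCC",
                             magnification = "100x", tileSize = 224L,
                             stride = tileSize, includeExtraControls = TRUE,
                             positiveThreshold = 0.10, split = "development") {
  stopifnot(is(cohort, "CohortDataset"))
  info <- cohort@info
  if (!is.null(split)) info <- info[info$split == split, , drop = FALSE]
  info <- info[info$magnification == magnification, , drop = FALSE]
  targetIds <- info$image_id[info$diagnosis == targetClass &
                               info$image_id %in% names(cohort@masks)]
  if (length(targetIds) == 0)
    stop("no annotated ", targetClass, " images at ", magnification,
         if (!is.null(split)) paste0(" in the ", split, " split"))
  parts <- lapply(targetIds, function(id) {
    tl <- splitIntoTiles(cohort@images[[id]], tileSize, stride)
    tl$tumor_fraction <- vapply(seq_len(nrow(tl)), function(i)
      tileTumorFraction(cohort@masks[[id]], tl$row[i], tl$col[i], tl$size[i]),
      numeric(1))
    tl$label <- labelTile(tl$tumor_fraction, positiveThreshold)
    tl
  })
  usedIds <- targetIds
  if (includeExtraControls) {
    ctlIds <- info$image_id[info$diagnosis != targetClass]
    if (length(ctlIds)) {
      ctl <- lapply(ctlIds, function(id) {
        tl <- splitIntoTiles(cohort@images[[id]], tileSize, stride)
        tl$tumor_fraction <- NA_real_
        tl$label <- "control"
        tl
      })
      parts <- c(parts, ctl)
      usedIds <- c(usedIds, ctlIds)
    }
  }
  tiles <- do.call(rbind, parts)
  rownames(tiles) <- NULL
  new("TileDataset", tiles = tiles, images = cohort@images[usedIds],
      targetClass = targetClass, magnification = magnification)
}
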