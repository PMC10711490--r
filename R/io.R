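# File plumbing: images as 8-bit RGB PNG, masks as single-channel PNG with
# {0, 255}, cohort manifests and tile tables as CSV, probability maps as a
# flat CSV plus a JSON grid sidecar.

writeImagePng <- function(pixels, path) {
  png::writePNG(pixels / 255, target = path)
}

readImagePixels <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  quantize255(a)
}

readMaskMatrix <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a > 0.5
}

#' Write a cohort to disk
#'
#' Writes each image as an 8-bit RGB PNG, each mask as a single-channel
#' {0, 255} PNG, and a `manifest.csv` with columns image_id, patient_id,
#' split, magnification, diagnosis, image_path, mask_path (empty when
#' unannotated).
#'
#' @param cohort a [CohortDataset-class].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "CohortDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  info <- cohort@info
  info$image_path <- file.path(dir, paste0(info$image_id, ".png"))
  info$mask_path <- ifelse(info$image_id %in% names(cohort@masks),
                           file.path(dir, paste0(info$image_id, "_mask.png")),
                           "")
  for (i in seq_len(nrow(info))) {
    id <- info$image_id[i]
    writeImagePng(cohort@images[[id]]@pixels, info$image_path[i])
    if (nzchar(info$mask_path[i]))
      png::writePNG(cohort@masks[[id]]@mask * 1, target = info$mask_path[i])
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(info, manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from a manifest CSV
#'
#' Validates the manifest (required columns, unique image ids, existing
#' paths, mask/image dimension agreement) with per-row error reporting and
#' loads the images and masks.
#'
#' @param path path to a manifest CSV with columns image_id, patient_id,
#'   split, magnification, diagnosis, image_path and optionally mask_path.
#' @return a [CohortDataset-class].
#' @export
readCohortManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  info <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "patient_id", "split", "magnification", "diagnosis",
            "image_path")
  miss <- setdiff(need, names(info))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  if (!"mask_path" %in% names(info)) info$mask_path <- ""
  info$mask_path[is.na(info$mask_path)] <- ""
  dup <- which(duplicated(info$image_id))
  if (length(dup))
    stop("duplicate image_id '", info$image_id[dup[1]], "' at manifest row ",
         dup[1])
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  images <- list(); masks <- list()
  for (i in seq_len(nrow(info))) {
    ip <- resolve(info$image_path[i])
    if (!file.exists(ip))
      stop("manifest row ", i, ": image file not found: ", info$image_path[i])
    px <- readImagePixels(ip)
    images[[info$image_id[i]]] <- new("SpecimenImage", pixels = px,
                                      patientId = info$patient_id[i],
                                      imageId = info$image_id[i],
                                      magnification = info$magnification[i],
                                      diagnosis = info$diagnosis[i])
    if (nzchar(info$mask_path[i])) {
      mp <- resolve(info$mask_path[i])
      if (!file.exists(mp))
        stop("manifest row ", i, ": mask file not found: ", info$mask_path[i])
      m <- readMaskMatrix(mp)
      if (!identical(dim(m), dim(px)[1:2]))
        stop("manifest row ", i, ": mask dimensions ",
             paste(dim(m), collapse = "x"), " differ from image ",
             paste(dim(px)[1:2], collapse = "x"))
      masks[[info$image_id[i]]] <- new("TumorMask", mask = m,
                                       imageId = info$image_id[i])
    }
  }
  new("CohortDataset", images = images, masks = masks,
      info = info[, c("image_id", "patient_id", "split", "magnification",
                      "diagnosis")])
}

#' Write / read a probability map
#'
#' The map is serialized as a flat CSV (row, col, value, count; 0-based
#' cell indices) with a JSON sidecar (`<path>.grid.json`) holding the grid
#' geometry and magnification tags.
#'
#' @param map a [ProbabilityMap-class].
#' @param path CSV path.
#' @return `writeProbabilityMap`: `path` invisibly; `readProbabilityMap`:
#'   the reconstructed [ProbabilityMap-class].
#' @export
writeProbabilityMap <- function(map, path) {
  stopifnot(is(map, "ProbabilityMap"))
  g <- map@grid
  idx <- expand.grid(row = seq_len(g@nRows) - 1L, col = seq_len(g@nCols) - 1L)
  utils::write.csv(data.frame(row = idx$row, col = idx$col,
                              value = as.vector(map@values),
                              count = as.vector(map@counts)),
                   path, row.names = FALSE)
  side <- list(tileSize = g@tileSize, stride = g@stride, nRows = g@nRows,
               nCols = g@nCols, imageHeight = g@imageHeight,
               imageWidth = g@imageWidth,
               modelMagnification = map@modelMagnification,
               imageMagnification = map@imageMagnification)
  jsonlite::write_json(side, paste0(path, ".grid.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeProbabilityMap
#' @export
readProbabilityMap <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".grid.json"), simplifyVector = TRUE)
  g <- new("GridSpec", tileSize = as.integer(side$tileSize),
           stride = as.integer(side$stride), nRows = as.integer(side$nRows),
           nCols = as.integer(side$nCols),
           imageHeight = as.integer(side$imageHeight),
           imageWidth = as.integer(side$imageWidth))
  vals <- matrix(0, g@nRows, g@nCols)
  cnts <- matrix(0L, g@nRows, g@nCols)
  vals[cbind(df$row + 1L, df$col + 1L)] <- df$value
  cnts[cbind(df$row + 1L, df$col + 1L)] <- as.integer(df$count)
  new("ProbabilityMap", grid = g, values = vals, counts = cnts,
      modelMagnification = side$modelMagnification,
      imageMagnification = side$imageMagnification)
}
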