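# Pixel-level evaluation of a probability map against a ground-truth mask.
# The mask is reshaped to the map's prediction grid (each cell labeled by
# its majority tumor fraction), cells are flattened to score/label
# sequences, and four metrics are computed: average precision (AUPRC),
# AUROC, the highest Dice coefficient over thresholds, and folds enrichment
# of precision (AUPRC / positive fraction).

#' Reshape a pixel mask to a prediction grid
#'
#' Each grid cell's tumor fraction is the mean mask value over its pixel
#' block (border cells are truncated); the cell label is 1 iff the fraction
#' reaches `cellPositiveThreshold`.
#'
#' @param mask a [TumorMask-class] or logical matrix matching the grid's
#'   image dimensions.
#' @param grid a [GridSpec-class].
#' @param cellPositiveThreshold majority threshold in [0, 1] (default 0.5).
#' @return a [GridMask-class].
#' @export
reshapeMaskToGrid <- function(mask, grid, cellPositiveThreshold = 0.5) {
  m <- if (is(mask, "TumorMask")) mask@mask else mask
  if (nrow(m) != grid@imageHeight || ncol(m) != grid@imageWidth)
    stop("mask dimensions do not match the grid's image dimensions")
  s <- grid@stride
  cs <- apply(m * 1, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  S <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  S[-1L, -1L] <- cs           # integral image, S[i+1, j+1] = sum m[1:i, 1:j]
  rb <- c(seq.int(0L, grid@imageHeight - 1L, by = s), grid@imageHeight)
  cb <- c(seq.int(0L, grid@imageWidth - 1L, by = s), grid@imageWidth)
  frac <- matrix(0, grid@nRows, grid@nCols)
  for (r in seq_len(grid@nRows)) for (c in seq_len(grid@nCols)) {
    r0 <- rb[r]; r1 <- rb[r + 1L]; c0 <- cb[c]; c1 <- cb[c + 1L]
    tot <- S[r1 + 1L, c1 + 1L] - S[r0 + 1L, c1 + 1L] -
      S[r1 + 1L, c0 + 1L] + S[r0 + 1L, c0 + 1L]
    frac[r, c] <- tot / ((r1 - r0) * (c1 - c0))
  }
  new("GridMask", grid = grid,
      labels = (frac >= cellPositiveThreshold) * 1,
      cellFractions = frac)
}

checkScoresLabels <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels must not be NA")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise (non-interpolated) average precision over all prediction
#' thresholds: tied scores collapse to one operating point, and each
#' point's precision is weighted by its recall increment.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 ground truth (at least one positive).
#' @return average precision in [0, 1].
#' @export
averagePrecision <- function(scores, labels) {
  checkScoresLabels(scores, labels)
  P <- sum(labels == 1)
  if (P == 0) stop("average precision undefined without positive labels")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  ends <- cumsum(rle(scores[o])$lengths)
  tp <- cumsum(y)[ends]
  prec <- tp / ends
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Area under the ROC curve
#'
#' Rank-statistic formulation: the probability that a random positive
#' outscores a random negative, ties counted one half.
#'
#' @inheritParams averagePrecision
#' @return AUROC in [0, 1].
#' @export
aurocScore <- function(scores, labels) {
  checkScoresLabels(scores, labels)
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) stop("AUROC requires both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Highest Dice coefficient over a threshold grid
#'
#' Dice(t) = 2 TP / (2 TP + FP + FN) for the prediction `scores >= t`;
#' returns the maximum over the grid and the smallest threshold achieving
#' it. The default grid is all distinct score values plus 0 and 1 (exact
#' maximum); very large inputs fall back to 101 evenly spaced thresholds.
#'
#' @inheritParams averagePrecision
#' @param thresholdGrid numeric vector of thresholds, or `NULL` for the
#'   default.
#' @param denseLimit number of distinct scores above which the evenly
#'   spaced fallback grid is used.
#' @return list with `diceMax` and `threshold`.
#' @export
bestDice <- function(scores, labels, thresholdGrid = NULL,
                     denseLimit = 10000L) {
  checkScoresLabels(scores, labels)
  P <- sum(labels == 1)
  if (P == 0) stop("Dice undefined without positive labels")
  if (is.null(thresholdGrid)) {
    u <- unique(scores)
    thresholdGrid <- if (length(u) > denseLimit)
      seq(0, 1, length.out = 101L) else sort(unique(c(0, 1, u)))
  }
  if (length(thresholdGrid) == 0) stop("empty threshold grid")
  dice <- vapply(thresholdGrid, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    2 * tp / (P + sum(pred))
  }, numeric(1))
  dice[is.nan(dice)] <- 0   # empty prediction set
  dmax <- max(dice)
  list(diceMax = dmax,
       threshold = min(thresholdGrid[dice >= dmax - 1e-15]))
}

#' Folds enrichment of precision
#'
#' AUPRC divided by the proportion of positive pixels: the precision gain
#' over a random locator (a random ranking has average precision close to
#' the prevalence).
#'
#' @param auprc average precision of the map.
#' @param positiveFraction proportion of positive cells (> 0).
#' @return folds enrichment (>= 0).
#' @export
foldsEnrichment <- function(auprc, positiveFraction) {
  if (positiveFraction <= 0)
    stop("folds enrichment undefined for zero positive fraction")
  auprc / positiveFraction
}

#' Image eligibility for cross-validated evaluation
#'
#' An image is eligible when at least `minNegativeFraction` of its grid
#' cells are non-tumor (the >= 10 percent non-tumor rule, inclusive) and at
#' least one cell is tumor (the metrics are undefined otherwise).
#'
#' @param gridMask a [GridMask-class].
#' @param minNegativeFraction minimum non-tumor cell fraction (default 0.10).
#' @return logical flag.
#' @export
imageEligible <- function(gridMask, minNegativeFraction = 0.10) {
  stopifnot(is(gridMask, "GridMask"))
  lab <- gridMask@labels
  negFrac <- sum(lab == 0) / length(lab)
  negFrac >= minNegativeFraction - 1e-12 && any(lab == 1)
}

#' Score a probability map against a ground-truth mask
#'
#' Reshapes the mask to the map's prediction grid, flattens cells to
#' score/label sequences, and computes average precision, AUROC, the
#' highest Dice coefficient, folds enrichment of precision, the grid-level
#' positive fraction, and the eligibility flag. `mode = "pixel"` instead
#' upsamples the map to pixel resolution and scores against the raw mask.
#'
#' @param map a [ProbabilityMap-class].
#' @param mask the paired [TumorMask-class] (or logical matrix).
#' @param cellPositiveThreshold mask-reshaping majority threshold.
#' @param minNegativeFraction eligibility rule (default 0.10).
#' @param mode `"grid"` (default; mask reshaped down to the grid) or
#'   `"pixel"` (map upsampled to pixels).
#' @param thresholdGrid passed to [bestDice()].
#' @return an [ImageEvalResult-class].
#' @export
evaluateImage <- function(map, mask, cellPositiveThreshold = 0.5,
                          minNegativeFraction = 0.10,
                          mode = c("grid", "pixel"), thresholdGrid = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(map, "ProbabilityMap"))
  g <- map@grid
  gm <- reshapeMaskToGrid(mask, g, cellPositiveThreshold)
  if (mode == "grid") {
    scores <- as.vector(map@values)
    labels <- as.vector(gm@labels)
  } else {
    rowCell <- pmin(g@nRows, (seq_len(g@imageHeight) - 1L) %/% g@stride + 1L)
    colCell <- pmin(g@nCols, (seq_len(g@imageWidth) - 1L) %/% g@stride + 1L)
    scores <- as.vector(map@values[rowCell, colCell, drop = FALSE])
    m <- if (is(mask, "TumorMask")) mask@mask else mask
    labels <- as.vector(m * 1)
  }
  auprc <- averagePrecision(scores, labels)
  auroc <- aurocScore(scores, labels)
  dice <- bestDice(scores, labels, thresholdGrid)
  posFrac <- mean(labels)
  new("ImageEvalResult",
      auprc = auprc, auroc = auroc, diceMax = dice$diceMax,
      diceThreshold = dice$threshold,
      fep = foldsEnrichment(auprc, posFrac),
      positiveFraction = posFrac,
      eligible = imageEligible(gm, minNegativeFraction))
}

#' Evaluate a model over a cohort's annotated images
#'
#' Runs sliding-window inference and [evaluateImage()] on every annotated
#' image of the target class in the chosen split. Images whose reshaped
#' grid mask has no positive cell are reported with NA metrics and
#' `eligible = FALSE`.
#'
#' @inheritParams buildTrainingSet
#' @param model a trained [TileClassifier-class].
#' @param stride inference stride (default half the tile).
#' @param aggregation passed to [slidingWindowProbabilityMap()].
#' @param cellPositiveThreshold,minNegativeFraction passed to
#'   [evaluateImage()].
#' @return data.frame, one row per image: image_id, patient_id,
#'   magnification, the four metrics, positive_fraction, eligible.
#' @export
evaluateCohort <- function(model, cohort, targetClass = "BCC",
                           magnification = "100x", split = "validation",
                           tileSize = 224L, stride = tileSize %/% 2L,
                           aggregation = "mean",
                           cellPositiveThreshold = 0.5,
                           minNegativeFraction = 0.10) {
  info <- cohort@info
  if (!is.null(split)) info <- info[info$split == split, , drop = FALSE]
  ids <- info$image_id[info$diagnosis == targetClass &
                         info$magnification == magnification &
                         info$image_id %in% names(cohort@masks)]
  if (length(ids) == 0)
    stop("no annotated ", targetClass, " images to evaluate")
  rows <- lapply(ids, function(id) {
    map <- slidingWindowProbabilityMap(model, cohort@images[[id]],
                                       tileSize, stride,
                                       aggregation = aggregation)
    gm <- reshapeMaskToGrid(cohort@masks[[id]], map@grid,
                            cellPositiveThreshold)
    base <- data.frame(image_id = id,
                       patient_id = info$patient_id[info$image_id == id],
                       magnification = magnification,
                       stringsAsFactors = FALSE)
    if (!any(gm@labels == 1)) {
      return(cbind(base, data.frame(auprc = NA_real_, auroc = NA_real_,
                                    dice_max = NA_real_,
                                    dice_threshold = NA_real_,
                                    fep = NA_real_, positive_fraction = 0,
                                    eligible = FALSE)))
    }
    res <- evaluateImage(map, cohort@masks[[id]], cellPositiveThreshold,
                         minNegativeFraction)
    cbind(base, as.data.frame(res))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
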