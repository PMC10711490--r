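test_that("mask reshaping matches a per-cell pixel-count oracle", {
  set.seed(41)
  m <- matrix(runif(300 * 260) < 0.4, 300, 260)
  g <- gridSpec(300, 260, tileSize = 128L, stride = 64L)
  gm <- reshapeMaskToGrid(m, g, cellPositiveThreshold = 0.5)
  rb <- c(seq(0, 299, by = 64), 300)
  cb <- c(seq(0, 259, by = 64), 260)
  for (r in seq_len(g@nRows)) for (cc in seq_len(g@nCols)) {
    block <- m[(rb[r] + 1):rb[r + 1], (cb[cc] + 1):cb[cc + 1]]
    expect_equal(cellFractions(gm)[r, cc], mean(block))
    expect_identical(cellLabels(gm)[r, cc], as.numeric(mean(block) >= 0.5))
  }
  # trivial masks
  allOne <- reshapeMaskToGrid(matrix(TRUE, 300, 260), g)
  expect_true(all(cellLabels(allOne) == 1))
  expect_true(all(cellFractions(allOne) == 1))
  # left-half mask with stride dividing the width labels exactly half
  half <- matrix(rep(c(TRUE, FALSE), each = 256 * 128), 256, 256)
  gh <- gridSpec(256, 256, 128L, 64L)
  gmh <- reshapeMaskToGrid(half, gh)
  expect_true(all(cellLabels(gmh)[, 1:2] == 1))
  expect_true(all(cellLabels(gmh)[, 3:4] == 0))
  expect_error(reshapeMaskToGrid(m, gh), "dimensions")
})

test_that("average precision follows the step-wise definition with tie groups", {
  expect_identical(averagePrecision(c(0.9, 0.1), c(1, 0)), 1)
  expect_identical(averagePrecision(c(0.2, 0.7, 0.5), c(1, 1, 1)), 1)
  expect_equal(averagePrecision(c(0.9, 0.8, 0.7), c(0, 1, 1)), 7 / 12)
  # all scores tied: single operating point at prevalence precision
  expect_equal(averagePrecision(rep(0.5, 4), c(1, 0, 1, 0)), 0.5)
  expect_error(averagePrecision(c(0.1, 0.2), c(0, 0)), "positive")
  expect_error(averagePrecision(c(0.1, NA), c(0, 1)), "NA")
})

test_that("AUROC is the tie-aware rank statistic", {
  expect_identical(aurocScore(c(3, 2, 1), c(1, 1, 0)), 1)
  expect_identical(aurocScore(rep(1, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(aurocScore(c(0.9, 0.4, 0.6), c(1, 1, 0)), 0.5)
  expect_equal(aurocScore(c(0.9, 0.6, 0.6), c(1, 1, 0)), 0.75)
  expect_error(aurocScore(1:3, c(1, 1, 1)), "both classes")
})

test_that("best Dice scans all distinct thresholds and reports the smallest argmax", {
  # binary scores equal to labels: perfect Dice at threshold 1
  b <- bestDice(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_identical(b$diceMax, 1)
  # scores all zero with positives present: best is predict-everything
  y <- c(1, 1, 0, 0, 0)
  b0 <- bestDice(rep(0, 5), y)
  expect_equal(b0$diceMax, 2 * 2 / (2 + 5))
  expect_identical(b0$threshold, 0)
  expect_error(bestDice(c(1, 0), c(1, 0), thresholdGrid = numeric(0)),
               "empty threshold grid")
  expect_error(bestDice(c(1, 0), c(0, 0)), "positive")
})

test_that("folds enrichment is the precision gain over a random locator", {
  expect_identical(foldsEnrichment(0.5, 0.25), 2)
  expect_identical(foldsEnrichment(1, 0.5), 2)
  expect_error(foldsEnrichment(0.5, 0), "zero positive")
  # random scores at large n: AP tends to prevalence, so FEP tends to 1
  set.seed(91)
  n <- 1e5
  scores <- runif(n)
  labels <- rbinom(n, 1, 0.2)
  fep <- foldsEnrichment(averagePrecision(scores, labels), mean(labels))
  expect_equal(fep, 1, tolerance = 0.03)
})

test_that("eligibility uses the inclusive 10 percent non-tumor rule", {
  g <- gridSpec(200, 200, 40L, 20L)   # 10 x 10 cells
  mk <- function(nPos) {
    lab <- matrix(0, 10, 10)
    if (nPos > 0) lab[seq_len(nPos)] <- 1
    new("GridMask", grid = g, labels = lab,
        cellFractions = lab)
  }
  expect_true(imageEligible(mk(90)))    # exactly 10% negative: eligible
  expect_false(imageEligible(mk(95)))   # 5% negative
  expect_false(imageEligible(mk(0)))    # no positive cell
  expect_true(imageEligible(mk(50)))
})

test_that("evaluate_image satisfies the perfect-predictor and definitional identities", {
  sp <- generateSpecimen(tinyParams(size = 256L, seed = 71L,
                                    blobRadiusRange = c(60, 90)), "p")
  g <- gridSpec(256, 256, 64L, 32L)
  gm <- reshapeMaskToGrid(sp$mask, g)
  counts <- matrix(1L, g@nRows, g@nCols)
  oracleMap <- new("ProbabilityMap", grid = g, values = cellLabels(gm),
                   counts = counts, modelMagnification = "100x",
                   imageMagnification = "100x")
  res <- evaluateImage(oracleMap, sp$mask)
  expect_identical(res@auprc, 1)
  expect_identical(res@auroc, 1)
  expect_identical(res@diceMax, 1)
  expect_identical(res@fep, 1 / res@positiveFraction)

  # noisy map: definitional identity FEP x positive fraction = AUPRC
  set.seed(5)
  noisy <- new("ProbabilityMap", grid = g,
               values = matrix(runif(g@nRows * g@nCols), g@nRows),
               counts = counts, modelMagnification = "100x",
               imageMagnification = "100x")
  rn <- evaluateImage(noisy, sp$mask)
  expect_lt(abs(rn@fep * rn@positiveFraction - rn@auprc), 1e-12)

  # label-independent map on a large grid: AUROC near one half
  gl <- gridSpec(1600, 1600, 64L, 32L)
  bigMask <- matrix(rep(c(TRUE, FALSE), each = 1600 * 800), 1600, 1600)
  bigMap <- new("ProbabilityMap", grid = gl,
                values = matrix(runif(50 * 50), 50),
                counts = matrix(1L, 50, 50),
                modelMagnification = "100x", imageMagnification = "100x")
  rb <- evaluateImage(bigMap, bigMask)
  expect_equal(rb@auroc, 0.5, tolerance = 0.05)

  # pixel mode scores against the raw mask at pixel resolution
  rp <- evaluateImage(oracleMap, sp$mask, mode = "pixel")
  expect_equal(rp@positiveFraction, positiveFraction(sp$mask))
})

test_that("metric invariances: duplication and AUROC complement symmetry", {
  set.seed(17)
  for (k in 1:20) {
    inst <- randomScoredInstance(sample(10:40, 1), tie = k %% 2 == 0)
    s <- inst$s; y <- inst$y
    expect_equal(averagePrecision(c(s, s), c(y, y)), averagePrecision(s, y),
                 tolerance = 1e-12)
    expect_equal(aurocScore(c(s, s), c(y, y)), aurocScore(s, y),
                 tolerance = 1e-12)
    expect_equal(bestDice(c(s, s), c(y, y))$diceMax, bestDice(s, y)$diceMax,
                 tolerance = 1e-12)
    expect_equal(aurocScore(-s, 1 - y), aurocScore(s, y), tolerance = 1e-12)
  }
})
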