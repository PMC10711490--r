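test_that("architecture contract: three dense layers, softmax outputs, seeded builds", {
  expect_error(new("ArchitectureSpec", backboneId = "small",
                   denseWidths = c(64L, 16L), nClasses = 2L,
                   pretrained = FALSE) |> validObject(),
               "three")
  expect_error(buildModel(architectureSpec("resnet50"), 1L, 64L),
               "unknown backbone")
  expect_error(buildModel(architectureSpec(pretrained = TRUE), 1L, 64L),
               "backboneWeights")
  expect_error(buildModel(architectureSpec(), 1L, inputSize = 100L),
               "divisible")

  m <- buildModel(architectureSpec(), seed = 4L, inputSize = 64L)
  px <- generateSpecimen(tinyParams(size = 64L, seed = 6L,
                                    blobRadiusRange = c(10, 20)), "p")$image
  tile <- pixelData(px)
  P <- predictTiles(m, list(tile, tile))
  expect_identical(dim(P), c(2L, 2L))
  expect_identical(colnames(P), c("positive", "control"))
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  expect_true(all(P >= 0))

  # same seed -> identical model and predictions; different seed differs
  m2 <- buildModel(architectureSpec(), seed = 4L, inputSize = 64L)
  expect_identical(predictTiles(m2, list(tile)), P[1, , drop = FALSE])
  m3 <- buildModel(architectureSpec(), seed = 5L, inputSize = 64L)
  expect_false(identical(predictTiles(m3, list(tile)),
                         P[1, , drop = FALSE]))

  # deterministic inference, permutation equivariance, size checking
  t2 <- tile[1:32, 1:32, , drop = FALSE]
  expect_error(predictTiles(m, list(t2)), "does not match model input")
  tiles <- lapply(1:5, function(k) {
    s <- generateSpecimen(tinyParams(size = 64L, seed = 60L + k,
                                     blobRadiusRange = c(10, 20)), "p")
    pixelData(s$image)
  })
  Pa <- predictTiles(m, tiles)
  expect_identical(predictTiles(m, tiles), Pa)
  perm <- c(3, 1, 5, 2, 4)
  expect_identical(predictTiles(m, tiles[perm]), Pa[perm, ])
})

test_that("tile augmentation is label-preserving, bounded and involutive", {
  px <- pixelData(generateSpecimen(tinyParams(size = 64L, seed = 1L,
                                              blobRadiusRange = c(10, 20)),
                                   "p")$image)
  # identity spec
  expect_identical(augmentTile(px, NULL), px)
  expect_identical(augmentTile(px, list(flip = FALSE, rotate = FALSE),
                               seed = 3L), px)
  # involutions and group structure
  expect_identical(applyTileTransform(applyTileTransform(px, "hflip"),
                                      "hflip"), px)
  expect_identical(applyTileTransform(applyTileTransform(px, "vflip"),
                                      "vflip"), px)
  expect_identical(applyTileTransform(applyTileTransform(px, "rot180"),
                                      "rot180"), px)
  r <- px
  for (k in 1:4) r <- applyTileTransform(r, "rot90")
  expect_identical(r, px)
  # rot90 then rot270 is the identity
  expect_identical(
    applyTileTransform(applyTileTransform(px, "rot90"), "rot270"), px)

  # deterministic given seed; jitter bounded by the configured delta
  spec <- list(flip = FALSE, rotate = FALSE, brightnessDelta = 0.05)
  a1 <- augmentTile(px, spec, seed = 7L)
  expect_identical(augmentTile(px, spec, seed = 7L), a1)
  expect_identical(dim(a1), dim(px))
  expect_lte(max(abs(a1 - px)), ceiling(0.05 * 255))
  expect_true(all(a1 >= 0L & a1 <= 255L))
})

test_that("training respects the epoch cap, early stopping and grouped split", {
  expect_error(trainConfig(maxEpochs = 201L), "\\[1, 200\\]")
  expect_error(trainConfig(validationFraction = 0), "\\(0, 1\\)")

  co <- tinyCohort(nPatients = 8L, seed = 31L)
  ts <- buildTrainingSet(co, "BCC", "100x", tileSize = 64L, stride = 64L)
  model <- buildModel(architectureSpec(), seed = 1L, inputSize = 64L)
  cfg <- quickTrainConfig(seed = 5L)
  fit <- trainClassifier(model, ts, cfg)
  h <- fit$history

  expect_lte(nrow(h), cfg$maxEpochs)
  expect_lte(nrow(h), 200L)
  expect_identical(h$epoch, seq_len(nrow(h)))
  # restored checkpoint reproduces the minimum validation loss recorded
  # after the burn-in window
  burn <- attr(h, "burnIn")
  expect_identical(attr(h, "restoredValLoss"),
                   min(h$valLoss[h$epoch > burn]))
  expect_identical(h$valLoss[attr(h, "bestEpoch")],
                   min(h$valLoss[h$epoch > burn]))

  # internal split has zero patient overlap (grouped split applies here:
  # several patients contribute positive tiles)
  tl <- tileInfo(ts)
  valPat <- unique(tl$patient_id[attr(h, "validationTiles")])
  trPat <- unique(tl$patient_id[-attr(h, "validationTiles")])
  expect_length(intersect(valPat, trPat), 0L)

  # reproducibility: same config -> identical trained predictions
  fit2 <- trainClassifier(model, ts, cfg)
  probe <- lapply(1:3, function(i) tilePixels(ts, i))
  expect_identical(predictTiles(fit$model, probe),
                   predictTiles(fit2$model, probe))

  # error paths
  single <- ts
  single@tiles$label <- "positive"
  expect_error(trainClassifier(model, single, cfg), "two classes")
  wrongSize <- buildModel(architectureSpec(), 1L, inputSize = 96L)
  expect_error(trainClassifier(wrongSize, ts, cfg), "does not match")
})

test_that("training separates a clearly separable tile set", {
  co <- tinyCohort(nPatients = 8L, seed = 31L)
  ts <- buildTrainingSet(co, "BCC", "100x", tileSize = 64L, stride = 64L)
  model <- buildModel(architectureSpec(), seed = 1L, inputSize = 64L)
  fit <- trainClassifier(model, ts, quickTrainConfig(seed = 5L))
  # held-out check: tiles of validation-split BCC images, labeled from masks
  hold <- buildTrainingSet(co, "BCC", "100x", tileSize = 64L, stride = 64L,
                           split = "validation",
                           includeExtraControls = TRUE)
  P <- predictTiles(fit$model, hold)
  y <- tileInfo(hold)$label == "positive"
  acc <- mean((P[, "positive"] >= 0.5) == y)
  expect_gte(acc, 0.80)
  expect_gt(aurocScore(P[, "positive"], as.integer(y)), 0.9)
})
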