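test_that("tile grids are edge-snapped, row-major and deterministic", {
  expect_identical(tileOrigins(448, 224, 224), c(0L, 224L))
  expect_identical(tileOrigins(448, 224, 112), c(0L, 112L, 224L))
  expect_identical(tileOrigins(160, 64, 64), c(0L, 64L, 96L))
  expect_error(tileOrigins(100, 224, 112), "exceeds")
  expect_error(tileOrigins(300, 224, 0), "stride")

  img <- generateSpecimen(tinyParams(size = 448L, seed = 2L), "p")$image
  t1 <- splitIntoTiles(img, 224L, 224L)
  expect_identical(nrow(t1), 4L)
  expect_identical(t1$row, c(0L, 0L, 224L, 224L))
  expect_identical(t1$col, c(0L, 224L, 0L, 224L))
  t2 <- splitIntoTiles(img, 224L, 112L)
  expect_identical(nrow(t2), 9L)

  # 1600 x 1200 at tile 224 / stride 112 vs independent origin enumeration
  big <- new("SpecimenImage",
             pixels = array(0L, c(1200L, 1600L, 3L)), patientId = "p",
             imageId = "big", magnification = "40x", diagnosis = "BCC")
  tl <- splitIntoTiles(big, 224L, 112L)
  enumerate <- function(dim) {
    o <- c(); r <- 0
    while (r + 224 <= dim) { o <- c(o, r); r <- r + 112 }
    if (o[length(o)] != dim - 224) o <- c(o, dim - 224)
    o
  }
  expect_identical(nrow(tl), length(enumerate(1200)) * length(enumerate(1600)))
  expect_setequal(unique(tl$row), enumerate(1200))
  expect_setequal(unique(tl$col), enumerate(1600))

  # coverage: the union of tile windows covers every pixel exactly when
  # stride <= tile size (counted by brute-force accumulation)
  cover <- matrix(0L, 160, 160)
  timg <- generateSpecimen(tinyParams(seed = 3L), "p")$image
  tt <- splitIntoTiles(timg, 64L, 48L)
  for (i in seq_len(nrow(tt)))
    cover[(tt$row[i] + 1):(tt$row[i] + 64),
          (tt$col[i] + 1):(tt$col[i] + 64)] <-
      cover[(tt$row[i] + 1):(tt$row[i] + 64),
            (tt$col[i] + 1):(tt$col[i] + 64)] + 1L
  expect_true(all(cover >= 1L))
})

test_that("tile tumor fractions match a pixel-count oracle", {
  set.seed(8)
  m <- matrix(runif(300 * 280) < 0.3, 300, 280)
  expect_identical(tileTumorFraction(m, 10, 20, 64),
                   sum(m[11:74, 21:84]) / 64^2)
  expect_identical(tileTumorFraction(matrix(TRUE, 64, 64), 0, 0, 64), 1)
  expect_identical(tileTumorFraction(matrix(FALSE, 64, 64), 0, 0, 64), 0)
  expect_error(tileTumorFraction(m, 280, 0, 64), "out of mask bounds")
})

test_that("tile labeling uses the inclusive 10 percent boundary", {
  expect_identical(labelTile(0.10), "positive")
  expect_identical(labelTile(0.0999), "control")
  expect_identical(labelTile(1.0), "positive")
  expect_identical(labelTile(0), "control")
  expect_identical(labelTile(c(0.05, 0.5)), c("control", "positive"))
  expect_error(labelTile(-0.1), "\\[0, 1\\]")
  expect_error(labelTile(1.2), "\\[0, 1\\]")
  # threshold is a parameter
  expect_identical(labelTile(0.3, positiveThreshold = 0.5), "control")
})

test_that("training sets respect labels, provenance and extra controls", {
  co <- tinyCohort(nPatients = 8L, seed = 31L)
  ts <- buildTrainingSet(co, "BCC", "100x", tileSize = 64L, stride = 64L)
  tl <- tileInfo(ts)
  info <- imageInfo(co)

  # every positive tile's recomputed tumor fraction is >= 0.10
  pos <- tl[tl$label == "positive", ]
  refrac <- vapply(seq_len(nrow(pos)), function(i)
    tileTumorFraction(cohortMasks(co)[[pos$image_id[i]]],
                      pos$row[i], pos$col[i], pos$size[i]), numeric(1))
  expect_true(all(refrac >= 0.10))
  expect_equal(refrac, pos$tumor_fraction)

  # relabeling from stored fractions reproduces stored labels
  known <- !is.na(tl$tumor_fraction)
  expect_identical(labelTile(tl$tumor_fraction[known]), tl$label[known])

  # provenance: tile patient ids match their source images
  expect_identical(tl$patient_id,
                   info$patient_id[match(tl$image_id, info$image_id)])

  # extra controls: all tiles of non-target images, labeled control, NA frac
  expect_true(all(tl$label[is.na(tl$tumor_fraction)] == "control"))

  # without extra controls, tiles come solely from target-class images
  ts0 <- buildTrainingSet(co, "BCC", "100x", tileSize = 64L, stride = 64L,
                          includeExtraControls = FALSE)
  dx <- info$diagnosis[match(tileInfo(ts0)$image_id, info$image_id)]
  expect_true(all(dx == "BCC"))
  expect_true(all(!is.na(tileInfo(ts0)$tumor_fraction)))

  # each extra 160 x 160 control image at stride 64 contributes 9 tiles
  nOther <- sum(info$diagnosis != "BCC" & info$split == "development" &
                  info$magnification == "100x")
  expect_identical(sum(is.na(tl$tumor_fraction)), nOther * 9L)

  expect_error(buildTrainingSet(co, "BCC", "40x", 64L), "no annotated")
})

test_that("tile pixel windows are read from the source image", {
  co <- tinyCohort(nPatients = 4L, seed = 13L)
  ts <- buildTrainingSet(co, "BCC", "100x", tileSize = 64L, stride = 64L)
  tl <- tileInfo(ts)
  i <- which(tl$label == "positive")[1]
  px <- tilePixels(ts, i)
  src <- pixelData(cohortImages(co)[[tl$image_id[i]]])
  expect_identical(px, src[(tl$row[i] + 1):(tl$row[i] + 64),
                           (tl$col[i] + 1):(tl$col[i] + 64), , drop = FALSE])
})
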