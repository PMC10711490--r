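test_that("specimen generation is deterministic and geometry-exact", {
  p <- synthesisParams(seed = 42L)
  a <- generateSpecimen(p, "patA", "BCC")
  b <- generateSpecimen(p, "patA", "BCC")
  expect_identical(pixelData(a$image), pixelData(b$image))
  expect_identical(maskData(a$mask), maskData(b$mask))
  expect_s4_class(a$image, "SpecimenImage")
  expect_true(validObject(a$image))

  # no blobs -> empty mask
  z <- generateSpecimen(synthesisParams(nTumorBlobs = 0L, seed = 3L), "patB")
  expect_identical(positiveFraction(z$mask), 0)

  # one circle of radius 100 centered in 448 x 448: mask equals the
  # analytic pixel-count oracle and positive fraction follows
  sc <- generateSpecimen(synthesisParams(nTumorBlobs = 1L, seed = 5L),
                         "patC", "BCC",
                         blobCenters = c(223.5, 223.5),
                         blobAxes = c(100, 100))
  ii <- 0:447
  oracle <- outer((ii - 223.5)^2, (ii - 223.5)^2, "+") <= 100^2
  expect_identical(unname(maskData(sc$mask)), unname(oracle))
  expect_equal(positiveFraction(sc$mask), sum(oracle) / 448^2)

  # different seeds give different images
  c2 <- generateSpecimen(synthesisParams(seed = 43L), "patA", "BCC")
  expect_false(identical(pixelData(a$image), pixelData(c2$image)))
})

test_that("generator rejects invalid parameters", {
  expect_error(synthesisParams(imageWidth = 0), "positive")
  expect_error(synthesisParams(separability = 1.5), "separability")
  expect_error(synthesisParams(blobRadiusRange = c(50, 10)), "increasing")
  # blob radius beyond the half-diagonal
  expect_error(synthesisParams(imageWidth = 100, imageHeight = 100,
                               blobRadiusRange = c(10, 400)),
               "half-diagonal")
  expect_error(generateSpecimen(tinyParams(), "p", "unknownDx"),
               "no tumor texture")
})

test_that("control images carry distractor kinds and no tumor texture", {
  p <- synthesisParams(seed = 11L)
  for (kind in c("plain", "other_tumor", "follicle_rings",
                 "inflammation_speckle")) {
    img <- generateControlImage(kind, p, "patD")
    expect_identical(dim(pixelData(img)), c(448L, 448L, 3L))
    expect_identical(diagnosis(img), kind)
  }
  expect_error(generateControlImage("bubbles", p, "patD"), "unknown control")

  # plain background matches the background distribution: per-channel means
  # of two independent plain images agree within sampling tolerance
  a <- pixelData(generateControlImage("plain", synthesisParams(seed = 1L), "x"))
  b <- pixelData(generateControlImage("plain", synthesisParams(seed = 2L), "y"))
  for (ch in 1:3)
    expect_lt(abs(mean(a[, , ch]) - mean(b[, , ch])), 3)
})

test_that("separability 0 renders tumor regions indistinguishable from background", {
  # with separability 0 no nuclei are drawn and colors match the background
  # process, so tumor-region statistics equal background statistics
  p <- synthesisParams(separability = 0, seed = 9L)
  sp <- generateSpecimen(p, "p0", "BCC")
  m <- maskData(sp$mask)
  px <- pixelData(sp$image)
  for (ch in 1:3) {
    inside <- mean(px[, , ch][m])
    outside <- mean(px[, , ch][!m])
    expect_lt(abs(inside - outside), 4)
  }
})

test_that("tile separability of the textures is monotone in the parameter", {
  # fixed simple classifier: threshold on mean intensity at the midpoint of
  # the class means; accuracy should not decrease with separability
  tileAcc <- function(sep, n = 250) {
    size <- 96L
    dark <- function(img) mean(pixelData(img))
    vals <- vapply(seq_len(n), function(k) {
      prm <- synthesisParams(imageWidth = size, imageHeight = size,
                             nTumorBlobs = 1L, blobRadiusRange = c(60, 65),
                             separability = sep, seed = 5000L + k)
      if (k %% 2 == 0) {
        sp <- generateSpecimen(prm, "p", "BCC",
                               blobCenters = c(47.5, 47.5),
                               blobAxes = c(67, 67))
        c(dark(sp$image), 1)
      } else {
        c(dark(generateControlImage("plain", prm, "p")), 0)
      }
    }, numeric(2))
    x <- vals[1, ]; y <- vals[2, ]
    cut <- (mean(x[y == 1]) + mean(x[y == 0])) / 2
    mean((x < cut) == (y == 1))
  }
  accs <- vapply(c(0.2, 0.5, 0.9), tileAcc, numeric(1))
  expect_true(all(diff(accs) > -0.03))   # non-decreasing within noise
  expect_gt(accs[3], accs[1])
})

test_that("cohorts have the declared structure", {
  co <- tinyCohort(nPatients = 10L, imagesPerPatient = 4L, seed = 21L)
  info <- imageInfo(co)
  expect_identical(nrow(info), 40L)
  expect_identical(length(unique(info$patient_id)), 10L)
  expect_false(anyDuplicated(info$image_id) > 0)
  # patients assigned whole to one split
  expect_true(all(tapply(info$split, info$patient_id,
                         function(s) length(unique(s))) == 1))
  # masks exactly for tumor-class images
  tumorIds <- info$image_id[info$diagnosis %in% c("BCC", "SCC")]
  expect_setequal(names(cohortMasks(co)), tumorIds)
  expect_true(validObject(co))
  # deterministic
  co2 <- tinyCohort(nPatients = 10L, imagesPerPatient = 4L, seed = 21L)
  expect_identical(imageInfo(co2), info)
  expect_identical(pixelData(cohortImages(co2)[[1]]),
                   pixelData(cohortImages(co)[[1]]))
  expect_error(generateCohort(3, 2, classMix = c(BCC = 0.5, SCC = 0.2)),
               "sum to 1")
})

test_that("patient-level class mix follows the binomial sampling model", {
  # diagnosis draw only (images not rendered): use 1-image patients at a
  # small size to keep this cheap, n large enough for a 3-SE check
  co <- generateCohort(600L, 1L, classMix = c(BCC = 0.85, SCC = 0.15),
                       params = tinyParams(size = 64L,
                                           blobRadiusRange = c(15, 30)),
                       seed = 99L)
  info <- imageInfo(co)
  share <- mean(tapply(info$diagnosis, info$patient_id,
                       function(d) d[1]) == "BCC")
  se <- sqrt(0.85 * 0.15 / 600)
  expect_lt(abs(share - 0.85), 3 * se)
})
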