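test_that("LOOCV builds one leak-free fold per eligible patient", {
  co <- tinyCohort(nPatients = 10L, seed = 51L)
  folds <- patientLoocvFolds(co, targetClass = "BCC",
                             magnification = "100x",
                             tileSize = 64L, stride = 32L)
  info <- imageInfo(co)
  annotated <- info[info$image_id %in% names(cohortMasks(co)) &
                      info$diagnosis == "BCC", ]
  # folds are per-patient, sorted, with zero train/test overlap
  testPats <- vapply(folds, function(f) f$testPatient, character(1))
  expect_identical(testPats, sort(unique(testPats)))
  for (f in folds) {
    expect_length(intersect(f$testPatient, f$trainPatients), 0L)
    expect_true(all(f$testImages %in%
                      annotated$image_id[annotated$patient_id ==
                                           f$testPatient]))
  }
  # patients without annotated images never appear anywhere
  unannotated <- setdiff(unique(info$patient_id),
                         unique(annotated$patient_id))
  everywhere <- c(testPats, unlist(lapply(folds, `[[`, "trainPatients")))
  expect_length(intersect(unannotated, everywhere), 0L)
  expect_error(patientLoocvFolds(subsetCohort(co, testPats[1]),
                                 targetClass = "BCC"),
               "at least 2 eligible")
})

test_that("bootstrap CIs are seeded, degenerate-safe and support BCa", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  a <- bootstrapCi(x, nIterations = 2000L, seed = 7L)
  b <- bootstrapCi(x, nIterations = 2000L, seed = 7L)
  expect_identical(c(a@ciLow, a@ciHigh), c(b@ciLow, b@ciHigh))
  expect_lte(a@ciLow, a@pointEstimate)
  expect_gte(a@ciHigh, a@pointEstimate)
  expect_identical(a@nIterations, 2000L)

  # constant data collapse to a point interval
  k <- bootstrapCi(rep(2.5, 8), nIterations = 500L, seed = 1L)
  expect_identical(c(k@ciLow, k@ciHigh), c(2.5, 2.5))

  bca <- bootstrapCi(x, nIterations = 2000L, seed = 7L, method = "bca")
  expect_lte(bca@ciLow, bca@ciHigh)
  expect_error(bootstrapCi(numeric(0)), "empty")
  expect_error(bootstrapCi(1), "at least 2")

  # default iteration count is the study's 10,000
  expect_identical(formals(bootstrapCi)$nIterations, 10000L)
})

test_that("paired Wilcoxon drops zeros, reports the median difference, flags at 0.01", {
  set.seed(61)
  a <- runif(20)
  # positive shift on every pair: strong one-directional evidence whose
  # exact p agrees with the brute-force null enumeration
  shift <- runif(20, 0.1, 0.5)
  b <- a - shift
  w <- pairedWilcoxon(a, b)
  expect_lt(w$pValue, 0.01)
  expect_true(w$significant)
  expect_equal(w$medianDifference, median(shift))
  expect_equal(w$pValue, wilcoxExactP(a - b), tolerance = 1e-12)
  # exact branch agrees with the reference implementation in stats
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(w$pValue, ref$p.value, tolerance = 1e-12)
  expect_equal(w$statistic, unname(ref$statistic))

  # swapping negates the median difference, preserves the p-value
  w2 <- pairedWilcoxon(b, a)
  expect_identical(w2$pValue, w$pValue)
  expect_identical(w2$medianDifference, -w$medianDifference)

  # zero differences are dropped; all-zero input is signaled
  expect_error(pairedWilcoxon(a, a), "all paired differences are zero")
  w3 <- suppressWarnings(pairedWilcoxon(a, a - c(rep(0, 3), rep(0.1, 17))))
  expect_identical(w3$nEffective, 17L)
  expect_error(pairedWilcoxon(a, b[-1]), "equal lengths")
})

test_that("Fleiss' kappa on masks matches the direct formula and its boundaries", {
  # identical raters with both categories present agree perfectly
  base <- matrix(FALSE, 100, 150)   # 2 x 3 tiles of 50 px
  base[1:50, 1:50] <- TRUE
  expect_identical(fleissKappaMasks(list(base, base, base)), 1)

  # hand-built 3-rater, 6-tile disagreement pattern vs the direct formula
  lab <- rbind(c(1, 1, 1), c(1, 1, 0), c(0, 0, 0),
               c(1, 0, 0), c(0, 1, 0), c(1, 1, 1))
  mkMask <- function(r) {
    m <- matrix(FALSE, 100, 150)
    tilePos <- list(c(0, 0), c(0, 50), c(0, 100),
                    c(50, 0), c(50, 50), c(50, 100))
    for (i in seq_len(6)) if (lab[i, r] == 1)
      m[(tilePos[[i]][1] + 1):(tilePos[[i]][1] + 50),
        (tilePos[[i]][2] + 1):(tilePos[[i]][2] + 50)] <- TRUE
    m
  }
  masks <- lapply(1:3, mkMask)
  counts <- cbind(tumor = rowSums(lab), nontumor = 3 - rowSums(lab))
  expect_equal(fleissKappaMasks(masks), fleissOracle(counts),
               tolerance = 1e-12)

  # >= 5 percent boundary is inclusive: exactly 125 of 2500 pixels
  m1 <- matrix(FALSE, 100, 100); m1[1:5, 1:25] <- TRUE    # tile 1: exactly 5%
  m2 <- matrix(FALSE, 100, 100); m2[1:5, 1:25] <- TRUE
  m2[51:100, 51:100] <- TRUE                              # second category too
  # both raters label tile 1 tumor (inclusive) -> agreement on it
  k <- fleissKappaMasks(list(m1, m1))
  expect_identical(k, 1)

  # geometry disagreement and single-category degeneracy are signaled
  expect_error(fleissKappaMasks(list(m1, matrix(FALSE, 100, 150))),
               "geometry")
  expect_error(fleissKappaMasks(list(matrix(FALSE, 100, 100),
                                     matrix(FALSE, 100, 100))),
               "single category")
  expect_error(fleissKappaMasks(list(m1)), "2 raters")

  # independent random raters: kappa near zero
  set.seed(71)
  rand <- lapply(1:3, function(r) {
    lab <- matrix(runif(100) < 0.5, 10, 10)
    lab[rep(1:10, each = 50), rep(1:10, each = 50)]   # 500 x 500, 100 tiles
  })
  expect_lt(abs(fleissKappaMasks(rand)), 0.15)

  # per-image mode averages per-image kappas
  kp <- fleissKappaMasks(list(list(base, m1), list(base, m1)),
                         mode = "perImage")
  expect_identical(kp, 1)
})
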