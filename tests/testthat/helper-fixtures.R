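# Shared fixtures built in code. Small geometries (128-256 px images,
# 64 px tiles) keep unit tests fast; the reference-scale demo is computed
# once and memoized for the tests that need a trained pipeline.

tinyParams <- function(size = 160L, seed = 1L, ...) {
  args <- list(imageWidth = size, imageHeight = size, nTumorBlobs = 1L,
               blobRadiusRange = c(120, 160) * size / 448, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthesisParams, args)
}

tinyCohort <- function(nPatients = 6L, imagesPerPatient = 3L, seed = 7L,
                       size = 160L, classMix = c(BCC = 0.68, SCC = 0.12,
                                                 AK = 0.10, normal = 0.10)) {
  generateCohort(nPatients, imagesPerPatient, classMix = classMix,
                 params = tinyParams(size = size), seed = seed)
}

.fixtureEnv <- new.env(parent = emptyenv())

demoFixture <- function() {
  if (is.null(.fixtureEnv$demo))
    .fixtureEnv$demo <- suppressMessages(runDemo(seed = 1L))
  .fixtureEnv$demo
}

quickTrainConfig <- function(seed = 5L, maxEpochs = 60L, ...) {
  trainConfig(maxEpochs = maxEpochs, seed = seed, ...)
}
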