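# End-to-end orchestration: simulate (or read) a cohort, tile and train
# (fully or weakly supervised), run sliding-window inference over the
# held-out split, evaluate, and summarize. Every numeric constant of the
# method is collected in runConfig() and logged next to the results.

#' Construct a validated pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one place. The
#' defaults are the package's reference study conditions: a synthetic
#' cohort of 12 patients with 4 images each at 448 x 448 px and
#' separability 0.9, 224 px tiles labeled positive at >= 10 percent tumor
#' area, overlapping inference at stride 112, mask cells labeled at
#' majority (0.5), eligibility at >= 10 percent non-tumor, WSL filtering at
#' t = 0.5, a 200-epoch training cap, 10,000 bootstrap iterations and a
#' 0.01 type I error rate.
#'
#' @param manifest optional path to a cohort manifest CSV; when `NULL` a
#'   synthetic cohort is generated.
#' @param nPatients,imagesPerPatient,imageWidth,imageHeight,separability,classMix,distractorDensity
#'   synthetic cohort conditions (ignored when `manifest` is given).
#' @param targetClass,magnification the model to build.
#' @param method `"fsl"` (fully supervised) or `"wsl"` (two-stage weakly
#'   supervised).
#' @param tileSize,trainStride,inferenceStride tiling geometry in pixels.
#' @param tilePositiveThreshold tumor-area fraction labeling a tile
#'   positive (default 0.10).
#' @param wslThreshold stage-2 confidence filtering threshold t.
#' @param maskCellThreshold majority threshold for mask reshaping.
#' @param eligibilityMinNegative minimum non-tumor cell fraction for an
#'   image to enter evaluation summaries.
#' @param kappaTileSize,kappaTumorThreshold interrater-agreement tile rule
#'   (50 px, 5 percent).
#' @param maxEpochs,earlyStoppingPatience,batchSize,learningRate,validationFraction
#'   training hyperparameters (see [trainConfig()]).
#' @param aggregation sliding-window aggregation rule.
#' @param bootstrapIterations bootstrap resamples for summary CIs.
#' @param alpha type I error rate for paired comparisons.
#' @param seed master seed; all pipeline randomness derives from it.
#' @return validated list of class `"mohsmapRunConfig"`.
#' @export
runConfig <- function(manifest = NULL,
                      nPatients = 12L, imagesPerPatient = 4L,
                      imageWidth = 448L, imageHeight = 448L,
                      separability = 0.9,
                      classMix = c(BCC = 0.68, SCC = 0.12, AK = 0.10,
                                   normal = 0.10),
                      distractorDensity = 1,
                      targetClass = "BCC", magnification = "100x",
                      method = c("fsl", "wsl"),
                      tileSize = 224L, trainStride = tileSize,
                      inferenceStride = tileSize %/% 2L,
                      tilePositiveThreshold = 0.10, wslThreshold = 0.5,
                      maskCellThreshold = 0.5,
                      eligibilityMinNegative = 0.10,
                      kappaTileSize = 50L, kappaTumorThreshold = 0.05,
                      maxEpochs = 200L, earlyStoppingPatience = 10L,
                      batchSize = 32L, learningRate = 1e-3,
                      validationFraction = 0.2,
                      aggregation = "mean",
                      bootstrapIterations = 10000L, alpha = 0.01,
                      seed = 1L) {
  method <- match.arg(method)
  for (nm in c("tilePositiveThreshold", "wslThreshold", "maskCellThreshold",
               "eligibilityMinNegative", "kappaTumorThreshold", "alpha",
               "separability")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop("invalid configuration: ", nm, " = ", v,
           " must be a single value in [0, 1]")
  }
  if (trainStride < 1L || inferenceStride < 1L ||
      inferenceStride > tileSize || trainStride > tileSize)
    stop("invalid configuration: strides must lie in [1, tileSize]")
  if (maxEpochs < 1L || maxEpochs > 200L)
    stop("invalid configuration: maxEpochs must lie in [1, 200]")
  cfg <- list(manifest = manifest, nPatients = as.integer(nPatients),
              imagesPerPatient = as.integer(imagesPerPatient),
              imageWidth = as.integer(imageWidth),
              imageHeight = as.integer(imageHeight),
              separability = separability, classMix = classMix,
              distractorDensity = distractorDensity,
              targetClass = targetClass, magnification = magnification,
              method = method, tileSize = as.integer(tileSize),
              trainStride = as.integer(trainStride),
              inferenceStride = as.integer(inferenceStride),
              tilePositiveThreshold = tilePositiveThreshold,
              wslThreshold = wslThreshold,
              maskCellThreshold = maskCellThreshold,
              eligibilityMinNegative = eligibilityMinNegative,
              kappaTileSize = as.integer(kappaTileSize),
              kappaTumorThreshold = kappaTumorThreshold,
              maxEpochs = as.integer(maxEpochs),
              earlyStoppingPatience = as.integer(earlyStoppingPatience),
              batchSize = as.integer(batchSize),
              learningRate = learningRate,
              validationFraction = validationFraction,
              aggregation = aggregation,
              bootstrapIterations = as.integer(bootstrapIterations),
              alpha = alpha, seed = as.integer(seed))
  class(cfg) <- "mohsmapRunConfig"
  cfg
}

pipelineTrainConfig <- function(config, seedOffset,
                                patience = config$earlyStoppingPatience,
                                learningRate = config$learningRate,
                                weightDecay = 1e-3) {
  trainConfig(maxEpochs = config$maxEpochs,
              earlyStoppingPatience = patience,
              validationFraction = config$validationFraction,
              batchSize = config$batchSize,
              learningRate = learningRate, weightDecay = weightDecay,
              seed = substreamSeed(config$seed, seedOffset))
}

#' Subset a cohort to a set of patients
#'
#' @param cohort a [CohortDataset-class].
#' @param patientIds patients to keep.
#' @return a [CohortDataset-class].
#' @export
subsetCohort <- function(cohort, patientIds) {
  info <- cohort@info[cohort@info$patient_id %in% patientIds, , drop = FALSE]
  ids <- info$image_id
  new("CohortDataset", images = cohort@images[ids],
      masks = cohort@masks[intersect(names(cohort@masks), ids)],
      info = info)
}

#' Run the full pipeline
#'
#' Simulate (or read) a cohort, train a tile classifier on the development
#' split (fully supervised from masks, or weakly supervised in two stages),
#' assemble saliency maps for every annotated target-class validation
#' image, evaluate them against the masks, and summarize the per-image
#' metrics (medians with a bootstrap CI on the median AUPRC).
#'
#' @param config a [runConfig()] object.
#' @param outDir optional output directory; when given, writes
#'   `results.csv` (one row per evaluated image), `summary.json`,
#'   `effective_config.json` and `run_log.txt`.
#' @param cohort optional pre-built [CohortDataset-class] (overrides both
#'   `manifest` and the synthetic generator).
#' @return list with `cohort`, `model`, `results` (data.frame),
#'   `summary` (list), `wslReport` (when `method = "wsl"`), `history`,
#'   `config`.
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL, cohort = NULL) {
  stopifnot(inherits(config, "mohsmapRunConfig"))
  log <- character()
  say <- function(...) {
    line <- sprintf(...)
    message(line)
    log <<- c(log, line)
  }
  if (is.null(cohort)) {
    if (!is.null(config$manifest)) {
      say("reading cohort manifest %s", config$manifest)
      cohort <- readCohortManifest(config$manifest)
    } else {
      say("generating synthetic cohort: %d patients x %d images, %dx%d px, separability %.2f, seed %d",
          config$nPatients, config$imagesPerPatient, config$imageHeight,
          config$imageWidth, config$separability, config$seed)
      params <- synthesisParams(imageWidth = config$imageWidth,
                                imageHeight = config$imageHeight,
                                magnification = config$magnification,
                                separability = config$separability,
                                distractorDensity = config$distractorDensity,
                                blobRadiusRange = c(120, 160) *
                                  min(config$imageWidth,
                                      config$imageHeight) / 448)
      cohort <- generateCohort(config$nPatients, config$imagesPerPatient,
                               classMix = config$classMix, params = params,
                               seed = substreamSeed(config$seed, 1000L))
    }
  }
  wslReport <- NULL
  spec <- architectureSpec()
  if (config$method == "fsl") {
    say("building fully supervised training set (tile %d px, stride %d, positive >= %.2f)",
        config$tileSize, config$trainStride, config$tilePositiveThreshold)
    ts <- buildTrainingSet(cohort, config$targetClass, config$magnification,
                           config$tileSize, config$trainStride,
                           positiveThreshold = config$tilePositiveThreshold)
    say("training on %d tiles (%d positive)", nTiles(ts),
        sum(ts@tiles$label == "positive"))
    model <- buildModel(spec, seed = substreamSeed(config$seed, 2000L),
                        inputSize = config$tileSize)
    fit <- trainClassifier(model, ts, pipelineTrainConfig(config, 2001L))
    model <- fit$model
    history <- fit$history
  } else {
    say("two-stage weakly supervised training (t = %.2f)", config$wslThreshold)
    wcfg <- wslConfig(filteringThreshold = config$wslThreshold,
                      stage1 = pipelineTrainConfig(config, 2101L,
                                                   patience = 30L,
                                                   learningRate = 3e-4,
                                                   weightDecay = 1),
                      stage2 = pipelineTrainConfig(config, 2102L))
    w <- trainWsl(cohort, config$targetClass, config$magnification,
                  config = wcfg, tileSize = config$tileSize,
                  stride = config$trainStride, spec = spec,
                  seed = substreamSeed(config$seed, 2100L))
    model <- w$model
    history <- w$stage2History
    wslReport <- w$report
    say("stage-2 kept %d / %d positive tiles (survival %.2f)",
        w$report$nKeptPositive, w$report$nWeakPositive,
        w$report$survivalRate)
  }
  say("evaluating validation split (inference stride %d, aggregation %s)",
      config$inferenceStride, config$aggregation)
  results <- evaluateCohort(model, cohort, config$targetClass,
                            config$magnification, split = "validation",
                            tileSize = config$tileSize,
                            stride = config$inferenceStride,
                            aggregation = config$aggregation,
                            cellPositiveThreshold = config$maskCellThreshold,
                            minNegativeFraction = config$eligibilityMinNegative)
  elig <- results[results$eligible %in% TRUE, , drop = FALSE]
  summary <- list(nImages = nrow(results), nEligible = nrow(elig))
  if (nrow(elig) >= 2) {
    ci <- bootstrapCi(elig$auprc, nIterations = config$bootstrapIterations,
                      seed = substreamSeed(config$seed, 3000L))
    summary <- c(summary, list(
      medianAuprc = stats::median(elig$auprc),
      medianAuroc = stats::median(elig$auroc),
      medianDice = stats::median(elig$dice_max),
      medianFep = stats::median(elig$fep),
      auprcCiLow = ci@ciLow, auprcCiHigh = ci@ciHigh))
    say("median AUPRC %.3f (95%% CI %.3f-%.3f), AUROC %.3f, Dice %.3f, FEP %.2f over %d eligible images",
        summary$medianAuprc, ci@ciLow, ci@ciHigh, summary$medianAuroc,
        summary$medianDice, summary$medianFep, nrow(elig))
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(outDir, "results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    cfgOut <- config
    class(cfgOut) <- NULL
    cfgOut$classMix <- as.list(cfgOut$classMix)
    jsonlite::write_json(cfgOut, file.path(outDir, "effective_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(log, file.path(outDir, "run_log.txt"))
  }
  list(cohort = cohort, model = model, results = results, summary = summary,
       wslReport = wslReport, history = history, config = config)
}

#' Run the reference synthetic demo
#'
#' [runPipeline()] under the package's reference study conditions (see
#' [runConfig()]), fully supervised.
#'
#' @param seed master seed.
#' @param outDir optional output directory.
#' @param ... overrides forwarded to [runConfig()].
#' @return see [runPipeline()].
#' @export
runDemo <- function(seed = 1L, outDir = NULL, ...) {
  runPipeline(runConfig(seed = seed, ...), outDir = outDir)
}

#' Patient-level LOOCV of the fully supervised pipeline
#'
#' For each fold from [patientLoocvFolds()], trains on all other annotated
#' patients' development data and evaluates the held-out patient's eligible
#' images.
#'
#' @param cohort a [CohortDataset-class].
#' @param config a [runConfig()] object (method `"fsl"`).
#' @return data.frame of per-image results with a `fold_id` column.
#' @export
runLoocv <- function(cohort, config = runConfig()) {
  folds <- patientLoocvFolds(cohort, targetClass = config$targetClass,
                             magnification = config$magnification,
                             tileSize = config$tileSize,
                             stride = config$inferenceStride,
                             cellPositiveThreshold = config$maskCellThreshold,
                             minNegativeFraction = config$eligibilityMinNegative)
  out <- lapply(folds, function(f) {
    train <- subsetCohort(cohort, f$trainPatients)
    ts <- buildTrainingSet(train, config$targetClass, config$magnification,
                           config$tileSize, config$trainStride,
                           positiveThreshold = config$tilePositiveThreshold,
                           split = NULL)
    model <- buildModel(architectureSpec(),
                        seed = substreamSeed(config$seed, 4000L + f$foldId),
                        inputSize = config$tileSize)
    fit <- trainClassifier(model, ts,
                           pipelineTrainConfig(config, 4500L + f$foldId))
    rows <- lapply(f$testImages, function(id) {
      map <- slidingWindowProbabilityMap(fit$model, cohort@images[[id]],
                                         config$tileSize,
                                         config$inferenceStride,
                                         aggregation = config$aggregation)
      res <- evaluateImage(map, cohort@masks[[id]],
                           config$maskCellThreshold,
                           config$eligibilityMinNegative)
      cbind(data.frame(fold_id = f$foldId, image_id = id,
                       patient_id = f$testPatient), as.data.frame(res))
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
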