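# Tile classifier: a convolutional feature extractor topped by exactly
# three dense layers and a final softmax, trained with categorical
# cross-entropy, augmentation, early stopping, and a hard 200-epoch cap.
#
# The bundled "small" backbone is a 4-stage extractor (4x mean-pool stem,
# then three 3x3 convolution + ReLU + 2x2 mean-pool blocks, then global
# mean/sd pooling per channel). Its filters are drawn once from a seeded
# He-scaled Gaussian and kept fixed; only the dense head is trained. Fixed
# random convolutional features are a standard lightweight design for
# texture discrimination and keep training fully deterministic; externally
# trained backbone weights can be plugged in instead.

#' Construct an architecture specification
#'
#' @param backboneId feature extractor id; `"small"` is the bundled
#'   from-scratch extractor. Any other id requires `backboneWeights` at
#'   [buildModel()] time.
#' @param denseWidths exactly three hidden dense-layer widths.
#' @param nClasses number of softmax classes (>= 2).
#' @param pretrained whether externally supplied backbone weights are used.
#' @return an [ArchitectureSpec-class].
#' @export
architectureSpec <- function(backboneId = "small",
                             denseWidths = c(256L, 64L, 16L),
                             nClasses = 2L, pretrained = FALSE) {
  new("ArchitectureSpec", backboneId = backboneId,
      denseWidths = as.integer(denseWidths), nClasses = as.integer(nClasses),
      pretrained = isTRUE(pretrained))
}

#' Construct a training configuration
#'
#' @param maxEpochs epoch cap, at most 200.
#' @param earlyStoppingPatience epochs without validation-loss improvement
#'   before stopping; best weights are restored.
#' @param earlyStoppingBurnIn epochs excluded from best-checkpoint tracking:
#'   on small tile sets the first validation-loss evaluations reflect
#'   initialization transients rather than model quality, and restoring
#'   them would return an effectively untrained model.
#' @param validationFraction fraction of patients (not tiles) held out as
#'   the internal validation split.
#' @param batchSize,learningRate Adam minibatch size and step size.
#' @param weightDecay decoupled L2 penalty applied to the dense weight
#'   matrices each step (AdamW style); keeps logits bounded so softmax
#'   probabilities stay graded instead of saturating.
#' @param augmentation list with elements `flip`, `rotate` (logical),
#'   `brightnessDelta` (max per-channel shift as a fraction of full scale)
#'   and `variants` (number of augmented copies per training tile,
#'   including the identity). `NULL` disables augmentation.
#' @param seed integer seed controlling splits, shuffling and augmentation.
#' @return validated list of class `"mohsmapTrainConfig"`.
#' @export
trainConfig <- function(maxEpochs = 200L, earlyStoppingPatience = 10L,
                        earlyStoppingBurnIn = 10L,
                        validationFraction = 0.2, batchSize = 32L,
                        learningRate = 1e-3, weightDecay = 1e-3,
                        augmentation = list(flip = TRUE, rotate = TRUE,
                                            brightnessDelta = 0.03,
                                            variants = 4L),
                        seed = 1L) {
  maxEpochs <- as.integer(maxEpochs)
  if (maxEpochs < 1L || maxEpochs > 200L)
    stop("maxEpochs must lie in [1, 200]")
  if (validationFraction <= 0 || validationFraction >= 1)
    stop("validationFraction must lie in (0, 1)")
  cfg <- list(maxEpochs = maxEpochs,
              earlyStoppingPatience = as.integer(earlyStoppingPatience),
              earlyStoppingBurnIn = as.integer(min(earlyStoppingBurnIn,
                                                   maxEpochs - 1L)),
              validationFraction = validationFraction,
              batchSize = as.integer(batchSize),
              learningRate = learningRate, weightDecay = weightDecay,
              augmentation = augmentation, seed = as.integer(seed))
  class(cfg) <- "mohsmapTrainConfig"
  cfg
}

.STEM_POOL <- 4L
.CONV_CHANNELS <- c(3L, 8L, 16L, 32L)

# Filters are random but orthogonalized per block (QR of a Gaussian draw,
# columns rescaled to the He norm): orthogonal filter banks span diverse
# directions regardless of the draw, which removes the occasional
# low-quality filter set a plain Gaussian draw can produce.
initExtractor <- function(seed) {
  withSeed(seed, {
    f <- lapply(seq_len(length(.CONV_CHANNELS) - 1L), function(l) {
      cin <- .CONV_CHANNELS[l]; cout <- .CONV_CHANNELS[l + 1L]
      fanIn <- 9L * cin
      G <- matrix(stats::rnorm(fanIn * cout), fanIn, cout)
      Q <- qr.Q(qr(G))[, seq_len(cout), drop = FALSE]
      array(Q * sqrt(2), c(3L, 3L, cin, cout))
    })
    list(filters = f, stemPool = .STEM_POOL)
  })
}

# 3x3 same-padding convolution via 9 shifted slices
conv3 <- function(A, W) {
  H <- dim(A)[1]; Wd <- dim(A)[2]
  cin <- dim(W)[3]; cout <- dim(W)[4]
  P <- array(0, c(H + 2L, Wd + 2L, cin))
  P[2:(H + 1L), 2:(Wd + 1L), ] <- A
  out <- array(0, c(H, Wd, cout))
  for (o in seq_len(cout)) {
    acc <- matrix(0, H, Wd)
    for (ci in seq_len(cin)) for (di in 0:2) for (dj in 0:2) {
      w <- W[di + 1L, dj + 1L, ci, o]
      acc <- acc + w * P[(1L + di):(H + di), (1L + dj):(Wd + dj), ci]
    }
    out[, , o] <- acc
  }
  out
}

poolArray <- function(A, f) {
  d <- dim(A)
  out <- array(0, c(d[1] %/% f, d[2] %/% f, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- poolMat(A[, , ch], f)
  out
}

extractorFeatures <- function(extractor, pixels) {
  d <- dim(pixels)
  if (d[1] != d[2]) stop("tiles must be square")
  if (d[1] %% (extractor$stemPool * 8L) != 0L)
    stop("tile size must be divisible by ", extractor$stemPool * 8L)
  A <- pixels / 255
  A <- poolArray(A, extractor$stemPool)
  # Per-channel spatial pooling: global mean and sd plus the max and
  # upper-quartile mean. The order statistics respond to locally
  # concentrated texture (a small tumor blob inside a mostly benign tile),
  # which global averaging alone dilutes.
  poolStats <- function(B) {
    as.vector(vapply(seq_len(dim(B)[3]), function(ch) {
      v <- B[, , ch]
      q <- stats::quantile(v, 0.75, names = FALSE)
      c(mean(v), stats::sd(v), max(v), mean(v[v >= q]))
    }, numeric(4)))
  }
  # Color statistics of the stem-pooled input are included alongside the
  # convolutional texture responses: they carry the stain-density signal
  # independently of the particular random filter draw.
  stem <- poolStats(A)
  for (W in extractor$filters) {
    A <- conv3(A, W)
    A[A < 0] <- 0
    A <- poolArray(A, 2L)
  }
  c(stem, poolStats(A))
}

featureDim <- function() {
  4L * (.CONV_CHANNELS[1] + .CONV_CHANNELS[length(.CONV_CHANNELS)])
}

softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

initHead <- function(dIn, widths, nClasses, seed) {
  dims <- c(dIn, widths, nClasses)
  withSeed(seed, {
    W <- lapply(seq_len(length(dims) - 1L), function(l)
      matrix(stats::rnorm(dims[l] * dims[l + 1L],
                          sd = sqrt(2 / dims[l])), dims[l], dims[l + 1L]))
    b <- lapply(dims[-1L], function(k) numeric(k))
    list(W = W, b = b)
  })
}

headForward <- function(head, X) {
  A <- X
  nl <- length(head$W)
  for (l in seq_len(nl - 1L)) {
    A <- sweep(A %*% head$W[[l]], 2, head$b[[l]], "+")
    A[A < 0] <- 0
  }
  softmaxRows(sweep(A %*% head$W[[nl]], 2, head$b[[nl]], "+"))
}

crossEntropy <- function(P, yIdx) {
  -mean(log(pmax(P[cbind(seq_along(yIdx), yIdx)], 1e-12)))
}

#' Build an initialized tile classifier
#'
#' @param spec an [ArchitectureSpec-class].
#' @param seed integer seed; identical (spec, seed) pairs give identical
#'   initial weights and hence identical predictions.
#' @param inputSize expected square tile side in pixels (default 224; must
#'   be divisible by 32).
#' @param classOrder ordered class labels (length `nClasses`); prediction
#'   columns follow this order and the first class is the target class by
#'   convention.
#' @param backboneWeights optional externally trained extractor (a list
#'   with elements `filters` and `stemPool`), required for any
#'   `backboneId` other than `"small"`.
#' @return a [TileClassifier-class].
#' @export
buildModel <- function(spec, seed = 1L, inputSize = 224L,
                       classOrder = c("positive", "control"),
                       backboneWeights = NULL) {
  stopifnot(is(spec, "ArchitectureSpec"))
  validObject(spec)
  if (length(classOrder) != spec@nClasses)
    stop("classOrder must have nClasses entries")
  inputSize <- as.integer(inputSize)
  if (inputSize %% 32L != 0L)
    stop("inputSize must be divisible by 32")
  if (!is.null(backboneWeights)) {
    extractor <- backboneWeights
  } else if (spec@backboneId == "small") {
    if (spec@pretrained)
      stop("pretrained = TRUE requires externally supplied backboneWeights")
    extractor <- initExtractor(substreamSeed(seed, 1L))
  } else {
    stop("unknown backbone '", spec@backboneId,
         "' (supply backboneWeights for external architectures)")
  }
  head <- initHead(featureDim(), spec@denseWidths, spec@nClasses,
                   substreamSeed(seed, 2L))
  new("TileClassifier", architecture = spec,
      parameters = list(extractor = extractor, head = head,
                        featMean = NULL, featSd = NULL, trained = FALSE,
                        seed = as.integer(seed)),
      classOrder = classOrder, inputSize = inputSize)
}

.TRANSFORMS <- c("identity", "hflip", "vflip", "rot90", "rot180", "rot270",
                 "transpose", "antitranspose")

#' Apply a deterministic dihedral transform to a square tile
#'
#' @param pixels integer array size x size x 3.
#' @param transform one of `"identity"`, `"hflip"`, `"vflip"`, `"rot90"`,
#'   `"rot180"`, `"rot270"`, `"transpose"`, `"antitranspose"`.
#' @return transformed array, same shape.
#' @export
applyTileTransform <- function(pixels, transform = "identity") {
  transform <- match.arg(transform, .TRANSFORMS)
  n <- dim(pixels)[1]
  tr <- function(f) {
    out <- pixels
    for (ch in 1:3) out[, , ch] <- f(pixels[, , ch])
    out
  }
  switch(transform,
         identity = pixels,
         hflip = pixels[, n:1, , drop = FALSE],
         vflip = pixels[n:1, , , drop = FALSE],
         rot90 = tr(function(m) t(m)[n:1, , drop = FALSE]),
         rot180 = pixels[n:1, , , drop = FALSE][, n:1, , drop = FALSE],
         rot270 = tr(function(m) t(m)[, n:1, drop = FALSE]),
         transpose = tr(t),
         antitranspose = tr(function(m) t(m)[n:1, n:1, drop = FALSE]))
}

#' Randomly augment a tile
#'
#' Samples one label-preserving transform from the configured inventory
#' (dihedral flips/rotations) and applies a bounded per-channel brightness
#' shift. A degenerate spec (all options off, or `NULL`) is the identity.
#'
#' @param pixels integer array size x size x 3, values 0..255.
#' @param spec augmentation spec as in [trainConfig()].
#' @param seed integer seed; deterministic given (pixels, spec, seed).
#' @return augmented integer array, same shape, values 0..255.
#' @export
augmentTile <- function(pixels, spec, seed = 1L) {
  if (is.null(spec)) return(pixels)
  pool <- "identity"
  if (isTRUE(spec$flip)) pool <- c(pool, "hflip", "vflip")
  if (isTRUE(spec$rotate)) pool <- c(pool, "rot90", "rot180", "rot270")
  delta <- spec$brightnessDelta
  if (is.null(delta)) delta <- 0
  withSeed(seed, {
    out <- applyTileTransform(pixels, sample(pool, 1L))
    if (delta > 0) {
      shift <- round(stats::runif(3, -delta, delta) * 255)
      for (ch in 1:3)
        out[, , ch] <- clamp(out[, , ch] + as.integer(shift[ch]), 0L, 255L)
    }
    out
  })
}

datasetFeatures <- function(extractor, dataset, variants = 1L,
                            augmentation = NULL, seed = 1L) {
  n <- nrow(dataset@tiles)
  lapply(seq_len(variants), function(v) {
    X <- matrix(0, n, featureDim())
    for (i in seq_len(n)) {
      px <- tilePixels(dataset, i)
      if (v > 1L)
        px <- augmentTile(px, augmentation, substreamSeed(seed, i * 8L + v))
      X[i, ] <- extractorFeatures(extractor, px)
    }
    X
  })
}

adamInit <- function(head) {
  list(m = lapply(c(head$W, head$b), function(x) x * 0),
       v = lapply(c(head$W, head$b), function(x) x * 0), t = 0L)
}

adamStep <- function(head, grads, state, lr) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  pars <- c(head$W, head$b)
  for (k in seq_along(pars)) {
    g <- grads[[k]]
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g * g
    mh <- state$m[[k]] / (1 - b1^state$t)
    vh <- state$v[[k]] / (1 - b2^state$t)
    pars[[k]] <- pars[[k]] - lr * mh / (sqrt(vh) + eps)
  }
  nl <- length(head$W)
  list(head = list(W = pars[seq_len(nl)], b = pars[nl + seq_len(nl)]),
       state = state)
}

headGradients <- function(head, X, yIdx, nClasses) {
  n <- nrow(X)
  nl <- length(head$W)
  Z <- vector("list", nl); A <- vector("list", nl + 1L)
  A[[1L]] <- X
  for (l in seq_len(nl)) {
    Z[[l]] <- sweep(A[[l]] %*% head$W[[l]], 2, head$b[[l]], "+")
    A[[l + 1L]] <- if (l < nl) pmax(Z[[l]], 0) else Z[[l]]
  }
  P <- softmaxRows(A[[nl + 1L]])
  Y <- matrix(0, n, nClasses)
  Y[cbind(seq_len(n), yIdx)] <- 1
  dZ <- (P - Y) / n
  gW <- vector("list", nl); gb <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    gW[[l]] <- crossprod(A[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1L) {
      dA <- dZ %*% t(head$W[[l]])
      dZ <- dA * (Z[[l - 1L]] > 0)
    }
  }
  list(grads = c(gW, gb), loss = crossEntropy(P, yIdx))
}

#' Train a tile classifier
#'
#' Minimizes categorical cross-entropy on augmented tiles with Adam, using
#' an internal validation split grouped by patient (no patient appears in
#' both halves), early stopping on validation loss with best-weight
#' restoration, and a hard cap of 200 epochs.
#'
#' @param model an initialized [TileClassifier-class] from [buildModel()].
#' @param dataset a [TileDataset-class] with at least two label classes.
#' @param config a [trainConfig()] object.
#' @return list with elements `model` (trained [TileClassifier-class]) and
#'   `history` (data.frame epoch/trainLoss/valLoss, one row per epoch run,
#'   with attributes `bestEpoch` and `restoredValLoss`).
#' @export
trainClassifier <- function(model, dataset, config = trainConfig()) {
  stopifnot(is(model, "TileClassifier"), is(dataset, "TileDataset"),
            inherits(config, "mohsmapTrainConfig"))
  tiles <- dataset@tiles
  if (nrow(tiles) == 0L) stop("empty tile dataset")
  if (!all(tiles$label %in% model@classOrder))
    stop("dataset labels outside the model's classOrder")
  if (length(unique(tiles$label)) < 2L)
    stop("training requires at least two classes present")
  if (tiles$size[1] != model@inputSize)
    stop("tile size ", tiles$size[1], " does not match model input ",
         model@inputSize)
  yIdx <- match(tiles$label, model@classOrder)
  n <- nrow(tiles)

  # Internal validation split, grouped by patient and stratified by whether
  # a patient contributes positive tiles (so both halves see both classes).
  # When all positives come from a single patient a grouped split cannot put
  # positives on both sides; a stratified tile-level split is used instead.
  valIdx <- withSeed(substreamSeed(config$seed, 3L), {
    labByPat <- split(tiles$label, tiles$patient_id)
    pats <- names(labByPat)
    posPats <- pats[vapply(labByPat, function(l) any(l == "positive"),
                           logical(1))]
    ctlPats <- setdiff(pats, posPats)
    takeFrom <- function(x) {
      k <- min(length(x) - 1L,
               max(1L, round(config$validationFraction * length(x))))
      if (k >= 1L) sample(x, k) else character(0)
    }
    if (length(posPats) >= 2L) {
      valPats <- c(takeFrom(posPats),
                   if (length(ctlPats) >= 2L) takeFrom(ctlPats))
      which(tiles$patient_id %in% valPats)
    } else {
      unlist(lapply(split(seq_len(n), tiles$label), function(ix)
        sample(ix, max(1L, round(config$validationFraction * length(ix))))),
        use.names = FALSE)
    }
  })
  trIdx <- setdiff(seq_len(n), valIdx)

  aug <- config$augmentation
  variants <- if (is.null(aug)) 1L else max(1L, as.integer(aug$variants))
  feats <- datasetFeatures(model@parameters$extractor, dataset,
                           variants = variants, augmentation = aug,
                           seed = substreamSeed(config$seed, 4L))
  mu <- colMeans(feats[[1L]][trIdx, , drop = FALSE])
  sd <- apply(feats[[1L]][trIdx, , drop = FALSE], 2, stats::sd)
  sd[sd < 1e-6] <- 1e-6
  std <- function(X) sweep(sweep(X, 2, mu), 2, sd, "/")
  featsStd <- lapply(feats, std)
  Xval <- featsStd[[1L]][valIdx, , drop = FALSE]
  yVal <- yIdx[valIdx]

  head <- model@parameters$head
  state <- adamInit(head)
  nClasses <- model@architecture@nClasses
  hist <- list()
  best <- list(loss = Inf, head = head, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(config$maxEpochs)) {
    ord <- withSeed(substreamSeed(config$seed, 100L + epoch), {
      vSel <- sample.int(variants, length(trIdx), replace = TRUE)
      list(perm = sample(trIdx), v = vSel)
    })
    vByTile <- integer(n); vByTile[trIdx] <- ord$v
    losses <- c()
    starts <- seq(1L, length(ord$perm), by = config$batchSize)
    for (s in starts) {
      bi <- ord$perm[s:min(s + config$batchSize - 1L, length(ord$perm))]
      Xb <- do.call(rbind, lapply(bi, function(i)
        featsStd[[vByTile[i]]][i, , drop = FALSE]))
      g <- headGradients(head, Xb, yIdx[bi], nClasses)
      upd <- adamStep(head, g$grads, state, config$learningRate)
      head <- upd$head; state <- upd$state
      if (config$weightDecay > 0)
        head$W <- lapply(head$W, function(w)
          w * (1 - config$learningRate * config$weightDecay))
      losses <- c(losses, g$loss)
    }
    valLoss <- crossEntropy(headForward(head, Xval), yVal)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                trainLoss = mean(losses),
                                valLoss = valLoss)
    if (epoch <= config$earlyStoppingBurnIn) next
    if (valLoss < best$loss - 1e-9) {
      best <- list(loss = valLoss, head = head, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$earlyStoppingPatience) break
    }
  }
  if (is.infinite(best$loss))   # never past burn-in: keep the final weights
    best <- list(loss = valLoss, head = head, epoch = epoch)
  history <- do.call(rbind, hist)
  model@parameters$head <- best$head
  model@parameters$featMean <- mu
  model@parameters$featSd <- sd
  model@parameters$trained <- TRUE
  attr(history, "bestEpoch") <- best$epoch
  attr(history, "burnIn") <- config$earlyStoppingBurnIn
  attr(history, "restoredValLoss") <-
    crossEntropy(headForward(best$head, Xval), yVal)
  attr(history, "validationTiles") <- valIdx
  list(model = model, history = history)
}

# Inference averages the softmax outputs over all eight dihedral views of
# each tile (a deterministic orientation ensemble): the fixed random
# convolution filters are not rotation invariant, and averaging removes the
# resulting orientation noise from the probability estimate.
predictPixelList <- function(model, pixelList, viewAverage = TRUE) {
  views <- if (viewAverage) .TRANSFORMS else "identity"
  probs <- 0
  for (v in views) {
    feats <- do.call(rbind, lapply(pixelList, function(px) {
      d <- dim(px)
      if (d[1] != model@inputSize || d[2] != model@inputSize)
        stop("tile size ", d[1], " x ", d[2], " does not match model input ",
             model@inputSize)
      extractorFeatures(model@parameters$extractor,
                        applyTileTransform(px, v))
    }))
    mu <- model@parameters$featMean
    sd <- model@parameters$featSd
    if (!is.null(mu)) feats <- sweep(sweep(feats, 2, mu), 2, sd, "/")
    probs <- probs + headForward(model@parameters$head, feats)
  }
  P <- probs / length(views)
  colnames(P) <- model@classOrder
  P
}

#' @param viewAverage average the softmax outputs over the eight dihedral
#'   views of each tile (deterministic orientation ensemble; default TRUE).
#' @rdname predictTiles
setMethod("predictTiles", signature(model = "TileClassifier", tiles = "list"),
          function(model, tiles, viewAverage = TRUE, ...)
            predictPixelList(model, tiles, viewAverage))

#' @rdname predictTiles
setMethod("predictTiles",
          signature(model = "TileClassifier", tiles = "TileDataset"),
          function(model, tiles, viewAverage = TRUE, ...) {
            px <- lapply(seq_len(nrow(tiles@tiles)),
                         function(i) tilePixels(tiles, i))
            predictPixelList(model, px, viewAverage)
          })

#' @rdname predictTiles
setMethod("predictTiles", signature(model = "function", tiles = "list"),
          function(model, tiles, ...) {
            p <- vapply(tiles, model, numeric(1))
            stopIfNot01(p, "stub classifier output")
            P <- cbind(positive = p, control = 1 - p)
            P
          })

#' @rdname predictTiles
setMethod("predictTiles",
          signature(model = "function", tiles = "TileDataset"),
          function(model, tiles, ...) {
            px <- lapply(seq_len(nrow(tiles@tiles)),
                         function(i) tilePixels(tiles, i))
            predictTiles(model, px)
          })
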