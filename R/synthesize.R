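# Synthetic frozen-section generator. Background emulates eosin-stained
# stroma (pink base + smoothed colored noise); tumor texture is a field of
# dark elliptical nuclei whose density and color contrast scale linearly
# with the separability parameter, so separability 0 renders tumor regions
# with a texture identically distributed to the background. Tumor region
# geometry is analytic (random ellipses); a mask pixel is positive iff its
# center lies inside a planted ellipse, so mask and rendered texture
# coincide exactly.

.BG_BASE <- c(0.92, 0.78, 0.83)
.NUCLEUS_PALETTES <- list(
  BCC = c(0.27, 0.20, 0.47),   # hematoxylin-dominant basaloid nuclei
  SCC = c(0.52, 0.22, 0.28)    # eosinophilic keratinocyte tone
)
.NUCLEUS_MAX_DENSITY <- 0.0040 # nuclei per px^2 at separability 1
.CONTROL_KINDS <- c("other_tumor", "follicle_rings", "inflammation_speckle",
                    "plain")

#' Construct synthesis parameters
#'
#' @param imageWidth,imageHeight image size in pixels (defaults are the
#'   package's test-scale size; the study-scale 1600 x 1200 is available by
#'   setting them).
#' @param magnification `"40x"` or `"100x"`.
#' @param nTumorBlobs number of planted elliptical tumor regions.
#' @param blobRadiusRange min/max ellipse semi-axis in pixels.
#' @param separability texture contrast between tumor and background in
#'   [0, 1]; 0 = identically distributed, 1 = maximal nucleus density and
#'   color contrast.
#' @param distractorDensity density multiplier for distractor structures in
#'   control images.
#' @param seed integer seed; all randomness of a generated image flows from
#'   it through a counter-based substream.
#' @return a [SynthesisParams-class] object.
#' @examples
#' p <- synthesisParams(seed = 7)
#' sp <- generateSpecimen(p, patientId = "pat01", diagnosis = "BCC")
#' positiveFraction(sp$mask)
#' @export
synthesisParams <- function(imageWidth = 448L, imageHeight = 448L,
                            magnification = "100x", nTumorBlobs = 1L,
                            blobRadiusRange = c(120, 160),
                            separability = 0.9, distractorDensity = 1,
                            seed = 1L) {
  new("SynthesisParams",
      imageWidth = as.integer(imageWidth),
      imageHeight = as.integer(imageHeight),
      magnification = magnification,
      nTumorBlobs = as.integer(nTumorBlobs),
      blobRadiusRange = as.numeric(blobRadiusRange),
      separability = as.numeric(separability),
      distractorDensity = as.numeric(distractorDensity),
      seed = as.integer(seed))
}

# stroma-like background texture, numeric [0,1] H x W x 3
renderBackground <- function(H, W) {
  out <- array(0, c(H, W, 3L))
  shade <- boxBlur(matrix(stats::rnorm(H * W, 0, 0.55), H, W), radius = 6L)
  for (ch in 1:3) {
    grain <- matrix(stats::rnorm(H * W, 0, 0.02), H, W)
    out[, , ch] <- clamp(.BG_BASE[ch] + shade * c(0.9, 1.1, 0.8)[ch] + grain,
                         0, 1)
  }
  out
}

# scatter filled ellipses ("nuclei") over a layer, in place
drawNuclei <- function(layer, density, color, contrast,
                       axisRange = c(2.5, 5.5)) {
  H <- dim(layer)[1]; W <- dim(layer)[2]
  n <- stats::rpois(1, density * H * W)
  if (n == 0) return(layer)
  ci <- stats::runif(n, 0, H - 1); cj <- stats::runif(n, 0, W - 1)
  a <- stats::runif(n, axisRange[1], axisRange[2])
  b <- a * stats::runif(n, 0.55, 1)
  th <- stats::runif(n, 0, pi)
  jit <- matrix(stats::runif(3 * n, -0.06, 0.06), n, 3)
  for (k in seq_len(n)) {
    i0 <- max(0, floor(ci[k] - a[k])); i1 <- min(H - 1, ceiling(ci[k] + a[k]))
    j0 <- max(0, floor(cj[k] - a[k])); j1 <- min(W - 1, ceiling(cj[k] + a[k]))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    dx <- outer(ii - ci[k], rep(1, length(jj)))
    dy <- outer(rep(1, length(ii)), jj - cj[k])
    u <- dx * cos(th[k]) + dy * sin(th[k])
    v <- -dx * sin(th[k]) + dy * cos(th[k])
    inside <- (u / a[k])^2 + (v / b[k])^2 <= 1
    if (!any(inside)) next
    for (ch in 1:3) {
      block <- layer[ii + 1L, jj + 1L, ch]
      col <- clamp((1 - contrast) * .BG_BASE[ch] +
                     contrast * (color[ch] + jit[k, ch]), 0, 1)
      block[inside] <- col
      layer[ii + 1L, jj + 1L, ch] <- block
    }
  }
  layer
}

renderTumorTexture <- function(H, W, separability, palette) {
  layer <- renderBackground(H, W)
  drawNuclei(layer, density = separability * .NUCLEUS_MAX_DENSITY,
             color = palette, contrast = separability)
}

# analytic ellipse geometry -> logical mask; centers in 0-based pixel coords
ellipseMask <- function(H, W, centers, axes, angles) {
  mask <- matrix(FALSE, H, W)
  for (k in seq_len(nrow(centers))) {
    ci <- centers[k, 1]; cj <- centers[k, 2]
    a <- axes[k, 1]; b <- axes[k, 2]; th <- angles[k]
    r <- max(a, b)
    i0 <- max(0, floor(ci - r)); i1 <- min(H - 1, ceiling(ci + r))
    j0 <- max(0, floor(cj - r)); j1 <- min(W - 1, ceiling(cj + r))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    dx <- outer(ii - ci, rep(1, length(jj)))
    dy <- outer(rep(1, length(ii)), jj - cj)
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    mask[ii + 1L, jj + 1L] <- mask[ii + 1L, jj + 1L] |
      ((u / a)^2 + (v / b)^2 <= 1)
  }
  mask
}

#' Generate one synthetic specimen image with its tumor mask
#'
#' Plants `nTumorBlobs` random ellipses (possibly overlapping), renders them
#' with the tumor texture of the given diagnosis and everything else with
#' the background texture, and returns the exact planted geometry as the
#' mask. Deterministic given the seed in `params`.
#'
#' @param params a [SynthesisParams-class] object.
#' @param patientId,imageId identifiers stored in the result.
#' @param diagnosis `"BCC"` or `"SCC"` (selects the nucleus palette).
#' @param blobCenters,blobAxes,blobAngles optional explicit geometry
#'   overriding the random draw: an n x 2 matrix of (row, col) centers in
#'   0-based pixel coordinates, an n x 2 matrix of semi-axes in pixels, and
#'   a length-n vector of rotation angles in radians.
#' @return list with elements `image` ([SpecimenImage-class]) and `mask`
#'   ([TumorMask-class]).
#' @export
generateSpecimen <- function(params, patientId, diagnosis = "BCC",
                             imageId = paste0(patientId, "_img1"),
                             blobCenters = NULL, blobAxes = NULL,
                             blobAngles = NULL) {
  stopifnot(is(params, "SynthesisParams"))
  validObject(params)
  if (!diagnosis %in% names(.NUCLEUS_PALETTES))
    stop("no tumor texture defined for diagnosis '", diagnosis, "'")
  H <- params@imageHeight; W <- params@imageWidth
  withSeed(params@seed, {
    nb <- params@nTumorBlobs
    if (is.null(blobCenters)) {
      if (nb > 0) {
        blobCenters <- cbind(stats::runif(nb, 0, H - 1),
                             stats::runif(nb, 0, W - 1))
        blobAxes <- matrix(stats::runif(2 * nb, params@blobRadiusRange[1],
                                        params@blobRadiusRange[2]), nb, 2)
        blobAngles <- stats::runif(nb, 0, pi)
      } else {
        blobCenters <- matrix(numeric(0), 0, 2)
        blobAxes <- matrix(numeric(0), 0, 2)
        blobAngles <- numeric(0)
      }
    } else {
      blobCenters <- rbind(blobCenters)
      blobAxes <- rbind(blobAxes)
      if (is.null(blobAngles)) blobAngles <- rep(0, nrow(blobCenters))
      if (any(blobAxes > sqrt(H^2 + W^2) / 2))
        stop("blob radius exceeds the image half-diagonal")
    }
    mask <- ellipseMask(H, W, blobCenters, blobAxes, blobAngles)
    bg <- renderBackground(H, W)
    if (any(mask)) {
      tumor <- renderTumorTexture(H, W, params@separability,
                                  .NUCLEUS_PALETTES[[diagnosis]])
      for (ch in 1:3) {
        b <- bg[, , ch]; t <- tumor[, , ch]
        b[mask] <- t[mask]
        bg[, , ch] <- b
      }
    }
    img <- new("SpecimenImage", pixels = quantize255(bg),
               patientId = as.character(patientId),
               imageId = as.character(imageId),
               magnification = params@magnification,
               diagnosis = diagnosis)
    list(image = img, mask = new("TumorMask", mask = mask, imageId = imageId))
  })
}

#' Generate a control image of a given distractor kind
#'
#' Control images carry no target-class tumor texture and no mask (they are
#' implicitly all-negative). Kinds: `"plain"` (background only),
#' `"other_tumor"` (planted blobs rendered with the other tumor class's
#' texture), `"follicle_rings"` (concentric keratinized ring structures,
#' the hair-follicle lookalike), `"inflammation_speckle"` (sparse small
#' dark cells).
#'
#' @param kind one of the configured distractor kinds.
#' @param params a [SynthesisParams-class] object.
#' @param patientId,imageId identifiers.
#' @param diagnosis diagnosis label to record (defaults to the kind).
#' @param otherPalette palette name used by `"other_tumor"`.
#' @return a [SpecimenImage-class].
#' @export
generateControlImage <- function(kind, params, patientId,
                                 imageId = paste0(patientId, "_ctl1"),
                                 diagnosis = kind, otherPalette = "SCC") {
  stopifnot(is(params, "SynthesisParams"))
  validObject(params)
  if (!kind %in% .CONTROL_KINDS)
    stop("unknown control kind '", kind, "'; available: ",
         paste(.CONTROL_KINDS, collapse = ", "))
  H <- params@imageHeight; W <- params@imageWidth
  withSeed(params@seed, {
    layer <- renderBackground(H, W)
    dd <- params@distractorDensity
    if (kind == "other_tumor") {
      nb <- max(1L, params@nTumorBlobs)
      centers <- cbind(stats::runif(nb, 0, H - 1), stats::runif(nb, 0, W - 1))
      axes <- matrix(stats::runif(2 * nb, params@blobRadiusRange[1],
                                  params@blobRadiusRange[2]), nb, 2)
      angles <- stats::runif(nb, 0, pi)
      reg <- ellipseMask(H, W, centers, axes, angles)
      tumor <- renderTumorTexture(H, W, params@separability,
                                  .NUCLEUS_PALETTES[[otherPalette]])
      for (ch in 1:3) {
        b <- layer[, , ch]; t <- tumor[, , ch]
        b[reg] <- t[reg]
        layer[, , ch] <- b
      }
    } else if (kind == "follicle_rings") {
      nRings <- max(1L, stats::rpois(1, dd * 2.5))
      for (k in seq_len(nRings)) {
        ci <- stats::runif(1, 0.15 * H, 0.85 * H)
        cj <- stats::runif(1, 0.15 * W, 0.85 * W)
        r <- stats::runif(1, 0.06 * min(H, W), 0.18 * min(H, W))
        th <- stats::runif(1, 5, 9)
        ii <- max(0, floor(ci - r - th)):min(H - 1, ceiling(ci + r + th))
        jj <- max(0, floor(cj - r - th)):min(W - 1, ceiling(cj + r + th))
        d <- sqrt(outer((ii - ci)^2, rep(1, length(jj))) +
                    outer(rep(1, length(ii)), (jj - cj)^2))
        ring <- abs(d - r) <= th / 2
        core <- d < r - th / 2
        ringCol <- c(0.45, 0.30, 0.35); coreCol <- c(0.85, 0.75, 0.55)
        for (ch in 1:3) {
          block <- layer[ii + 1L, jj + 1L, ch]
          block[ring] <- ringCol[ch]
          block[core] <- clamp(coreCol[ch] +
                                 stats::rnorm(sum(core), 0, 0.03), 0, 1)
          layer[ii + 1L, jj + 1L, ch] <- block
        }
      }
    } else if (kind == "inflammation_speckle") {
      layer <- drawNuclei(layer, density = dd * 0.0018,
                          color = c(0.20, 0.18, 0.40), contrast = 0.9,
                          axisRange = c(0.8, 1.8))
    } # "plain": background only
    new("SpecimenImage", pixels = quantize255(layer),
        patientId = as.character(patientId),
        imageId = as.character(imageId),
        magnification = params@magnification,
        diagnosis = diagnosis)
  })
}

.controlKindFor <- function(diagnosis, u) {
  switch(diagnosis,
         AK = "inflammation_speckle",
         normal = if (u < 0.5) "plain" else "follicle_rings",
         stop("no control kind for diagnosis '", diagnosis, "'"))
}

#' Generate a synthetic cohort
#'
#' Draws a diagnosis per patient from `classMix`, assigns patients whole to
#' a development or validation split, and generates `imagesPerPatient`
#' images per patient: tumor-class patients (`BCC`, `SCC`) get specimen
#' images with exact masks, control-class patients (`AK`, `normal`) get
#' distractor images without masks. Every image draws its randomness from a
#' counter-based substream of `seed`, so per-image content is independent
#' of generation order.
#'
#' @param nPatients number of patients (>= 1).
#' @param imagesPerPatient images per patient.
#' @param classMix named numeric vector of patient-level diagnosis
#'   probabilities over `BCC`, `SCC`, `AK`, `normal`; must sum to 1.
#' @param params a [SynthesisParams-class]; its `seed` slot is ignored in
#'   favor of `seed`.
#' @param seed integer seed for the whole cohort.
#' @param validationFraction fraction of patients assigned (whole) to the
#'   validation split.
#' @return a [CohortDataset-class].
#' @export
generateCohort <- function(nPatients, imagesPerPatient = 4L,
                           classMix = c(BCC = 0.68, SCC = 0.12,
                                        AK = 0.10, normal = 0.10),
                           params = synthesisParams(), seed = 1L,
                           validationFraction = 0.3) {
  stopifnot(nPatients >= 1, imagesPerPatient >= 1)
  if (abs(sum(classMix) - 1) > 1e-8)
    stop("classMix must sum to 1")
  if (is.null(names(classMix)) || !all(names(classMix) %in%
                                       c("BCC", "SCC", "AK", "normal")))
    stop("classMix names must be among BCC, SCC, AK, normal")
  seed <- as.integer(seed)
  assign <- withSeed(seed, {
    dx <- sample(names(classMix), nPatients, replace = TRUE, prob = classMix)
    nVal <- if (nPatients >= 2) max(1L, round(validationFraction * nPatients))
            else 0L
    val <- sample.int(nPatients, nVal)
    list(dx = dx, val = val)
  })
  images <- list(); masks <- list(); rows <- list()
  idx <- 0L
  for (p in seq_len(nPatients)) {
    pid <- sprintf("pat%03d", p)
    split <- if (p %in% assign$val) "validation" else "development"
    dxp <- assign$dx[p]
    for (k in seq_len(imagesPerPatient)) {
      idx <- idx + 1L
      iid <- sprintf("img%04d", idx)
      sub <- substreamSeed(seed, idx)
      pk <- params; pk@seed <- sub
      if (dxp %in% c("BCC", "SCC")) {
        sp <- generateSpecimen(pk, pid, diagnosis = dxp, imageId = iid)
        images[[iid]] <- sp$image
        masks[[iid]] <- sp$mask
      } else {
        u <- withSeed(substreamSeed(sub, 999L), stats::runif(1))
        kind <- .controlKindFor(dxp, u)
        images[[iid]] <- generateControlImage(kind, pk, pid, imageId = iid,
                                              diagnosis = dxp)
      }
      rows[[idx]] <- data.frame(image_id = iid, patient_id = pid,
                                split = split,
                                magnification = params@magnification,
                                diagnosis = dxp,
                                stringsAsFactors = FALSE)
    }
  }
  new("CohortDataset", images = images, masks = masks,
      info = do.call(rbind, rows))
}
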