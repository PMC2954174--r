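#' @include AllClasses.R volume-ops.R
NULL

#' Phantom cohort configuration
#'
#' Parameters of the synthetic brain-phantom generator. The phantom
#' emulates the statistical structure the laterality pipeline assumes:
#' activation blobs contralateral to the grasping hand over a noisy
#' baseline inside a symmetric brain mask, a cohort of jittered bilateral
#' motor-hand (KNOB) tracings whose overlap decays with threshold,
#' two-to-three-compartment tissue segmentations with a controllable
#' hemispheric white-matter asymmetry, and binomial grasping-error counts
#' whose handedness effect is tied to the implanted WM asymmetry.
#'
#' Defaults describe a 64 x 64 x 48 grid of 2 mm voxels, a four-subject
#' activation cohort (three left-hand graspers and one right-hand grasper)
#' and a 62-subject anatomical cohort, with activation amplitude 3
#' (standardized units above a baseline of 1), noise SD 1, a 6 mm
#' (1 sigma) activation blob, knob centers 22 mm lateral of the midline,
#' 8 mm radii, 2 mm tracing jitter, a white-matter base fraction of 0.60,
#' a cohort-mean WM asymmetry quotient of -0.2 (SD 0.5), 3% CSF, and 60
#' grasping trials per hand at a base error probability of 0.2 with a
#' logit-scale handedness effect of 1.5.
#'
#' @slot dims integer(3) grid dimensions; nx must be even.
#' @slot voxelSize numeric(3) voxel size in mm.
#' @slot nPET integer number of activation-study subjects.
#' @slot nAtlas integer number of anatomical (tracing) subjects.
#' @slot hands character, grasping hand per PET subject ("left"/"right").
#' @slot activationAmplitude numeric >= 0, blob peak height above baseline.
#' @slot noiseSD numeric >= 0, iid Gaussian noise SD inside the mask.
#' @slot blobSigmaMM numeric > 0, Gaussian activation blob sigma in mm.
#' @slot knobCenterMM numeric(3), right-hemisphere knob center in mm:
#'   distance from the mid-sagittal plane, then offsets from the grid
#'   center along the posterior-anterior and inferior-superior axes; the
#'   left-hemisphere center is its mirror image.
#' @slot knobRadiiMM numeric(3) tracing ellipsoid semi-axes in mm.
#' @slot tracingJitterMM numeric >= 0, uniform per-axis tracing
#'   displacement bound in mm.
#' @slot wmBase numeric in (0,1), mean white-matter fraction in the knob.
#' @slot wmAsymEffect numeric in [-2, 2], target asymmetry quotient of
#'   percent WM inside the tracing (positive = rightward).
#' @slot wmAsymSD numeric >= 0, between-subject SD of the implanted AQ.
#' @slot csfFrac numeric in [0, 0.05], CSF fraction inside the knob.
#' @slot trialsPerHand integer > 0, grasping trials per hand.
#' @slot errorProbBase numeric in (0,1), baseline grasping error rate.
#' @slot handednessEffect numeric, logit-scale link between a subject's WM
#'   asymmetry and the between-hand error-rate difference.
#' @slot maskSemiAxesMM numeric(3) brain-ellipsoid semi-axes in mm.
#' @seealso [phantomConfig()], [simulateCohort()]
#' @exportClass PhantomConfig
setClass("PhantomConfig", representation(
  dims = "integer",
  voxelSize = "numeric",
  nPET = "integer",
  nAtlas = "integer",
  hands = "character",
  activationAmplitude = "numeric",
  noiseSD = "numeric",
  blobSigmaMM = "numeric",
  knobCenterMM = "numeric",
  knobRadiiMM = "numeric",
  tracingJitterMM = "numeric",
  wmBase = "numeric",
  wmAsymEffect = "numeric",
  wmAsymSD = "numeric",
  csfFrac = "numeric",
  trialsPerHand = "integer",
  errorProbBase = "numeric",
  handednessEffect = "numeric",
  maskSemiAxesMM = "numeric"
))

setValidity("PhantomConfig", function(object) {
  msgs <- .checkGrid(object@dims, object@voxelSize)
  if (object@nPET < 1L) msgs <- c(msgs, "nPET must be >= 1")
  if (object@nAtlas < 1L) msgs <- c(msgs, "nAtlas must be >= 1")
  if (!all(object@hands %in% c("left", "right")))
    msgs <- c(msgs, "hands must be 'left' or 'right'")
  if (object@activationAmplitude < 0 || object@noiseSD < 0)
    msgs <- c(msgs, "amplitude and noise SD must be >= 0")
  if (object@blobSigmaMM <= 0) msgs <- c(msgs, "blobSigmaMM must be > 0")
  if (object@tracingJitterMM < 0) msgs <- c(msgs, "tracing jitter must be >= 0")
  if (object@wmAsymEffect < -2 || object@wmAsymEffect > 2)
    msgs <- c(msgs, "wmAsymEffect must lie in [-2, 2]")
  if (object@wmAsymSD < 0) msgs <- c(msgs, "wmAsymSD must be >= 0")
  if (object@wmBase <= 0 || object@wmBase >= 1)
    msgs <- c(msgs, "wmBase must lie in (0, 1)")
  if (object@csfFrac < 0 || object@csfFrac > 0.05)
    msgs <- c(msgs, "csfFrac must lie in [0, 0.05]")
  pR <- object@wmBase * (1 + object@wmAsymEffect / 2)
  pL <- object@wmBase * (1 - object@wmAsymEffect / 2)
  if (pR <= 0 || pL <= 0 || pR + object@csfFrac >= 1 ||
      pL + object@csfFrac >= 1)
    msgs <- c(msgs, paste(
      "unattainable tissue fractions: wmBase and wmAsymEffect imply",
      "per-hemisphere WM probabilities outside (0, 1 - csfFrac)"))
  if (object@trialsPerHand < 1L) msgs <- c(msgs, "trialsPerHand must be > 0")
  if (object@errorProbBase <= 0 || object@errorProbBase >= 1)
    msgs <- c(msgs, "errorProbBase must lie in (0, 1)")
  half <- object@dims * object@voxelSize / 2
  if (any(object@maskSemiAxesMM > half))
    msgs <- c(msgs, "brain ellipsoid exceeds the grid: reduce maskSemiAxesMM")
  if (length(msgs)) msgs else TRUE
})

#' @param dims,voxelSize,nPET,nAtlas,hands,activationAmplitude,noiseSD
#'   see the slot descriptions.
#' @param blobSigmaMM,knobCenterMM,knobRadiiMM,tracingJitterMM see slots.
#' @param wmBase,wmAsymEffect,wmAsymSD,csfFrac see slots.
#' @param trialsPerHand,errorProbBase,handednessEffect see slots.
#' @param maskSemiAxesMM brain-ellipsoid semi-axes in mm; the default fills
#'   roughly a third of the grid.
#' @return A validated `PhantomConfig`.
#' @examples
#' cfg <- phantomConfig(nAtlas = 10L)
#' cfg
#' @rdname PhantomConfig-class
#' @export
phantomConfig <- function(dims = c(64L, 64L, 48L),
                          voxelSize = c(2, 2, 2),
                          nPET = 4L,
                          nAtlas = 62L,
                          hands = c("left", "left", "left", "right"),
                          activationAmplitude = 3,
                          noiseSD = 1,
                          blobSigmaMM = 6,
                          knobCenterMM = c(22, 8, 20),
                          knobRadiiMM = c(8, 8, 8),
                          tracingJitterMM = 2,
                          wmBase = 0.60,
                          wmAsymEffect = -0.2,
                          wmAsymSD = 0.5,
                          csfFrac = 0.03,
                          trialsPerHand = 60L,
                          errorProbBase = 0.2,
                          handednessEffect = 1.5,
                          maskSemiAxesMM = NULL) {
  dims <- as.integer(dims)
  if (is.null(maskSemiAxesMM))
    maskSemiAxesMM <- c(0.41, 0.44, 0.42) * dims * voxelSize
  hands <- rep_len(hands, nPET)
  new("PhantomConfig",
      dims = dims, voxelSize = as.numeric(voxelSize),
      nPET = as.integer(nPET), nAtlas = as.integer(nAtlas),
      hands = hands,
      activationAmplitude = activationAmplitude, noiseSD = noiseSD,
      blobSigmaMM = blobSigmaMM, knobCenterMM = as.numeric(knobCenterMM),
      knobRadiiMM = as.numeric(knobRadiiMM),
      tracingJitterMM = tracingJitterMM,
      wmBase = wmBase, wmAsymEffect = wmAsymEffect, wmAsymSD = wmAsymSD,
      csfFrac = csfFrac, trialsPerHand = as.integer(trialsPerHand),
      errorProbBase = errorProbBase, handednessEffect = handednessEffect,
      maskSemiAxesMM = as.numeric(maskSemiAxesMM))
}

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf("PhantomConfig: %d x %d x %d grid @ %.3g mm\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@voxelSize[1]))
  cat(sprintf("  %d activation subjects (%s), %d atlas subjects\n",
              object@nPET, paste(substr(object@hands, 1, 1), collapse = ""),
              object@nAtlas))
  cat(sprintf("  amplitude %.3g, noise %.3g, blob sigma %.3g mm\n",
              object@activationAmplitude, object@noiseSD, object@blobSigmaMM))
  cat(sprintf("  WM base %.2f, target AQ %.2f (SD %.2f), handedness effect %.2f\n",
              object@wmBase, object@wmAsymEffect, object@wmAsymSD,
              object@handednessEffect))
  invisible(NULL)
})

# Ellipsoid membership in mm coordinates; center and semi are length-3.
.ellipsoidMask <- function(coords, center, semi) {
  ((coords$x - center[1]) / semi[1])^2 +
    ((coords$y - center[2]) / semi[2])^2 +
    ((coords$z - center[3]) / semi[3])^2 <= 1
}

# Knob center in mm coordinates for one hemisphere. The configured center
# gives the distance from the mid-sagittal plane; the right hemisphere is
# the positive-x side.
.knobCenter <- function(config, hemisphere) {
  c(if (hemisphere == "right") config@knobCenterMM[1] else -config@knobCenterMM[1],
    config@knobCenterMM[2], config@knobCenterMM[3])
}

#' Synthetic brain mask
#'
#' A left-right symmetric ellipsoidal brain mask centred on the grid. The
#' symmetry is exact: `flipLR(mask)` equals `mask` voxelwise.
#'
#' @param config a [PhantomConfig].
#' @return A [BrainMask].
#' @export
makeBrainMask <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  coords <- gridCoordArrays(config@dims, config@voxelSize)
  BrainMask(.ellipsoidMask(coords, c(0, 0, 0), config@maskSemiAxesMM),
            config@voxelSize)
}

#' Synthetic activation volume for one subject
#'
#' Baseline 1.0 inside the brain mask, plus a Gaussian activation blob of
#' height `activationAmplitude` centred on the knob of the hemisphere
#' contralateral to the grasping hand, plus iid Gaussian noise of SD
#' `noiseSD`; zero outside the mask.
#'
#' @param config a [PhantomConfig].
#' @param hand `"left"` or `"right"` grasping hand.
#' @param seed integer seed for this subject's noise stream.
#' @param brainMask optional precomputed [makeBrainMask()] result.
#' @return A [ScalarVolume].
#' @export
makePETSubject <- function(config, hand, seed,
                           brainMask = makeBrainMask(config)) {
  if (!hand %in% c("left", "right"))
    stop("unknown hand label: ", hand, call. = FALSE)
  coords <- gridCoordArrays(config@dims, config@voxelSize)
  contra <- if (hand == "left") "right" else "left"
  ctr <- .knobCenter(config, contra)
  d2 <- (coords$x - ctr[1])^2 + (coords$y - ctr[2])^2 + (coords$z - ctr[3])^2
  blob <- config@activationAmplitude * exp(-d2 / (2 * config@blobSigmaMM^2))
  inmask <- brainMask@voxels
  vals <- array(0, dim = config@dims)
  n <- sum(inmask)
  noise <- if (config@noiseSD > 0)
    withSeed(seed, stats::rnorm(n, 0, config@noiseSD)) else 0
  vals[inmask] <- 1 + blob[inmask] + noise
  ScalarVolume(vals, config@voxelSize)
}

#' Synthetic bilateral knob tracing for one subject
#'
#' One ellipsoid per hemisphere at the knob center, displaced by a uniform
#' per-axis offset within +/- `tracingJitterMM` and with semi-axes scaled
#' by a random factor in \[0.85, 1.15\]. Voxels falling outside the brain
#' mask are clipped with a warning.
#'
#' @inheritParams makePETSubject
#' @return A [BrainMask] with a nonempty component in each hemisphere.
#' @export
makeTracing <- function(config, seed, brainMask = makeBrainMask(config)) {
  coords <- gridCoordArrays(config@dims, config@voxelSize)
  j <- config@tracingJitterMM
  vals <- array(FALSE, dim = config@dims)
  withSeed(seed, {
    for (hemi in c("left", "right")) {
      off <- if (j > 0) stats::runif(3, -j, j) else c(0, 0, 0)
      scale <- stats::runif(1, 0.85, 1.15)
      vals <- vals | .ellipsoidMask(coords, .knobCenter(config, hemi) + off,
                                    config@knobRadiiMM * scale)
    }
  })
  outside <- vals & !brainMask@voxels
  if (any(outside)) {
    warning("tracing clipped to the brain mask (", sum(outside),
            " voxels removed)", call. = FALSE)
    vals <- vals & brainMask@voxels
  }
  BrainMask(vals, config@voxelSize)
}

#' Synthetic tissue segmentation for one subject
#'
#' Inside each hemisphere of the subject's tracing, voxels are labelled WM
#' with hemisphere-specific probabilities chosen so that the expected
#' asymmetry quotient of percent WM equals `asym` (CSF with probability
#' `csfFrac`, GM otherwise). The rest of the brain gets a default GM shell
#' around a WM core, with 10% of those voxels swapped between GM and WM
#' independently per subject to mimic segmentation variability; voxels
#' outside the brain are background.
#'
#' @inheritParams makePETSubject
#' @param tracing the subject's bilateral tracing from [makeTracing()].
#' @param asym target asymmetry quotient of percent WM inside the tracing,
#'   in \[-2, 2\]; defaults to the configured cohort effect.
#' @return A [TissueLabels] volume.
#' @export
makeSegmentation <- function(config, tracing, seed,
                             asym = config@wmAsymEffect,
                             brainMask = makeBrainMask(config)) {
  if (asym < -2 || asym > 2)
    stop("asym must lie in [-2, 2]", call. = FALSE)
  pR <- config@wmBase * (1 + asym / 2)
  pL <- config@wmBase * (1 - asym / 2)
  if (pR < 0 || pL < 0 || pR + config@csfFrac > 1 || pL + config@csfFrac > 1)
    stop("unattainable tissue fractions for asym = ", signif(asym, 3),
         call. = FALSE)
  codes <- tissueCodes()
  dims <- config@dims
  coords <- gridCoordArrays(dims, config@voxelSize)
  labs <- array(codes[["background"]], dim = dims)
  inbrain <- brainMask@voxels
  core <- .ellipsoidMask(coords, c(0, 0, 0), config@maskSemiAxesMM * 0.55)
  labs[inbrain] <- ifelse(core[inbrain], codes[["wm"]], codes[["gm"]])
  hemi <- hemisphereMasks(tracing)
  withSeed(seed, {
    # per-subject segmentation variability outside the tracing: swap a
    # random 10% of shell/core voxels between GM and WM
    out <- which(inbrain & !tracing@voxels)
    swap <- out[stats::runif(length(out)) < 0.1]
    labs[swap] <- ifelse(labs[swap] == codes[["wm"]], codes[["gm"]],
                         codes[["wm"]])
    for (side in c("left", "right")) {
      pWM <- if (side == "right") pR else pL
      idx <- which(tracing@voxels & hemi[[side]]@voxels)
      if (!length(idx)) next
      u <- stats::runif(length(idx))
      lab <- ifelse(u < config@csfFrac, codes[["csf"]],
                    ifelse(u < config@csfFrac + pWM, codes[["wm"]],
                           codes[["gm"]]))
      labs[idx] <- lab
    }
  })
  TissueLabels(labs, config@voxelSize)
}

#' Synthetic grasping-error counts for one subject
#'
#' Error counts per hand are binomial with `trialsPerHand` trials. On the
#' logit scale the right-hand error probability is shifted by
#' `handednessEffect * asym / 2` and the left-hand probability by the
#' opposite amount, so a subject with a leftward WM asymmetry (negative
#' `asym`) makes fewer right-hand errors and classifies as a right
#' performer.
#'
#' @inheritParams makePETSubject
#' @param asym the subject's implanted WM asymmetry quotient.
#' @return Named integer vector with elements `err_right` and `err_left`.
#' @export
makeBehavior <- function(config, asym, seed) {
  eta <- stats::qlogis(config@errorProbBase)
  shift <- config@handednessEffect * asym / 2
  pRight <- stats::plogis(eta + shift)
  pLeft <- stats::plogis(eta - shift)
  withSeed(seed, {
    c(err_right = stats::rbinom(1, config@trialsPerHand, pRight),
      err_left = stats::rbinom(1, config@trialsPerHand, pLeft))
  })
}

#' Synthetic cohort
#'
#' Container for one full phantom cohort: the shared brain mask, the
#' activation volumes and hand labels, the bilateral tracings and tissue
#' segmentations of the anatomical cohort with their implanted WM
#' asymmetries, and the behavioral error-count table.
#'
#' @slot brainMask shared [BrainMask].
#' @slot pet list of [ScalarVolume] activation volumes.
#' @slot hands character hand label per activation subject.
#' @slot tracings list of [BrainMask] tracings.
#' @slot segmentations list of [TissueLabels].
#' @slot wmAsym numeric implanted WM asymmetry quotient per atlas subject.
#' @slot behavior data.frame: subject, sex, err_right, err_left, trials.
#' @slot config the generating [PhantomConfig].
#' @slot seed integer master seed.
#' @seealso [simulateCohort()]
#' @exportClass SyntheticCohort
setClass("SyntheticCohort", representation(
  brainMask = "BrainMask",
  pet = "list",
  hands = "character",
  tracings = "list",
  segmentations = "list",
  wmAsym = "numeric",
  behavior = "data.frame",
  config = "PhantomConfig",
  seed = "integer"
))

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf(
    "SyntheticCohort: %d activation subjects, %d atlas subjects (seed %d)\n",
    length(object@pet), length(object@tracings), object@seed))
  invisible(NULL)
})

#' Simulate a full phantom cohort
#'
#' Generates the brain mask, per-subject activation volumes, tracings,
#' segmentations and behavior table from one master seed. Each subject
#' draws from an independent substream derived from the master seed, so
#' enlarging the cohort never perturbs earlier subjects, and the whole
#' cohort is reproduced exactly by the same seed.
#'
#' @param config a [PhantomConfig].
#' @param seed integer master seed.
#' @return A [SyntheticCohort].
#' @examples
#' cohort <- simulateCohort(phantomConfig(nAtlas = 6L), seed = 1)
#' cohort
#' @export
simulateCohort <- function(config = phantomConfig(), seed = 1L) {
  seed <- as.integer(seed)
  mask <- makeBrainMask(config)
  pet <- lapply(seq_len(config@nPET), function(i)
    makePETSubject(config, config@hands[i], spawnSeed(seed, i, 1L), mask))
  tracings <- vector("list", config@nAtlas)
  segs <- vector("list", config@nAtlas)
  asym <- numeric(config@nAtlas)
  behavior <- data.frame(
    subject = sprintf("S%03d", seq_len(config@nAtlas)),
    sex = character(config@nAtlas),
    err_right = integer(config@nAtlas),
    err_left = integer(config@nAtlas),
    trials = config@trialsPerHand,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(config@nAtlas)) {
    tracings[[i]] <- makeTracing(config, spawnSeed(seed, i, 2L), mask)
    a <- withSeed(spawnSeed(seed, i, 3L),
                  stats::rnorm(1, config@wmAsymEffect, config@wmAsymSD))
    # keep the drawn AQ inside the band where both hemisphere WM
    # probabilities stay within [0, 1 - csfFrac]
    aMax <- min(2, 2 * ((1 - config@csfFrac) / config@wmBase - 1)) * 0.999
    a <- max(-aMax, min(aMax, a))
    asym[i] <- a
    segs[[i]] <- makeSegmentation(config, tracings[[i]],
                                  spawnSeed(seed, i, 4L), asym = a,
                                  brainMask = mask)
    err <- makeBehavior(config, a, spawnSeed(seed, i, 5L))
    behavior$err_right[i] <- err[["err_right"]]
    behavior$err_left[i] <- err[["err_left"]]
    behavior$sex[i] <- withSeed(spawnSeed(seed, i, 6L),
                                sample(c("F", "M"), 1, prob = c(0.69, 0.31)))
  }
  new("SyntheticCohort", brainMask = mask, pet = pet,
      hands = config@hands, tracings = tracings, segmentations = segs,
      wmAsym = asym, behavior = behavior, config = config, seed = seed)
}
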