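# Synthetic inputs: a layered head phantom, FMISO-like tumour/blood images,
# and fully simulated virtual patients. Every generator is a pure function of
# its configuration and seed, so the whole pipeline is testable without any
# clinical images.

#' Generate a layered ellipsoidal head phantom
#'
#' An idealised digital head: an ellipsoidal grey-matter cortex shell over a
#' white-matter interior containing two CSF ventricles, with fractional
#' (partial-volume) blending over a one-voxel ramp at every interface. The
#' geometry is deterministic; the seed is accepted for interface uniformity
#' with the stochastic generators.
#'
#' @param shape voxel counts, numeric(3); at least ~16 voxels per axis so the
#'   layers fit.
#' @param spacing voxel size in mm, scalar or numeric(3).
#' @param headFrac ellipsoid semi-axes as a fraction of the half grid extent.
#' @param cortexThickness grey-matter shell thickness, mm.
#' @param ventricleRadii semi-axes of each ventricle, mm.
#' @param ventricleSep distance between ventricle centres along x, mm.
#' @param seed unused (deterministic geometry); kept for API symmetry.
#' @return a [TissueMap-class].
#' @examples
#' tm <- makePhantom(shape = c(32, 32, 32))
#' @export
makePhantom <- function(shape = c(96, 96, 96), spacing = c(1, 1, 1),
                        headFrac = 0.92, cortexThickness = 7,
                        ventricleRadii = c(6, 10, 6), ventricleSep = 16,
                        seed = NULL) {
  shape <- as.integer(shape)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  a <- headFrac * shape * spacing / 2       # semi-axes, mm
  if (min(a) <= cortexThickness + 2)
    stop("grid too small: the head cannot contain cortex and interior layers")
  centre <- shape * spacing / 2
  xs <- (seq_len(shape[1]) - 0.5) * spacing[1] - centre[1]
  ys <- (seq_len(shape[2]) - 0.5) * spacing[2] - centre[2]
  zs <- (seq_len(shape[3]) - 0.5) * spacing[3] - centre[3]

  ellipDepth <- function(cx, cy, cz, ax, ay, az) {
    # approximate signed depth (mm) inside the ellipsoid surface
    u <- sqrt(outer(outer((xs - cx)^2 / ax^2, (ys - cy)^2 / ay^2, `+`),
                    (zs - cz)^2 / az^2, `+`))
    (1 - u) * mean(c(ax, ay, az))
  }
  ramp <- function(d) pmin(pmax(d + 0.5, 0), 1)   # one-voxel linear blend

  inHead <- ramp(ellipDepth(0, 0, 0, a[1], a[2], a[3]))
  inCore <- ramp(ellipDepth(0, 0, 0, a[1] - cortexThickness,
                            a[2] - cortexThickness, a[3] - cortexThickness))
  vr <- ventricleRadii
  inVent <- pmax(
    ramp(ellipDepth(-ventricleSep / 2, 0, 0, vr[1], vr[2], vr[3])),
    ramp(ellipDepth(ventricleSep / 2, 0, 0, vr[1], vr[2], vr[3])))

  white <- inHead * inCore * (1 - inVent)
  grey <- inHead * (1 - inCore)
  csf <- inHead * inCore * inVent
  tissueMap(grey, white, csf, spacing)
}

#' Generate a synthetic FMISO-like tumour/blood ratio image
#'
#' Background T/B over the brain is a tissue-structured mixture of lognormals:
#' each voxel gets a composition-weighted tissue level (grey above white above
#' CSF, as in FMISO uptake) multiplied by lognormal noise, with the tissue
#' contrast and noise scale solved at run time so the brain-wide mean and
#' standard deviation match the requested targets exactly in expectation. The
#' background is right-skewed and non-normal, while its upper tail stays
#' almost entirely below the hypoxia threshold, which is what makes the
#' region-restricted hypoxic-volume definition meaningful (see the methods
#' vignette for why a single moment-matched lognormal cannot do this).
#'
#' A contiguous focal hypoxic lesion at `focusLevel` is placed at the boundary
#' of the dense tumour core (the `tumourMask` surface, i.e. the bulk/edge
#' interface) and sized to cover `focusFraction` of the tumour mask volume, so
#' it spans bulk and infiltrative edge.
#'
#' @param tissue a [TissueMap-class].
#' @param tumourMask 3D logical bulk-tumour (T1Gd-like) mask; required when
#'   `focusFraction > 0`.
#' @param bgMean,bgSd target brain-wide background mean and SD of T/B.
#' @param focusLevel T/B value of the hypoxic lesion (>= 1.2 to create
#'   hypoxia).
#' @param focusFraction lesion size as a fraction of the tumour mask volume,
#'   in \[0, 1\].
#' @param focusCentre optional voxel index of the lesion centre; default a
#'   deterministic voxel on the tumour mask surface.
#' @param noiseCV target lognormal noise coefficient of variation for the
#'   parenchyma (the remaining variance is carried by tissue contrast).
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return a [TBImage-class] (blood activity 1; values are ratios).
#' @export
makeTBMap <- function(tissue, tumourMask = NULL, bgMean = 0.813,
                      bgSd = 0.223, focusLevel = 1.52, focusFraction = 0.13,
                      focusCentre = NULL, noiseCV = 0.02, seed = NULL) {
  stopifnot(is(tissue, "TissueMap"))
  if (focusFraction < 0 || focusFraction > 1)
    stop("focusFraction must lie in [0, 1]")
  if (focusFraction > 0 && (is.null(tumourMask) || !any(tumourMask)))
    stop("a non-empty tumour mask is required to place a hypoxic lesion")
  if (focusFraction > 0 && focusLevel < 1.2)
    warning("focusLevel below 1.2 will not create hypoxia at the standard threshold")
  if (!is.null(seed)) set.seed(seed)

  fsum <- tissue@grey + tissue@white + tissue@csf
  brain <- fsum > 0.5
  nBrain <- sum(brain)
  if (nBrain == 0) stop("phantom contains no brain voxels")

  # composition-weighted relative tissue levels (grey > white >> CSF); the
  # brain-wide variance target must be carried by tissue contrast (shrunk by
  # gamma below), not by heavy-tailed voxel noise, and the low-uptake CSF
  # compartment supplies enough spread that grey matter stays well below the
  # hypoxia threshold
  rel <- c(grey = 1.15, white = 0.75, csf = 0.08)
  L <- (rel["grey"] * tissue@grey + rel["white"] * tissue@white +
        rel["csf"] * tissue@csf) / pmax(fsum, 1e-12)
  Lb <- L[brain]
  Lb <- Lb * (bgMean / mean(Lb))            # exact mean match
  varL <- mean((Lb - bgMean)^2)

  # split the target variance between tissue contrast (gamma) and noise (cv):
  # stretch or shrink the levels about the mean to carry the variance at the
  # requested noise scale, but never let any tissue level approach the
  # hypoxia threshold; any variance the capped contrast cannot carry falls
  # back into the noise
  levelCap <- 1.10
  needVar <- (bgSd^2 + bgMean^2) / (1 + noiseCV^2) - bgMean^2
  gammaRaw <- if (varL > 0) sqrt(max(needVar, 0) / varL) else 0
  gammaCap <- if (max(Lb) > bgMean)
    (levelCap - bgMean) / (max(Lb) - bgMean) else Inf
  gamma <- min(gammaRaw, gammaCap)
  cv <- sqrt(max((bgSd^2 + bgMean^2) / (bgMean^2 + gamma^2 * varL) - 1, 0))
  Lb <- pmax(bgMean + gamma * (Lb - bgMean), 0.05)

  sl <- sqrt(log(1 + cv^2))
  noise <- stats::rlnorm(nBrain, meanlog = -sl^2 / 2, sdlog = sl)
  vals <- array(0, dim(tissue))
  vals[brain] <- Lb * noise

  if (focusFraction > 0) {
    nFocus <- max(1L, round(focusFraction * sum(tumourMask)))
    if (is.null(focusCentre)) {
      surf <- which(surfaceVoxels(tumourMask), arr.ind = TRUE)
      focusCentre <- surf[which.max(surf[, 1]), ]   # deterministic pick
    }
    co <- .maskCoords(brain, tissue@spacing)
    cc <- (as.numeric(focusCentre) - 0.5) * tissue@spacing
    d2 <- (co[, 1] - cc[1])^2 + (co[, 2] - cc[2])^2 + (co[, 3] - cc[3])^2
    pick <- which(brain)[order(d2)[seq_len(min(nFocus, nBrain))]]
    vals[pick] <- focusLevel
  }
  new("TBImage", values = vals, bloodActivity = 1, spacing = tissue@spacing)
}

# grow a seeded tumour until the virtual bulk (T1Gd) volume reaches target;
# returns the density field at the first chunk end meeting it
.growToVolume <- function(diffusion, growth, init, targetVolume, thresholds,
                          maxDays = 3000, coarseChunk = 10, fineChunk = 2) {
  state <- init
  repeat {
    vol <- virtualMRI(state, "T1Gd", thresholds)@volume
    if (vol >= targetVolume) return(state)
    if (state@time - init@time > maxDays)
      stop("target tumour volume unreachable within the allowed growth time")
    chunk <- if (vol > 0.6 * targetVolume) fineChunk else coarseChunk
    state <- finalField(simulateGrowth(diffusion, growth, state, tSpan = chunk))
  }
}

#' Generate a virtual glioblastoma patient
#'
#' Builds a complete, fully known test subject: a head phantom; a tumour
#' seeded as a single voxel of cells and grown under ground-truth (D, rho)
#' until the virtual bulk-tumour (T1Gd) volume reaches `targetVolume`; two
#' pre-treatment observation pairs separated by `preInterval` days (the clock
#' is aligned so the first MRI is day 0); a two-phase conformal dose plan
#' built from the second MRI's masks and starting `rtDelay` days after it; a
#' synthetic T/B image whose focal hypoxic lesion covers `tbFocusFraction` of
#' the diagnostic bulk tumour; and post-treatment observations `postDelay`
#' days after the final fraction, simulated under the ground-truth
#' radiosensitivity with the ground-truth OER applied inside the hypoxic
#' volume. All outputs are reproducible from `seed`.
#'
#' @param D,rho ground-truth invasion (mm^2/year, white matter) and
#'   proliferation (1/year) rates.
#' @param alpha,alphaBeta ground-truth radiosensitivity (1/Gy) and fixed
#'   alpha/beta ratio (Gy). `alpha = 0` yields an untreated continuation.
#' @param oer ground-truth OER applied inside the hypoxic volume, in \[1, 3\].
#' @param targetVolume diagnostic bulk-tumour volume, cm^3.
#' @param preInterval days between the two pre-treatment MRIs.
#' @param rtDelay days from the second MRI to the first fraction.
#' @param postDelay days from the final fraction to the post-treatment MRI.
#' @param shape,spacing phantom grid.
#' @param seedDensityFrac initial single-voxel density as a fraction of K.
#' @param seedLocation voxel index of the seed; default an off-centre
#'   white-matter voxel.
#' @param thresholds imaging detection thresholds, fractions of K.
#' @param tbFocusLevel,tbFocusFraction,tbThreshold T/B image parameters, see
#'   [makeTBMap()].
#' @param regionMargin margin (mm) of the T2 region used to delineate the
#'   hypoxic volume.
#' @param marginPrimary,marginBoost clinical target margins, mm.
#' @param seed integer RNG seed.
#' @return a [VirtualPatient-class].
#' @export
makeVirtualPatient <- function(D = 12.84, rho = 13.82, alpha = 0.055,
                               alphaBeta = 10, oer = 2.5,
                               targetVolume = 18.8, preInterval = 13,
                               rtDelay = 5, postDelay = 3,
                               shape = c(96, 96, 96), spacing = 1,
                               seedDensityFrac = 0.8, seedLocation = NULL,
                               thresholds = detectionThresholds(),
                               tbFocusLevel = 1.52, tbFocusFraction = 0.13,
                               tbThreshold = 1.2, regionMargin = 20,
                               marginPrimary = 25, marginBoost = 20,
                               seed = 1) {
  set.seed(seed)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  tissue <- makePhantom(shape = shape, spacing = spacing)
  diffusion <- buildDiffusionMap(tissue, D)
  growth <- growthParams(Dw = D, rho = rho)
  rt <- radiosensitivity(alpha, alphaBeta)

  if (is.null(seedLocation)) {  # off-centre, snapped into white matter
    cand <- round(dim(tissue) / 2 + c(0.10, 0.10, 0.08) * dim(tissue))
    white <- which(tissue@white > 0.5 & diffusion@domain, arr.ind = TRUE)
    d2 <- colSums((t(white) - cand)^2)
    seedLocation <- white[which.min(d2), ]
  }
  init <- seedInitialCondition(diffusion, seedLocation,
                               seedDensityFrac * growth@K, K = growth@K,
                               time = 0)

  state1 <- .growToVolume(diffusion, growth, init, targetVolume, thresholds)
  # align the clock: first MRI is day 0
  shift <- state1@time
  state1 <- initialize(state1, time = 0)
  obs1 <- list(virtualMRI(state1, "T1Gd", thresholds),
               virtualMRI(state1, "T2", thresholds))
  state2 <- finalField(simulateGrowth(diffusion, growth, state1,
                                      tSpan = preInterval))
  obs2 <- list(virtualMRI(state2, "T1Gd", thresholds),
               virtualMRI(state2, "T2", thresholds))
  stateRT <- if (rtDelay > 0)
    finalField(simulateGrowth(diffusion, growth, state2, tSpan = rtDelay))
  else state2

  plan <- buildConformalPlan(obs2[[2]]@mask, obs2[[1]]@mask,
                             marginPrimary = marginPrimary,
                             marginBoost = marginBoost,
                             startDate = stateRT@time, spacing = spacing)

  tb <- makeTBMap(tissue, tumourMask = obs1[[1]]@mask,
                  focusLevel = tbFocusLevel, focusFraction = tbFocusFraction,
                  seed = NULL)
  region <- dilateMask(obs2[[2]]@mask, regionMargin, spacing)
  hv <- hypoxicVolume(tb, region, tbThreshold)
  oerMap <- buildOERMap(hv$mask, oer, threshold = tbThreshold,
                        spacing = spacing)

  postTime <- max(fractionDays(plan)) + postDelay
  sim <- simulateGrowth(diffusion, growth, stateRT,
                        tSpan = postTime - stateRT@time,
                        outputTimes = postTime, plan = plan, oerMap = oerMap,
                        rt = rt)
  final <- finalField(sim)
  obsPost <- list(virtualMRI(final, "T1Gd", thresholds),
                  virtualMRI(final, "T2", thresholds))

  cfg <- list(D = D, rho = rho, alpha = alpha, alphaBeta = alphaBeta,
              oer = oer, targetVolume = targetVolume,
              preInterval = preInterval, rtDelay = rtDelay,
              postDelay = postDelay, shape = shape, spacing = spacing,
              seedDensityFrac = seedDensityFrac, seedLocation = seedLocation,
              tbFocusLevel = tbFocusLevel, tbFocusFraction = tbFocusFraction,
              tbThreshold = tbThreshold, regionMargin = regionMargin,
              marginPrimary = marginPrimary, marginBoost = marginBoost,
              growthShiftDays = shift)
  new("VirtualPatient", tissue = tissue, diffusion = diffusion,
      growth = growth, rt = rt, oerValue = oer, oerMap = oerMap, tb = tb,
      plan = plan, obsPre = c(obs1, obs2), obsPost = obsPost,
      stateAtRTStart = stateRT, postTime = postTime,
      thresholds = thresholds, seed = seed, config = cfg)
}
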