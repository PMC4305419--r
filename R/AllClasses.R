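#' @import methods
NULL

# -- internal grid helpers ----------------------------------------------------

.is3dArray <- function(x) is.array(x) && length(dim(x)) == 3L

.checkSpacing <- function(spacing) {
  if (!is.numeric(spacing) || length(spacing) != 3L || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    return("voxel spacing must be three positive finite numbers (mm)")
  NULL
}

.sameGrid <- function(a, b) identical(dim(a), dim(b))

.stopIfGridMismatch <- function(...) {
  ds <- lapply(list(...), dim)
  ok <- vapply(ds[-1], identical, logical(1), ds[[1]])
  if (!all(ok)) stop("inputs are not defined on a common voxel grid", call. = FALSE)
  invisible(TRUE)
}

#' TissueMap: voxelised brain tissue composition
#'
#' Per-voxel grey-matter, white-matter and CSF fractions on a regular 3D grid,
#' playing the role of a digital brain phantom. Fractions are in \[0, 1\] and
#' sum to at most 1 per voxel; any remainder is background (outside the head).
#' The map is the source of the spatially varying invasion rate and of the
#' simulation domain: tumour cells migrate through grey and white matter but
#' not through CSF or background.
#'
#' @slot grey,white,csf 3D numeric arrays of tissue fractions on a common grid.
#' @slot spacing numeric(3), voxel edge lengths in mm (default 1 mm isotropic).
#'
#' @seealso [tissueMap()], [buildDiffusionMap()], [makePhantom()]
#' @export
setClass("TissueMap",
  representation(grey = "array", white = "array", csf = "array",
                 spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!.is3dArray(object@grey) || !.is3dArray(object@white) ||
        !.is3dArray(object@csf))
      return("grey, white and csf must be 3D arrays")
    if (!.sameGrid(object@grey, object@white) ||
        !.sameGrid(object@grey, object@csf))
      msg <- c(msg, "tissue fraction arrays must share one grid")
    sp <- .checkSpacing(object@spacing)
    if (!is.null(sp)) msg <- c(msg, sp)
    tol <- 1e-6
    rng <- range(object@grey, object@white, object@csf)
    if (rng[1] < -tol || rng[2] > 1 + tol)
      msg <- c(msg, "tissue fractions must lie in [0, 1]")
    if (length(msg) == 0 &&
        max(object@grey + object@white + object@csf) > 1 + 1e-4)
      msg <- c(msg, "tissue fractions must sum to at most 1 per voxel")
    if (length(msg)) msg else TRUE
  })

#' Construct a TissueMap
#'
#' @param grey,white,csf 3D arrays of per-voxel tissue fractions.
#' @param spacing voxel size in mm, scalar or numeric(3).
#' @return A [TissueMap-class] object.
#' @examples
#' tm <- tissueMap(array(0, c(4, 4, 4)) + 0.2, array(0.8, c(4, 4, 4)),
#'                 array(0, c(4, 4, 4)))
#' @export
tissueMap <- function(grey, white, csf, spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("TissueMap", grey = grey, white = white, csf = csf,
      spacing = as.numeric(spacing))
}

#' DiffusionField: spatially varying tumour cell motility
#'
#' The invasion-rate field D(x) (mm^2 per year) derived from a [TissueMap-class]
#' together with the simulation domain mask. White matter motility is 100 times
#' the grey matter motility; CSF and background carry D = 0 and act as no-flux
#' obstacles.
#'
#' @slot values 3D array, D(x) in mm^2/year; zero off-domain.
#' @slot domain 3D logical array; voxels where tumour cells may exist.
#' @slot Dw,Dg white/grey matter motility scalars (mm^2/year), `Dw == 100 * Dg`.
#' @slot spacing numeric(3) voxel size in mm.
#' @export
setClass("DiffusionField",
  representation(values = "array", domain = "array", Dw = "numeric",
                 Dg = "numeric", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!.is3dArray(object@values) || !.is3dArray(object@domain) ||
        !.sameGrid(object@values, object@domain))
      return("values and domain must be 3D arrays on one grid")
    if (!is.logical(object@domain)) msg <- c(msg, "domain must be logical")
    if (min(object@values) < 0) msg <- c(msg, "D(x) must be non-negative")
    if (any(object@values[!object@domain] != 0))
      msg <- c(msg, "D(x) must vanish outside the domain")
    if (abs(object@Dw - 100 * object@Dg) > 1e-9 * max(object@Dw, 1))
      msg <- c(msg, "white:grey motility ratio must be exactly 100")
    sp <- .checkSpacing(object@spacing)
    if (!is.null(sp)) msg <- c(msg, sp)
    if (length(msg)) msg else TRUE
  })

#' GrowthParams: net proliferation and invasion rates
#'
#' @slot Dw white-matter invasion rate (mm^2/year).
#' @slot rho net proliferation rate (1/year).
#' @slot K carrying capacity (cells/mm^3).
#' @slot cellDiameter nominal tumour cell diameter (micrometres) from which the
#'   default K is derived via close packing of spheres, K = 1/((4/3) pi (d/2)^3).
#' @export
setClass("GrowthParams",
  representation(Dw = "numeric", rho = "numeric", K = "numeric",
                 cellDiameter = "numeric"),
  validity = function(object) {
    if (object@Dw < 0) return("Dw must be non-negative")
    if (object@rho < 0) return("rho must be non-negative")
    if (object@K <= 0) return("carrying capacity must be positive")
    if (object@cellDiameter <= 0) return("cell diameter must be positive")
    TRUE
  })

#' Carrying capacity from cell diameter
#'
#' Maximum cell density of tissue assuming cells are spheres of the given
#' diameter: `K = 1 / ((4/3) * pi * (d/2)^3)` in cells per mm^3. For the
#' default 10 micrometre glioma cell this is 1.91e6 cells/mm^3.
#'
#' @param cellDiameter cell diameter in micrometres.
#' @return carrying capacity in cells/mm^3.
#' @examples
#' carryingCapacity()        # 1.91e6 cells/mm^3
#' @export
carryingCapacity <- function(cellDiameter = 10) {
  if (!is.numeric(cellDiameter) || cellDiameter <= 0)
    stop("cellDiameter must be positive (micrometres)")
  d_mm <- cellDiameter / 1000
  1 / ((4 / 3) * pi * (d_mm / 2)^3)
}

#' Construct growth parameters
#'
#' @param Dw white-matter invasion rate, mm^2/year.
#' @param rho net proliferation rate, 1/year.
#' @param K carrying capacity, cells/mm^3; defaults to
#'   [carryingCapacity()]`(cellDiameter)`.
#' @param cellDiameter nominal cell diameter in micrometres.
#' @return A [GrowthParams-class] object.
#' @export
growthParams <- function(Dw, rho, K = NULL, cellDiameter = 10) {
  if (is.null(K)) K <- carryingCapacity(cellDiameter)
  new("GrowthParams", Dw = Dw, rho = rho, K = K, cellDiameter = cellDiameter)
}

#' RadiosensitivityParams: linear-quadratic dose-response parameters
#'
#' The alpha/beta ratio is held fixed (10 Gy for tumour tissue) so that alpha
#' alone characterises patient-specific radiosensitivity; beta is derived as
#' `alpha / alphaBeta`.
#'
#' @slot alpha linear sensitivity, 1/Gy.
#' @slot alphaBeta alpha/beta ratio, Gy.
#' @export
setClass("RadiosensitivityParams",
  representation(alpha = "numeric", alphaBeta = "numeric"),
  validity = function(object) {
    if (object@alpha < 0) return("alpha must be non-negative (1/Gy)")
    if (object@alphaBeta <= 0) return("alpha/beta ratio must be positive (Gy)")
    TRUE
  })

#' Construct radiosensitivity parameters
#'
#' @param alpha linear LQ coefficient, 1/Gy.
#' @param alphaBeta alpha/beta ratio in Gy (default 10, tumour tissue).
#' @return A [RadiosensitivityParams-class] object.
#' @export
radiosensitivity <- function(alpha, alphaBeta = 10) {
  new("RadiosensitivityParams", alpha = alpha, alphaBeta = alphaBeta)
}

#' CellDensityField: tumour cell density c(x, t)
#'
#' @slot values 3D array, cells/mm^3, bounded by the carrying capacity.
#' @slot time time stamp in days from the simulation origin.
#' @slot K carrying capacity, cells/mm^3.
#' @slot spacing numeric(3) voxel size in mm.
#' @export
setClass("CellDensityField",
  representation(values = "array", time = "numeric", K = "numeric",
                 spacing = "numeric"),
  validity = function(object) {
    if (!.is3dArray(object@values)) return("values must be a 3D array")
    if (object@K <= 0) return("carrying capacity must be positive")
    tol <- 1e-6 * object@K
    rng <- range(object@values)
    if (rng[1] < -tol || rng[2] > object@K + tol)
      return("cell density must lie in [0, K]")
    sp <- .checkSpacing(object@spacing)
    if (!is.null(sp)) return(sp)
    TRUE
  })

#' DosePlan: spatio-temporal radiotherapy dose delivery
#'
#' An ordered list of phases; each phase carries a per-fraction dose grid (Gy
#' per voxel per fraction) and the days on which its fractions are delivered.
#' `dose(x, t)` is nonzero only at fraction days.
#'
#' @slot phases list of phases, each a list with elements `dose` (3D array,
#'   Gy/fraction), `days` (numeric, strictly increasing) and `label`.
#' @slot spacing numeric(3) voxel size in mm.
#' @seealso [buildConformalPlan()], [doseAt()], [cumulativeDose()]
#' @export
setClass("DosePlan",
  representation(phases = "list", spacing = "numeric"),
  validity = function(object) {
    if (length(object@phases) == 0) return("a plan needs at least one phase")
    dims <- NULL
    lastDay <- -Inf
    for (ph in object@phases) {
      if (!all(c("dose", "days") %in% names(ph)))
        return("each phase needs 'dose' and 'days'")
      if (!.is3dArray(ph$dose)) return("phase dose must be a 3D array")
      if (min(ph$dose) < 0) return("per-fraction dose must be non-negative")
      if (is.null(dims)) dims <- dim(ph$dose)
      if (!identical(dims, dim(ph$dose)))
        return("all phase dose grids must share one grid")
      if (length(ph$days) == 0 || any(diff(ph$days) <= 0))
        return("fraction days must be strictly increasing within a phase")
      if (ph$days[1] <= lastDay)
        return("fraction days must be strictly increasing across phases")
      lastDay <- ph$days[length(ph$days)]
    }
    sp <- .checkSpacing(object@spacing)
    if (!is.null(sp)) return(sp)
    TRUE
  })

#' TBImage: FMISO-PET tumour-to-blood ratio image
#'
#' Voxel tracer activity scaled by the mean venous blood activity. Values at or
#' above the hypoxia threshold (1.2 by convention) mark hypoxic tissue.
#'
#' @slot values 3D array of T/B ratios (dimensionless, >= 0).
#' @slot bloodActivity the scalar blood activity used for scaling.
#' @slot spacing numeric(3) voxel size in mm.
#' @export
setClass("TBImage",
  representation(values = "array", bloodActivity = "numeric",
                 spacing = "numeric"),
  validity = function(object) {
    if (!.is3dArray(object@values)) return("values must be a 3D array")
    if (min(object@values) < 0) return("T/B ratios must be non-negative")
    if (object@bloodActivity <= 0) return("blood activity must be positive")
    sp <- .checkSpacing(object@spacing)
    if (!is.null(sp)) return(sp)
    TRUE
  })

#' OERMap: binary spatial oxygen enhancement ratio field
#'
#' OER equals `oerValue` inside the hypoxic mask and 1 elsewhere. Values are
#' restricted to \[1, 3\]: 1 means no hypoxic protection, 3 the maximum
#' clinically plausible resistance.
#'
#' @slot mask 3D logical array, the hypoxic volume.
#' @slot oerValue scalar OER applied on the mask, in \[1, 3\].
#' @slot threshold the T/B threshold that defined the mask (bookkeeping).
#' @slot spacing numeric(3) voxel size in mm.
#' @export
setClass("OERMap",
  representation(mask = "array", oerValue = "numeric", threshold = "numeric",
                 spacing = "numeric"),
  validity = function(object) {
    if (!.is3dArray(object@mask) || !is.logical(object@mask))
      return("mask must be a 3D logical array")
    if (object@oerValue < 1 || object@oerValue > 3)
      return("OER must lie in [1, 3]")
    sp <- .checkSpacing(object@spacing)
    if (!is.null(sp)) return(sp)
    TRUE
  })

#' Observation: a dated tumour segmentation with derived size measures
#'
#' Holds a binary tumour mask for one MRI sequence on one date together with
#' the slice-summed volume `V = sum(A_i * dz_i)` and the radius of the sphere
#' of equivalent volume.
#'
#' @slot date acquisition day (days from the study origin).
#' @slot sequence MRI sequence label, `"T1Gd"` or `"T2"`.
#' @slot mask 3D logical array.
#' @slot spacing numeric(3) voxel size in mm.
#' @slot sliceAreas per-axial-slice tumour areas A_i in mm^2.
#' @slot volume tumour volume in cm^3.
#' @slot radius equivalent spherical radius in mm.
#' @seealso [observation()], [virtualMRI()], [volumeFromMask()]
#' @export
setClass("Observation",
  representation(date = "numeric", sequence = "character", mask = "array",
                 spacing = "numeric", sliceAreas = "numeric",
                 volume = "numeric", radius = "numeric"),
  validity = function(object) {
    if (!.is3dArray(object@mask) || !is.logical(object@mask))
      return("mask must be a 3D logical array")
    if (!object@sequence %in% c("T1Gd", "T2"))
      return("sequence must be 'T1Gd' or 'T2'")
    if (object@volume < 0) return("volume must be non-negative")
    sp <- .checkSpacing(object@spacing)
    if (!is.null(sp)) return(sp)
    TRUE
  })

#' SimilarityReport: voxel-wise and surface model-data agreement
#'
#' @slot tp,fp,fn,tn confusion counts within the evaluation region.
#' @slot ppv,sensitivity,specificity,jaccard,volumeSimilarity ratio metrics in
#'   \[0, 1\]; `NA` where the defining ratio is 0/0.
#' @export
setClass("SimilarityReport",
  representation(tp = "numeric", fp = "numeric", fn = "numeric", tn = "numeric",
                 ppv = "numeric", sensitivity = "numeric",
                 specificity = "numeric", jaccard = "numeric",
                 volumeSimilarity = "numeric"))

#' PatientParameters: patient-specific model parameter set
#'
#' @slot D net invasion rate, mm^2/year (interpreted as the white-matter rate
#'   when `dIsWhite = TRUE`, the convention used throughout).
#' @slot rho net proliferation rate, 1/year.
#' @slot lambda infiltration length sqrt(D/rho), mm.
#' @slot velocity supplied radial growth velocity, cm/year.
#' @slot velocityImplied Fisher velocity 2*sqrt(D*rho) implied by (D, rho),
#'   cm/year. Reported alongside `velocity`; the two are never silently
#'   reconciled.
#' @slot alpha radiosensitivity, 1/Gy (NA until calibrated).
#' @slot alphaBeta alpha/beta ratio, Gy.
#' @export
setClass("PatientParameters",
  representation(D = "numeric", rho = "numeric", lambda = "numeric",
                 velocity = "numeric", velocityImplied = "numeric",
                 alpha = "numeric", alphaBeta = "numeric"))

#' SimulationResult: time series of simulated cell density fields
#'
#' @slot fields list of [CellDensityField-class] snapshots at `times`.
#' @slot times snapshot times in days.
#' @slot dt the time step actually used (days).
#' @slot steps number of explicit steps taken.
#' @slot clampedMass total negative round-off mass clamped to zero (cells).
#' @export
setClass("SimulationResult",
  representation(fields = "list", times = "numeric", dt = "numeric",
                 steps = "numeric", clampedMass = "numeric"))

#' ScenarioResult: outcome of one forward treatment simulation
#'
#' @slot label scenario label, `"uniform"` or `"OER=<value>"`.
#' @slot oerValue the OER applied inside the hypoxic volume (1 for uniform).
#' @slot preCells,postCells total tumour cell number at the start of
#'   radiotherapy and at the evaluation time.
#' @slot percentKilled 100 * (1 - postCells/preCells).
#' @slot survivalRatio postCells relative to the uniform-sensitivity run.
#' @slot postObs list of virtual post-treatment observations (T1Gd, T2).
#' @slot radiusErrors named numeric: relative (%) and absolute (mm) equivalent
#'   radius errors versus the supplied truth, `NA` when no truth was given.
#' @export
setClass("ScenarioResult",
  representation(label = "character", oerValue = "numeric",
                 preCells = "numeric", postCells = "numeric",
                 percentKilled = "numeric", survivalRatio = "numeric",
                 postObs = "list", radiusErrors = "numeric"))

#' VirtualPatient: a fully synthetic, fully known test subject
#'
#' Bundles everything the pipeline consumes for one patient -- anatomy,
#' ground-truth growth and response parameters, serial pre- and post-treatment
#' observations, dose plan, T/B image and hypoxic mask -- generated by
#' [makeVirtualPatient()] so that the observations are exact model output
#' under the stored parameters and every slot is reproducible from the seed.
#'
#' @slot tissue [TissueMap-class] phantom.
#' @slot diffusion [DiffusionField-class] derived from it.
#' @slot growth ground-truth [GrowthParams-class].
#' @slot rt ground-truth [RadiosensitivityParams-class].
#' @slot oerValue ground-truth OER applied during the treatment simulation.
#' @slot oerMap [OERMap-class] used for the ground-truth treatment run.
#' @slot tb [TBImage-class] synthetic FMISO-PET tumour/blood image.
#' @slot plan [DosePlan-class].
#' @slot obsPre,obsPost lists of [Observation-class] (T1Gd and T2 at each date).
#' @slot stateAtRTStart [CellDensityField-class] at the first fraction day.
#' @slot postTime evaluation day of the post-treatment observations.
#' @slot thresholds named numeric imaging detection thresholds (fractions of K).
#' @slot seed integer RNG seed that reproduces the object.
#' @slot config the resolved generator configuration (list).
#' @export
setClass("VirtualPatient",
  representation(tissue = "TissueMap", diffusion = "DiffusionField",
                 growth = "GrowthParams", rt = "RadiosensitivityParams",
                 oerValue = "numeric", oerMap = "OERMap", tb = "TBImage",
                 plan = "DosePlan", obsPre = "list", obsPost = "list",
                 stateAtRTStart = "CellDensityField", postTime = "numeric",
                 thresholds = "numeric", seed = "numeric", config = "list"))
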