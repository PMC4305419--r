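# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' Voxel spacing of a gridded object
#' @param x a gridded pirt object.
#' @return numeric(3), voxel edge lengths in mm.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Voxel volume in mm^3
#' @param x a gridded pirt object.
#' @return scalar voxel volume, mm^3.
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname TissueMap-class
#' @param x a `TissueMap`.
#' @export
setGeneric("greyFraction", function(x) standardGeneric("greyFraction"))
#' @rdname TissueMap-class
#' @export
setGeneric("whiteFraction", function(x) standardGeneric("whiteFraction"))
#' @rdname TissueMap-class
#' @export
setGeneric("csfFraction", function(x) standardGeneric("csfFraction"))

#' Raw voxel values of a field-like object
#' @param x a `DiffusionField`, `CellDensityField`, `TBImage` or `OERMap`.
#' @return a 3D numeric array.
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' Simulation domain of a diffusion field
#' @param x a `DiffusionField`.
#' @return 3D logical array of voxels where tumour cells may exist.
#' @export
setGeneric("domainMask", function(x) standardGeneric("domainMask"))

#' Hypoxic mask of an OER map
#' @param x an `OERMap`.
#' @return 3D logical array.
#' @export
setGeneric("hypoxicMask", function(x) standardGeneric("hypoxicMask"))

#' Time stamp (days) of a time-carrying object
#' @param x a `CellDensityField` or `Observation`.
#' @export
setGeneric("timePoint", function(x) standardGeneric("timePoint"))

#' Total cell number of a density field
#' @param x a `CellDensityField`.
#' @return total cells, `sum(c) * voxelVolume`.
#' @export
setGeneric("totalCells", function(x) standardGeneric("totalCells"))

#' Cumulative dose grid of a plan
#' @param x a `DosePlan`.
#' @return 3D array of cumulative dose in Gy.
#' @export
setGeneric("cumulativeDose", function(x) standardGeneric("cumulativeDose"))

#' All fraction days of a plan
#' @param x a `DosePlan`.
#' @return sorted numeric vector of days.
#' @export
setGeneric("fractionDays", function(x) standardGeneric("fractionDays"))

#' Dose grid delivered at a given day
#'
#' Returns the per-fraction dose grid if `t` matches a fraction day of the
#' plan (to within `tol`), otherwise an all-zero grid.
#'
#' @param x a `DosePlan`.
#' @param t day.
#' @param tol day-matching tolerance.
#' @return 3D array of dose in Gy.
#' @export
setGeneric("doseAt", function(x, t, tol = 1e-6) standardGeneric("doseAt"))

#' @rdname Observation-class
#' @param x an `Observation`.
#' @export
setGeneric("obsMask", function(x) standardGeneric("obsMask"))
#' @rdname Observation-class
#' @export
setGeneric("obsVolume", function(x) standardGeneric("obsVolume"))
#' @rdname Observation-class
#' @export
setGeneric("obsRadius", function(x) standardGeneric("obsRadius"))

#' Calibrate the radiosensitivity parameter alpha
#'
#' @param x a `VirtualPatient` or a `CellDensityField` giving the tumour state
#'   at the start of radiotherapy.
#' @param ... passed on to methods.
#' @export
setGeneric("calibrateAlpha", function(x, ...) standardGeneric("calibrateAlpha"))
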