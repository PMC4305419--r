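# Standard-format I/O: NIfTI for rasters, JSON/CSV for tables and reports.
# Internal coordinates are 0-based voxel indices with voxel-centred values;
# voxel size is taken from (and written to) the NIfTI header.

#' Read a 3D NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `values` (3D array) and `spacing` (numeric(3), mm).
#' @export
readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D volume: ", path)
  vals <- array(as.numeric(img), dim(img))   # plain array, no header attrs
  sp <- RNifti::pixdim(img)[1:3]
  list(values = vals, spacing = as.numeric(sp))
}

#' Write a 3D volume as NIfTI
#'
#' @param values 3D numeric or logical array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel size in mm.
#' @return the path, invisibly.
#' @export
writeNiftiVolume <- function(values, path, spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  img <- RNifti::asNifti(array(as.numeric(values), dim(values)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a tissue map from per-class NIfTI volumes
#'
#' @param greyPath,whitePath,csfPath one file per tissue class, co-registered.
#' @return a [TissueMap-class]; voxel size from the header.
#' @export
readTissueMap <- function(greyPath, whitePath, csfPath) {
  g <- readNiftiVolume(greyPath)
  w <- readNiftiVolume(whitePath)
  c_ <- readNiftiVolume(csfPath)
  tissueMap(g$values, w$values, c_$values, spacing = g$spacing)
}

#' Write a density field with a JSON sidecar
#'
#' The sidecar records the time stamp, carrying capacity and voxel size so a
#' snapshot is self-describing.
#'
#' @param field a [CellDensityField-class].
#' @param path output NIfTI path; the sidecar gets extension `.json`.
#' @return the path, invisibly.
#' @export
writeDensityField <- function(field, path) {
  stopifnot(is(field, "CellDensityField"))
  writeNiftiVolume(field@values, path, field@spacing)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(time_days = field@time, K_cells_per_mm3 = field@K,
                            spacing_mm = field@spacing,
                            total_cells = totalCells(field)),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Tabulate observations
#'
#' @param obsList list of [Observation-class].
#' @return data.frame with date, sequence, volume (cm^3) and radius (mm).
#' @export
observationTable <- function(obsList) {
  do.call(rbind, lapply(obsList, function(o)
    data.frame(date = o@date, sequence = o@sequence, V_cm3 = o@volume,
               r_mm = o@radius)))
}

#' Write a calibration report as JSON
#'
#' @param params a [PatientParameters-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCalibrationReport <- function(params, path) {
  stopifnot(is(params, "PatientParameters"))
  jsonlite::write_json(list(
    D_mm2_per_year = params@D, rho_per_year = params@rho,
    invisibility_index_mm2 = params@D / params@rho,
    lambda_mm = params@lambda,
    velocity_supplied_cm_per_year = params@velocity,
    velocity_fisher_cm_per_year = params@velocityImplied,
    alpha_per_Gy = params@alpha, alpha_beta_Gy = params@alphaBeta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
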