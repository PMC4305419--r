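#' Slice-summed tumour volume from a segmentation mask
#'
#' The clinical volumetry convention: each axial slice contributes its tumour
#' pixel count times the pixel area, `A_i`, and the volume is
#' `V = sum(A_i * dz_i)` over slices, reported in cm^3.
#'
#' @param mask 3D logical array (third index = axial slice).
#' @param dz slice thickness in mm, scalar or one value per slice.
#' @param pixelArea in-plane pixel area in mm^2.
#' @return list with `volume_cm3` and `sliceAreas_mm2`.
#' @examples
#' m <- array(FALSE, c(8, 8, 2)); m[1:5, 1:2, 1] <- TRUE; m[1:5, 1:4, 2] <- TRUE
#' volumeFromMask(m, dz = 1, pixelArea = 1)$volume_cm3   # 0.030
#' @export
volumeFromMask <- function(mask, dz = 1, pixelArea = 1) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  nz <- dim(mask)[3]
  if (length(dz) == 1L) dz <- rep(dz, nz)
  if (length(dz) != nz || any(dz <= 0))
    stop("dz must be positive, one value per slice")
  areas <- apply(mask, 3, sum) * pixelArea
  list(volume_cm3 = sum(areas * dz) / 1000, sliceAreas_mm2 = areas)
}

#' Radius of the sphere of equivalent volume
#'
#' @param volume tumour volume in cm^3 (>= 0).
#' @return radius in mm, computed as \eqn{(3V / (4\pi))^{1/3}}.
#' @examples
#' equivalentRadius(18.8)   # ~16.5 mm
#' @export
equivalentRadius <- function(volume) {
  if (any(volume < 0)) stop("volume must be non-negative")
  (3 * volume * 1000 / (4 * pi))^(1 / 3)
}

#' Construct an Observation from a segmentation mask
#'
#' @param mask 3D logical tumour mask.
#' @param date acquisition day.
#' @param sequence `"T1Gd"` or `"T2"`.
#' @param spacing voxel size in mm.
#' @return an [Observation-class] with derived slice areas, volume and
#'   equivalent radius.
#' @export
observation <- function(mask, date = 0, sequence = c("T1Gd", "T2"),
                        spacing = c(1, 1, 1)) {
  sequence <- match.arg(sequence)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  v <- volumeFromMask(mask, dz = spacing[3], pixelArea = spacing[1] * spacing[2])
  new("Observation", date = date, sequence = sequence, mask = mask,
      spacing = as.numeric(spacing), sliceAreas = v$sliceAreas_mm2,
      volume = v$volume_cm3, radius = equivalentRadius(v$volume_cm3))
}

#' Radial growth velocity between two observations
#'
#' Velocity is the change in equivalent spherical radius per unit time,
#' annualised and reported in cm/year, the convention used for serial gross
#' tumour volumes.
#'
#' @param obs1,obs2 [Observation-class] objects of the same sequence, with
#'   `obs2` strictly later.
#' @return velocity in cm/year.
#' @export
growthVelocity <- function(obs1, obs2) {
  stopifnot(is(obs1, "Observation"), is(obs2, "Observation"))
  if (obs1@sequence != obs2@sequence)
    stop("velocity must be computed within one MRI sequence")
  dt <- obs2@date - obs1@date
  if (dt <= 0) stop("observations must be strictly ordered in time")
  (obs2@radius - obs1@radius) / dt * 365 / 10
}

#' Default imaging detection thresholds
#'
#' Densities at which tumour becomes visible on each MRI sequence, as
#' fractions of the carrying capacity: the contrast-enhancing T1Gd abnormality
#' corresponds to high cell density (0.80 K) and the T2/FLAIR abnormality to
#' the low-density infiltrative margin (0.16 K). These are the values used
#' across the proliferation-invasion modelling literature, but they are not
#' universal constants; every derived quantity can be recomputed under
#' user-supplied thresholds.
#'
#' @export
detectionThresholds <- function() c(T1Gd = 0.80, T2 = 0.16)

#' Virtual MRI: threshold a simulated density field into an observation
#'
#' Applies the imaging detection threshold for the requested sequence to the
#' simulated cell density, `mask = c >= theta_seq * K`, and derives volume and
#' equivalent radius. Because `theta_T1Gd > theta_T2`, the virtual T1Gd mask
#' is always contained in the virtual T2 mask.
#'
#' @param field a [CellDensityField-class].
#' @param sequence `"T1Gd"` or `"T2"`.
#' @param thresholds named fractions of K, see [detectionThresholds()].
#' @return an [Observation-class] dated at the field's time stamp.
#' @export
virtualMRI <- function(field, sequence = c("T1Gd", "T2"),
                       thresholds = detectionThresholds()) {
  stopifnot(is(field, "CellDensityField"))
  sequence <- match.arg(sequence)
  theta <- thresholds[[sequence]]
  if (is.null(theta) || theta <= 0 || theta >= 1)
    stop("detection threshold must be a fraction of K in (0, 1)")
  mask <- field@values >= theta * field@K
  observation(mask, date = field@time, sequence = sequence,
              spacing = field@spacing)
}
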