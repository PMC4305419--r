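#' Scale PET activity to a tumour/blood ratio image
#'
#' Divides the voxel tracer activity by the mean venous blood activity,
#' producing the dimensionless T/B ratio on which the hypoxia threshold is
#' defined.
#'
#' @param activity 3D array of tracer activity (any consistent unit).
#' @param bloodActivity scalar mean venous blood activity, same unit; must be
#'   positive.
#' @param spacing voxel size in mm.
#' @return a [TBImage-class].
#' @export
computeTB <- function(activity, bloodActivity, spacing = c(1, 1, 1)) {
  if (!is.numeric(bloodActivity) || length(bloodActivity) != 1L ||
      !is.finite(bloodActivity) || bloodActivity <= 0)
    stop("blood activity must be a positive scalar")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("TBImage", values = activity / bloodActivity,
      bloodActivity = bloodActivity, spacing = spacing)
}

#' Hypoxic volume within a region of interest
#'
#' The hypoxic mask is `T/B >= threshold` (inclusive) intersected with the
#' region mask; restricting to the tumour region (conventionally the T2
#' abnormality with a 2 cm margin) excludes scattered PET noise elsewhere in
#' the brain. The hypoxic volume is the voxel count times the voxel volume.
#'
#' @param tb a [TBImage-class].
#' @param regionMask 3D logical array on the same grid.
#' @param threshold T/B hypoxia threshold, inclusive (default 1.2).
#' @return list with `hv_cm3` (hypoxic volume, cm^3), `mask` (logical array),
#'   and `tb_max` (maximum T/B within the region, `NA` for an empty region).
#' @export
hypoxicVolume <- function(tb, regionMask, threshold = 1.2) {
  stopifnot(is(tb, "TBImage"))
  .stopIfGridMismatch(tb@values, regionMask)
  mask <- (tb@values >= threshold) & regionMask
  hv <- sum(mask) * prod(tb@spacing) / 1000
  tbMax <- if (any(regionMask)) max(tb@values[regionMask]) else NA_real_
  list(hv_cm3 = hv, mask = mask, tb_max = tbMax)
}

#' Regional hypoxic-volume report
#'
#' Tabulates hypoxic volume and maximum T/B for a named list of regions
#' (e.g. T2 + 2 cm, T2 minus T1Gd, T1Gd).
#'
#' @param tb a [TBImage-class].
#' @param regions named list of 3D logical arrays.
#' @param threshold T/B hypoxia threshold.
#' @return data.frame with columns `region`, `hv_cm3`, `tb_max`.
#' @export
hypoxiaReport <- function(tb, regions, threshold = 1.2) {
  rows <- lapply(names(regions), function(nm) {
    h <- hypoxicVolume(tb, regions[[nm]], threshold)
    data.frame(region = nm, hv_cm3 = h$hv_cm3, tb_max = h$tb_max)
  })
  do.call(rbind, rows)
}

#' Build a binary spatial OER map
#'
#' OER equals `oerValue` on the hypoxic mask and 1 elsewhere. Values outside
#' \[1, 3\] are rejected (1 = fully oxygenated response, 3 = maximal hypoxic
#' protection). `oerValue = 1` yields the identity map, i.e. the uniform
#' sensitivity scenario.
#'
#' @param mask 3D logical hypoxic mask.
#' @param oerValue scalar OER in \[1, 3\].
#' @param threshold the T/B threshold that produced the mask (metadata).
#' @param spacing voxel size in mm.
#' @return an [OERMap-class].
#' @export
buildOERMap <- function(mask, oerValue, threshold = 1.2, spacing = c(1, 1, 1)) {
  if (!is.numeric(oerValue) || length(oerValue) != 1L || oerValue < 1 ||
      oerValue > 3)
    stop("OER must be a scalar in [1, 3]")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("OERMap", mask = mask, oerValue = oerValue, threshold = threshold,
      spacing = spacing)
}
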