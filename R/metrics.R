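# Model-data agreement: voxel-wise confusion metrics, equivalent-radius
# errors, and signed surface-distance distributions.

#' Voxel-wise similarity metrics between predicted and observed masks
#'
#' Confusion counts are accumulated within an evaluation region only; with a
#' whole-brain region the metrics are dominated by the huge number of true
#' negatives far from the tumour, so the default region is the union of both
#' masks dilated by 20 mm. Metrics follow the standard definitions:
#' PPV = TP/(TP+FP), sensitivity = TP/(TP+FN), specificity = TN/(FP+TN),
#' Jaccard = TP/(FN+TP+FP), volume similarity = 1 - |FP-FN|/(FP+2TP+FN).
#' Ratios with a zero denominator are reported as `NA` (undefined), never 0.
#'
#' @param predMask,obsMask 3D logical arrays on a common grid, or
#'   [Observation-class] objects.
#' @param evalRegion 3D logical evaluation region; default the union of both
#'   masks dilated by `regionMargin`.
#' @param regionMargin margin (mm) of the default evaluation region.
#' @param spacing voxel size in mm (taken from Observations when given).
#' @return a [SimilarityReport-class].
#' @examples
#' a <- array(FALSE, c(16, 16, 16)); a[5:10, 5:10, 5:10] <- TRUE
#' b <- array(FALSE, c(16, 16, 16)); b[6:11, 5:10, 5:10] <- TRUE
#' confusionMetrics(a, b)
#' @export
confusionMetrics <- function(predMask, obsMask, evalRegion = NULL,
                             regionMargin = 20, spacing = c(1, 1, 1)) {
  if (is(predMask, "Observation")) {
    spacing <- predMask@spacing; predMask <- predMask@mask
  }
  if (is(obsMask, "Observation")) obsMask <- obsMask@mask
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  .stopIfGridMismatch(predMask, obsMask)
  if (is.null(evalRegion))
    evalRegion <- dilateMask(predMask | obsMask, regionMargin, spacing)
  .stopIfGridMismatch(predMask, evalRegion)
  if (!any(evalRegion)) stop("evaluation region is empty")

  p <- predMask[evalRegion]; o <- obsMask[evalRegion]
  tp <- sum(p & o); fp <- sum(p & !o); fn <- sum(!p & o); tn <- sum(!p & !o)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  new("SimilarityReport", tp = tp, fp = fp, fn = fn, tn = tn,
      ppv = ratio(tp, tp + fp),
      sensitivity = ratio(tp, tp + fn),
      specificity = ratio(tn, fp + tn),
      jaccard = ratio(tp, fn + tp + fp),
      volumeSimilarity = if (fp + 2 * tp + fn == 0) NA_real_ else
        1 - abs(fp - fn) / (fp + 2 * tp + fn))
}

#' Equivalent-radius prediction errors
#'
#' @param predObs predicted [Observation-class] (or radius in mm).
#' @param trueObs observed [Observation-class] (or radius in mm).
#' @return named numeric: `relative_pct` = 100 |r_pred - r_obs| / r_obs
#'   (`NA` when r_obs = 0) and `absolute_mm` = |r_pred - r_obs|.
#' @export
radiusErrors <- function(predObs, trueObs) {
  rp <- if (is(predObs, "Observation")) predObs@radius else predObs
  ro <- if (is(trueObs, "Observation")) trueObs@radius else trueObs
  if (is(predObs, "Observation") && is(trueObs, "Observation") &&
      predObs@sequence != trueObs@sequence)
    stop("radius errors must compare observations of the same sequence")
  absErr <- abs(rp - ro)
  c(relative_pct = if (ro == 0) NA_real_ else 100 * absErr / ro,
    absolute_mm = absErr)
}

# chunked nearest-neighbour distances from points a (n x 3) to points b (m x 3)
.nearestDistance <- function(a, b, chunk = 2048L) {
  bb <- rowSums(b^2)
  out <- numeric(nrow(a))
  i <- 1L
  while (i <= nrow(a)) {
    j <- min(i + chunk - 1L, nrow(a))
    ac <- a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(ac^2), bb, `+`) - 2 * ac %*% t(b)
    out[i:j] <- sqrt(pmax(apply(d2, 1, min), 0))
    i <- j + 1L
  }
  out
}

#' Signed distances between predicted and observed tumour surfaces
#'
#' For each voxel on the predicted surface, the Euclidean distance (voxel
#' centre to voxel centre) to the nearest observed-surface voxel, signed
#' positive where the predicted surface lies outside the observed mask (model
#' over-estimates the front) and negative inside it (under-estimation). Exact
#' intersections (distance zero) are excluded from the median and standard
#' deviation but counted separately, so the summary reflects bias and spread
#' of the genuinely separated surface.
#'
#' @param predMask,obsMask non-empty 3D logical arrays (or
#'   [Observation-class]).
#' @param spacing voxel size in mm.
#' @param symmetrized also measure observed-to-predicted distances and pool
#'   the two samples (off by default; the reported direction is
#'   predicted-to-observed).
#' @return list with `median_mm`, `sd_mm`, `zeroCount`, and `distances`
#'   (the full signed nonzero sample). When every surface voxel intersects,
#'   median and SD are reported as 0.
#' @export
surfaceDistance <- function(predMask, obsMask, spacing = c(1, 1, 1),
                            symmetrized = FALSE) {
  if (is(predMask, "Observation")) {
    spacing <- predMask@spacing; predMask <- predMask@mask
  }
  if (is(obsMask, "Observation")) obsMask <- obsMask@mask
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  .stopIfGridMismatch(predMask, obsMask)
  if (!any(predMask) || !any(obsMask))
    stop("surface distances need two non-empty masks")

  signedSample <- function(fromMask, toMask) {
    fromSurf <- surfaceVoxels(fromMask)
    toSurf <- surfaceVoxels(toMask)
    d <- .nearestDistance(.maskCoords(fromSurf, spacing),
                          .maskCoords(toSurf, spacing))
    inside <- toMask[fromSurf]
    sgn <- ifelse(inside, -1, 1)
    d * sgn
  }
  ds <- signedSample(predMask, obsMask)
  if (symmetrized) ds <- c(ds, -signedSample(obsMask, predMask))
  zero <- abs(ds) < 1e-9
  nz <- ds[!zero]
  list(median_mm = if (length(nz)) stats::median(nz) else 0,
       sd_mm = if (length(nz) > 1) stats::sd(nz) else 0,
       zeroCount = sum(zero),
       distances = nz)
}
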