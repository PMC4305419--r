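test_that("confusion metrics reproduce the printed formulas", {
  # engineered grid: TP=3, FP=1, FN=2, TN=10 inside the evaluation region
  pred <- array(FALSE, c(4, 4, 1)); obs <- array(FALSE, c(4, 4, 1))
  pred[1:4, 1, 1] <- TRUE              # 4 predicted
  obs[2:4, 1, 1] <- TRUE; obs[1:2, 2, 1] <- TRUE  # 5 observed
  region <- array(FALSE, c(4, 4, 1)); region[1:4, 1:4, 1] <- TRUE
  r <- confusionMetrics(pred, obs, evalRegion = region)
  expect_equal(c(r@tp, r@fp, r@fn, r@tn), c(3, 1, 2, 10))
  expect_equal(r@ppv, 0.75)
  expect_equal(r@sensitivity, 0.6)
  expect_equal(r@specificity, 10 / 11)
  expect_equal(r@jaccard, 0.5)
  expect_equal(r@volumeSimilarity, 8 / 9)
  expect_equal(r@tp + r@fp + r@fn + r@tn, sum(region))
})

test_that("perfect and degenerate agreement are handled exactly", {
  m <- ballMask(12, c(6, 6, 6), 3)
  r <- confusionMetrics(m, m, regionMargin = 3)
  expect_equal(c(r@ppv, r@sensitivity, r@jaccard, r@volumeSimilarity),
               c(1, 1, 1, 1))
  # empty prediction: PPV undefined (NA), sensitivity and Jaccard zero
  empty <- array(FALSE, dim(m))
  r2 <- confusionMetrics(empty, m, regionMargin = 3)
  expect_true(is.na(r2@ppv))
  expect_equal(r2@sensitivity, 0)
  expect_equal(r2@jaccard, 0)
  expect_error(confusionMetrics(m, m, evalRegion = empty), "empty")
})

test_that("swapping prediction and observation swaps PPV and sensitivity", {
  set.seed(23)
  a <- array(runif(12^3) < 0.2, c(12, 12, 12))
  b <- array(runif(12^3) < 0.2, c(12, 12, 12))
  ab <- confusionMetrics(a, b, regionMargin = 2)
  ba <- confusionMetrics(b, a, regionMargin = 2)
  expect_equal(ab@ppv, ba@sensitivity)
  expect_equal(ab@sensitivity, ba@ppv)
  expect_equal(ab@jaccard, ba@jaccard)
})

test_that("radius errors follow the volumetric-radius definitions", {
  expect_equal(radiusErrors(20.63, 18.0),
               c(relative_pct = 100 * 2.63 / 18, absolute_mm = 2.63))
  expect_equal(radiusErrors(10, 10), c(relative_pct = 0, absolute_mm = 0))
  e <- radiusErrors(5, 0)
  expect_true(is.na(e[["relative_pct"]]))
  expect_equal(e[["absolute_mm"]], 5)
})

test_that("surface distances are signed and zero on intersection", {
  m <- ballMask(24, c(12, 12, 12), 8)
  same <- surfaceDistance(m, m)
  expect_equal(same$median_mm, 0)
  expect_equal(same$sd_mm, 0)
  expect_equal(same$zeroCount, sum(surfaceVoxels(m)))
  # concentric balls: prediction 2 voxels outside the observation
  inner <- ballMask(24, c(12, 12, 12), 6)
  over <- surfaceDistance(m, inner)
  expect_equal(over$median_mm, 2, tolerance = 0.3)
  expect_true(all(over$distances > 0))
  # prediction strictly inside: every distance negative
  under <- surfaceDistance(inner, m)
  expect_true(all(under$distances < 0))
  expect_lt(under$median_mm, 0)
  expect_error(surfaceDistance(array(FALSE, dim(m)), m), "non-empty")
})

test_that("surface distances agree exactly with the brute-force oracle", {
  set.seed(37)
  for (rep in 1:3) {
    a <- dilateMask(array(runif(14^3) < 0.01, c(14, 14, 14)), 2)
    b <- dilateMask(array(runif(14^3) < 0.01, c(14, 14, 14)), 2)
    if (!any(a) || !any(b)) next
    fast <- surfaceDistance(a, b)
    slow <- bruteSurfaceDistance(a, b)
    expect_equal(sort(c(fast$distances, rep(0, fast$zeroCount))),
                 sort(slow), tolerance = 1e-12)
  }
  # anisotropic spacing
  a <- ballMask(10, c(5, 5, 5), 3); b <- ballMask(10, c(6, 5, 5), 3)
  sp <- c(0.5, 1, 2)
  fast <- surfaceDistance(a, b, spacing = sp)
  slow <- bruteSurfaceDistance(a, b, spacing = sp)
  expect_equal(sort(c(fast$distances, rep(0, fast$zeroCount))), sort(slow),
               tolerance = 1e-12)
})
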