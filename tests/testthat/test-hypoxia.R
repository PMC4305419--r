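test_that("T/B scaling is linear in activity and inverse in blood activity", {
  act <- array(runif(4^3, 0, 2), c(4, 4, 4))
  tb <- computeTB(act, 2)
  expect_equal(fieldValues(tb), act / 2)
  expect_equal(fieldValues(computeTB(act * 3, 2)), 3 * fieldValues(tb))
  expect_equal(fieldValues(computeTB(act, 4)), fieldValues(tb) / 2)
  expect_error(computeTB(act, 0), "positive")
  expect_error(computeTB(act, -1), "positive")
})

test_that("the 1.2 threshold is inclusive and the volume formula exact", {
  act <- array(1, c(20, 20, 20))
  act[1:10, 1:10, 1:10] <- 1.2          # exactly at threshold: hypoxic
  tb <- computeTB(act, 1)
  region <- array(TRUE, c(20, 20, 20))
  h <- hypoxicVolume(tb, region)
  expect_equal(h$hv_cm3, 1000 / 1000)
  expect_equal(sum(h$mask), 1000)
  expect_equal(h$tb_max, 1.2)
  # a synthetic mask with 2430 hypoxic voxels at 1 mm^3 gives 2.430 cm^3
  act2 <- array(0.8, c(30, 30, 30))
  act2[seq_len(2430)] <- 1.5
  h2 <- hypoxicVolume(computeTB(act2, 1), array(TRUE, c(30, 30, 30)))
  expect_equal(h2$hv_cm3, 2.430)
  # threshold above the global maximum finds nothing
  expect_equal(hypoxicVolume(computeTB(act2, 1), array(TRUE, c(30, 30, 30)),
                             threshold = 2)$hv_cm3, 0)
  # empty region: zero volume, missing maximum, no error
  h3 <- hypoxicVolume(tb, array(FALSE, c(20, 20, 20)))
  expect_equal(h3$hv_cm3, 0)
  expect_true(is.na(h3$tb_max))
})

test_that("raising the threshold never increases the hypoxic volume", {
  set.seed(5)
  tb <- computeTB(array(runif(12^3, 0, 2), c(12, 12, 12)), 1)
  region <- ballMask(12, c(6, 6, 6), 5)
  hv <- vapply(seq(0.5, 2, by = 0.25), function(th)
    hypoxicVolume(tb, region, th)$hv_cm3, numeric(1))
  expect_true(all(diff(hv) <= 0))
})

test_that("regional hypoxic volumes need not sum across overlapping regions", {
  set.seed(8)
  tb <- computeTB(array(runif(10^3, 0, 2), c(10, 10, 10)), 1)
  a <- array(FALSE, c(10, 10, 10)); a[1:6, , ] <- TRUE
  b <- array(FALSE, c(10, 10, 10)); b[4:10, , ] <- TRUE   # overlaps a
  hvU <- hypoxicVolume(tb, a | b)$hv_cm3
  hvA <- hypoxicVolume(tb, a)$hv_cm3
  hvB <- hypoxicVolume(tb, b)$hv_cm3
  # direct voxel-count oracle
  expect_equal(hvU, sum(fieldValues(tb) >= 1.2 & (a | b)) / 1000)
  expect_gt(hvA + hvB, hvU)          # double-counted overlap
})

test_that("OER maps are binary with values confined to [1, 3]", {
  mask <- array(FALSE, c(6, 6, 6)); mask[1:5, 1, 1] <- TRUE
  om <- buildOERMap(mask, 2.5)
  expect_equal(sum(fieldValues(om) == 2.5), 5)
  expect_equal(sum(fieldValues(om) == 1), 6^3 - 5)
  # OER = 1 is the uniform sensitivity scenario
  expect_true(all(fieldValues(buildOERMap(mask, 1)) == 1))
  # empty mask gives the identity map whatever the value
  expect_true(all(fieldValues(buildOERMap(array(FALSE, c(6, 6, 6)), 3)) == 1))
  expect_error(buildOERMap(mask, 0.9), "OER")
  expect_error(buildOERMap(mask, 3.5), "OER")
})

test_that("hypoxia reports tabulate regions like the clinical accounting", {
  act <- array(0.8, c(16, 16, 16))
  act[6:9, 6:9, 6:9] <- 1.5
  tb <- computeTB(act, 1)
  t1gd <- ballMask(16, c(8, 8, 8), 3)
  t2 <- ballMask(16, c(8, 8, 8), 6)
  rep <- hypoxiaReport(tb, list(`T2+` = dilateMask(t2, 2),
                                `T2-T1Gd` = t2 & !t1gd, T1Gd = t1gd))
  expect_equal(nrow(rep), 3)
  expect_true(all(rep$hv_cm3 >= 0))
  expect_equal(rep$region[1], "T2+")
  expect_true(rep$hv_cm3[1] >= max(rep$hv_cm3[2:3]))
})
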