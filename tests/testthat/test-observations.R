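test_that("slice-summed volume matches the clinical formula", {
  m <- array(FALSE, c(8, 8, 2))
  m[1:5, 1:2, 1] <- TRUE               # 10 mm^2
  m[1:5, 1:4, 2] <- TRUE               # 20 mm^2
  v <- volumeFromMask(m, dz = 1, pixelArea = 1)
  expect_equal(v$volume_cm3, 0.030)
  expect_equal(v$sliceAreas_mm2, c(10, 20))
  expect_equal(volumeFromMask(array(FALSE, c(4, 4, 4)))$volume_cm3, 0)
  # per-slice thicknesses are honoured
  expect_equal(volumeFromMask(m, dz = c(2, 3))$volume_cm3, 0.080)
})

test_that("a digital ball recovers the analytic sphere volume", {
  n <- 40
  mask <- ballMask(n, c(20, 20, 20), 16.49)
  v <- volumeFromMask(mask)$volume_cm3
  expect_equal(v, 18.8, tolerance = 0.02)       # voxelisation error < 2 %
  expect_equal(v, sum(mask) / 1000)             # count times voxel volume
})

test_that("equivalent radius inverts the sphere volume", {
  expect_equal(equivalentRadius(4 / 3 * pi / 1000), 1)
  expect_equal(equivalentRadius(0), 0)
  expect_equal(equivalentRadius(18.8), 16.49, tolerance = 1e-3)
  expect_error(equivalentRadius(-1), "non-negative")
})

test_that("growth velocity annualises the equivalent-radius change", {
  m1 <- ballMask(32, c(16, 16, 16), 10)
  obs1 <- observation(m1, date = 0, sequence = "T1Gd")
  r1 <- obsRadius(obs1)
  # construct a second mask whose radius is 0.865 mm larger
  m2 <- ballMask(32, c(16, 16, 16), 11.2)
  obs2 <- observation(m2, date = 13, sequence = "T1Gd")
  vExpected <- (obsRadius(obs2) - r1) / 13 * 365 / 10
  expect_equal(growthVelocity(obs1, obs2), vExpected)
  # radii engineered on the invariant scale: 0.865 mm over 13 d is 2.43 cm/yr
  expect_equal((10.865 - 10) / 13 * 365 / 10, 2.43, tolerance = 1e-3)
  expect_equal(growthVelocity(obs1, observation(m1, 13, "T1Gd")), 0)
  expect_error(growthVelocity(obs1, observation(m1, 0, "T1Gd")), "ordered")
  expect_error(growthVelocity(obs1, observation(m1, 13, "T2")), "sequence")
})

test_that("virtual MRI thresholds the density field per sequence", {
  K <- carryingCapacity()
  df <- cubeDomain(8, 10)
  full <- new("CellDensityField", values = array(K, c(8, 8, 8)), time = 0,
              K = K, spacing = c(1, 1, 1))
  expect_equal(sum(obsMask(virtualMRI(full, "T1Gd"))), 8^3)
  expect_equal(sum(obsMask(virtualMRI(full, "T2"))), 8^3)
  half <- initialize(full, values = array(0.5 * K, c(8, 8, 8)))
  expect_equal(sum(obsMask(virtualMRI(half, "T1Gd"))), 0)
  expect_equal(sum(obsMask(virtualMRI(half, "T2"))), 8^3)
})

test_that("an exponential profile yields the analytic T1Gd-T2 radius gap", {
  # plateau core with an exponential skirt, c = K min(1, exp(-(r - r0)/lambda)):
  # the 0.80 K and 0.16 K isosurfaces are lambda * log(0.80 / 0.16) apart
  n <- 64; lambda <- 4; r0 <- 10
  co <- as.matrix(expand.grid(1:n, 1:n, 1:n)) - 0.5
  r <- sqrt(rowSums(sweep(co, 2, c(n, n, n) / 2)^2))
  K <- carryingCapacity()
  vals <- array(K * pmin(1, exp(-(r - r0) / lambda)), c(n, n, n))
  fld <- new("CellDensityField", values = vals, time = 0, K = K,
             spacing = c(1, 1, 1))
  gap <- obsRadius(virtualMRI(fld, "T2")) - obsRadius(virtualMRI(fld, "T1Gd"))
  expect_equal(gap, lambda * log(0.80 / 0.16), tolerance = 0.02)
})

test_that("the virtual T1Gd mask is always nested inside the T2 mask", {
  set.seed(19)
  K <- carryingCapacity()
  for (rep in 1:5) {
    vals <- array(runif(10^3, 0, K), c(10, 10, 10))
    fld <- new("CellDensityField", values = vals, time = 0, K = K,
               spacing = c(1, 1, 1))
    m1 <- obsMask(virtualMRI(fld, "T1Gd")); m2 <- obsMask(virtualMRI(fld, "T2"))
    expect_true(all(m2[m1]))
  }
})
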