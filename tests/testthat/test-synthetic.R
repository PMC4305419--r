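test_that("the head phantom is a valid layered tissue map", {
  tm <- makePhantom(shape = c(48, 48, 48))
  s <- greyFraction(tm) + whiteFraction(tm) + csfFraction(tm)
  expect_lte(max(s), 1 + 1e-9)
  expect_gte(min(greyFraction(tm)), 0)
  # centre voxel is white-dominant
  expect_gt(whiteFraction(tm)[24, 24, 24], 0.5)
  # all three tissue classes are present
  expect_gt(sum(greyFraction(tm) > 0.5), 0)
  expect_gt(sum(csfFraction(tm) > 0.5), 0)
  # deterministic
  expect_identical(makePhantom(shape = c(24, 24, 24), cortexThickness = 4),
                   makePhantom(shape = c(24, 24, 24), cortexThickness = 4))
  expect_error(makePhantom(shape = c(10, 10, 10)), "small")
})

test_that("synthetic T/B backgrounds hit the target moments", {
  tm <- makePhantom(shape = c(64, 64, 64))   # > 1e5 brain voxels
  s <- greyFraction(tm) + whiteFraction(tm) + csfFraction(tm)
  brain <- s > 0.5
  expect_gt(sum(brain), 1e5)
  tb <- makeTBMap(tm, focusFraction = 0, seed = 2)
  v <- fieldValues(tb)[brain]
  expect_lt(abs(mean(v) - 0.813) / 0.813, 0.03)
  expect_lt(abs(stats::sd(v) - 0.223) / 0.223, 0.03)
  expect_gte(min(fieldValues(tb)), 0)
  # clearly non-normal background (as whole-brain T/B histograms are)
  ks <- suppressWarnings(stats::ks.test(v, "pnorm", mean(v), stats::sd(v)))
  expect_lt(ks$p.value, 1e-4)
  # without a focal lesion, essentially no hypoxia survives the threshold
  region <- dilateMask(ballMask(64, c(40, 32, 32), 10), 10)
  expect_lt(hypoxicVolume(tb, region)$hv_cm3, 0.05)
})

test_that("the focal lesion sizes the hypoxic volume by construction", {
  tm <- makePhantom(shape = c(64, 64, 64))
  tumour <- ballMask(64, c(38, 32, 32), 10)      # ~4.2 cm^3 bulk mask
  tb <- makeTBMap(tm, tumour, focusFraction = 0.13, seed = 3)
  region <- dilateMask(tumour, 20)
  hv <- hypoxicVolume(tb, region)
  expect_equal(hv$hv_cm3, 0.13 * sum(tumour) / 1000, tolerance = 0.05)
  expect_equal(hv$tb_max, 1.52)
  # focus fraction 0 leaves only the stochastic tail
  tb0 <- makeTBMap(tm, tumour, focusFraction = 0, seed = 3)
  expect_lt(hypoxicVolume(tb0, region)$hv_cm3, 0.05)
  # determinism: same seed, identical image
  expect_identical(fieldValues(tb),
                   fieldValues(makeTBMap(tm, tumour, focusFraction = 0.13,
                                         seed = 3)))
  expect_error(makeTBMap(tm, array(FALSE, c(64, 64, 64)),
                         focusFraction = 0.1), "tumour mask")
})

test_that("virtual patients are reproducible and internally consistent", {
  vp <- smallPatient()
  # observations are ordered and the bulk tumour reached its target volume
  expect_equal(obsVolume(vp@obsPre[[1]]), vp@config$targetVolume,
               tolerance = 0.10)
  expect_equal(timePoint(vp@obsPre[[3]]) - timePoint(vp@obsPre[[1]]), 13)
  # T1Gd nested in T2 at every date
  for (i in c(1, 3)) {
    expect_true(all(obsMask(vp@obsPre[[i + 1]])[obsMask(vp@obsPre[[i]])]))
  }
  # the plan delivers the full prescription somewhere
  expect_equal(max(cumulativeDose(vp@plan)), 61.2)
  # treatment shrank the tumour relative to the pre-treatment state
  expect_lt(obsVolume(vp@obsPost[[1]]), obsVolume(vp@obsPre[[3]]) * 1.5)
  # reproducibility from the seed at identical configuration
  vp2 <- makeVirtualPatient(targetVolume = 2, shape = c(48, 48, 48),
                            marginPrimary = 8, marginBoost = 6, seed = 11)
  expect_identical(fieldValues(vp2@tb), fieldValues(vp@tb))
  expect_identical(obsVolume(vp2@obsPost[[2]]), obsVolume(vp@obsPost[[2]]))
})

test_that("alpha = 0 reproduces the untreated continuation", {
  vp <- smallPatient()
  treated0 <- finalField(simulateGrowth(vp@diffusion, vp@growth,
    vp@stateAtRTStart, tSpan = vp@postTime - vp@stateAtRTStart@time,
    plan = vp@plan, oerMap = vp@oerMap, rt = radiosensitivity(0)))
  # untreated continuation stepped on the same event grid as the treated run
  fd <- fractionDays(vp@plan)
  untreated <- finalField(simulateGrowth(vp@diffusion, vp@growth,
    vp@stateAtRTStart, tSpan = vp@postTime - vp@stateAtRTStart@time,
    outputTimes = sort(unique(c(fd[fd > vp@stateAtRTStart@time],
                                vp@postTime)))))
  expect_identical(fieldValues(treated0), fieldValues(untreated))
})
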