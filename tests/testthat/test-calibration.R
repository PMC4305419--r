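test_that("the travelling-wave gap constant behaves as expected", {
  g <- fisherWaveGap(0.80, 0.16)
  expect_gt(g, 5); expect_lt(g, 7)       # interface width ~6 lambda
  # the interface is always wider than the exponential-tail estimate, which
  # is a lower bound (the minimal wave decays like (a + b x) exp(-x))
  expect_gt(g, log(0.80 / 0.16))
  expect_gt(fisherWaveGap(0.02, 0.005), log(0.02 / 0.005))
  expect_error(fisherWaveGap(0.16, 0.80))
})

test_that("velocity and radius gap invert to (D, rho) on the identity case", {
  # v = 2 sqrt(D rho) with D = rho = 1 gives v = 2 mm/yr, lambda = 1 mm
  th <- detectionThresholds()
  for (profile in c("fisher-wave", "exponential-tail")) {
    gapFactor <- if (profile == "fisher-wave") fisherWaveGap(th[["T1Gd"]],
                                                            th[["T2"]])
      else log(th[["T1Gd"]] / th[["T2"]])
    p <- estimateDRho(velocity = 0.2, rT1Gd = 10, rT2 = 10 + gapFactor,
                      profile = profile)
    expect_equal(p@D, 1, tolerance = 1e-12)
    expect_equal(p@rho, 1, tolerance = 1e-12)
    expect_equal(p@velocityImplied, p@velocity, tolerance = 1e-12)
  }
})

test_that("round trips over a plausible (D, rho) grid are exact", {
  th <- detectionThresholds()
  gapFactor <- fisherWaveGap(th[["T1Gd"]], th[["T2"]])
  for (D in c(1, 5, 12.84, 50)) for (rho in c(1, 13.82, 50)) {
    v <- fisherVelocity(D, rho) / 10          # cm/yr
    lambda <- sqrt(D / rho)
    p <- estimateDRho(v, rT1Gd = 20, rT2 = 20 + lambda * gapFactor)
    expect_equal(p@D, D, tolerance = 1e-9)
    expect_equal(p@rho, rho, tolerance = 1e-9)
    expect_equal(p@D / p@rho, lambda^2, tolerance = 1e-9)
  }
})

test_that("published-scale inputs reproduce the invisibility index 0.93", {
  # forward-compute v and the radius gap from D = 12.84, rho = 13.82, invert
  D <- 12.84; rho <- 13.82
  lambda <- sqrt(D / rho)
  gap <- lambda * fisherWaveGap(0.80, 0.16)
  p <- estimateDRho(fisherVelocity(D, rho) / 10, rT1Gd = 16.5,
                    rT2 = 16.5 + gap)
  expect_equal(round(p@D / p@rho, 2), 0.93)
  expect_equal(p@D, 12.84, tolerance = 1e-6)
  expect_equal(p@rho, 13.82, tolerance = 1e-6)
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(estimateDRho(2.4, 17, 16), "degenerate")
  expect_error(estimateDRho(-1, 16, 18), "positive")
  expect_error(estimateDRho(2.4, 16, 18, thresholds = c(T1Gd = 0.1, T2 = 0.5)))
})

test_that("alpha calibration inverts the monotone size-response curve", {
  vp <- smallPatient()
  # radii from three alpha values: fitted alpha order must invert size order
  radii <- vapply(c(0.03, 0.07, 0.2), function(a) {
    fld <- finalField(simulateGrowth(vp@diffusion, vp@growth,
      vp@stateAtRTStart, tSpan = vp@postTime - vp@stateAtRTStart@time,
      plan = vp@plan, oerMap = vp@oerMap,
      rt = radiosensitivity(a)))
    obsRadius(virtualMRI(fld, "T2", vp@thresholds))
  }, numeric(1))
  expect_true(all(diff(radii) < 0))   # larger alpha, smaller tumour
  fits <- vapply(radii, function(r) {
    calibrateAlpha(vp@stateAtRTStart, vp@diffusion, vp@growth, vp@plan,
                   postObs = r, oerMap = vp@oerMap, postTime = vp@postTime,
                   thresholds = vp@thresholds)$alpha
  }, numeric(1))
  expect_true(all(diff(fits) > 0))
  expect_equal(fits, c(0.03, 0.07, 0.2), tolerance = 0.05)
})

test_that("an observed size outside the achievable range is flagged", {
  vp <- smallPatient()
  untreated <- finalField(simulateGrowth(vp@diffusion, vp@growth,
    vp@stateAtRTStart, tSpan = vp@postTime - vp@stateAtRTStart@time))
  rUntreated <- obsRadius(virtualMRI(untreated, "T2", vp@thresholds))
  fit <- suppressWarnings(
    calibrateAlpha(vp@stateAtRTStart, vp@diffusion, vp@growth, vp@plan,
                   postObs = rUntreated + 1, oerMap = vp@oerMap,
                   postTime = vp@postTime, thresholds = vp@thresholds))
  expect_equal(fit$flag, "at_lower")
  expect_equal(fit$alpha, 1e-4)
})
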