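test_that("carrying capacity follows the close-packing formula", {
  expect_equal(carryingCapacity(10), 1 / (4 / 3 * pi * 0.005^3))
  expect_error(carryingCapacity(0))
})

test_that("LQ survival matches the closed form, with OER dose equivalence", {
  rt <- radiosensitivity(alpha = 0.055, alphaBeta = 10)
  expect_equal(lqSurvival(0, rt), 1)
  expect_equal(lqSurvival(1.8, rt), exp(-0.055 * 1.8 - 0.0055 * 1.8^2))
  expect_equal(lqSurvival(1.8, rt), 0.88975, tolerance = 1e-4)
  expect_equal(lqSurvival(1.8, rt, oer = 2.5),
               exp(-0.0396 - 0.0028512), tolerance = 1e-10)
  # scaling (alpha, beta) by OER is the same as scaling dose
  for (d in c(0.9, 1.8, 3.6)) for (o in c(1.5, 2, 3))
    expect_identical(lqSurvival(d, rt, oer = o), lqSurvival(d / o, rt))
  expect_error(lqSurvival(-1, rt), "non-negative")
  expect_error(lqSurvival(1.8, rt, oer = 0.5), "OER")
})

test_that("radiotherapy fraction kill is density-dependent and bounded", {
  K <- carryingCapacity()
  vals <- array(c(K, 0, 0.1 * K, 0.5 * K), c(4, 1, 1))
  fld <- new("CellDensityField", values = vals, time = 0, K = K,
             spacing = c(1, 1, 1))
  rt <- radiosensitivity(0.055)
  # choose a dose whose survival is exactly 0.9 to check the hand example
  d <- uniroot(function(x) lqSurvival(x, rt) - 0.9, c(0.1, 4),
               tol = 1e-12)$root
  out <- applyRtFraction(fld, array(d, c(4, 1, 1)), rt)
  expect_equal(fieldValues(out)[1, 1, 1], K)        # necrotic core untouched
  expect_equal(fieldValues(out)[2, 1, 1], 0)
  expect_equal(fieldValues(out)[3, 1, 1], 0.091 * K, tolerance = 1e-6)
  expect_true(all(fieldValues(out) <= fieldValues(fld) + 1e-9))
  expect_true(all(fieldValues(out) >= 0))
  expect_error(applyRtFraction(fld, array(1, c(2, 1, 1)), rt), "grid")
})

test_that("seeding respects the domain and clamps to K", {
  df <- cubeDomain(8, D = 10)
  K <- carryingCapacity()
  f <- seedInitialCondition(df, c(4, 4, 4), 2 * K, K = K)
  expect_equal(max(fieldValues(f)), K)
  expect_equal(totalCells(f), K * voxelVolume(f))
  allCsfish <- buildDiffusionMap(makePhantom(shape = c(24, 24, 24),
                                             cortexThickness = 4), 10)
  expect_error(seedInitialCondition(allCsfish, c(1, 1, 1), K, K = K),
               "domain")
})

test_that("null dynamics leave the field unchanged exactly", {
  # D = 0 everywhere and rho = 0: nothing moves, nothing grows
  n <- 6
  df <- new("DiffusionField", values = array(0, c(n, n, n)),
            domain = array(TRUE, c(n, n, n)), Dw = 0, Dg = 0,
            spacing = c(1, 1, 1))
  gp <- growthParams(Dw = 0, rho = 0)
  init <- seedInitialCondition(df, c(3, 3, 3), 0.5 * gp@K, K = gp@K)
  out <- finalField(simulateGrowth(df, gp, init, tSpan = 50))
  expect_identical(fieldValues(out), fieldValues(init))
})

test_that("with D = 0 the solver reproduces the logistic closed form", {
  df <- cubeDomain(1, D = 1e-15)
  for (rho in c(2, 13.82)) {
    gp <- growthParams(Dw = 1e-15, rho = rho)
    c0 <- 0.01 * gp@K
    init <- seedInitialCondition(df, c(1, 1, 1), c0, K = gp@K)
    out <- finalField(simulateGrowth(df, gp, init, tSpan = 120))
    rhoD <- rho / 365
    expected <- gp@K * c0 * exp(rhoD * 120) /
      (gp@K + c0 * (exp(rhoD * 120) - 1))
    expect_equal(fieldValues(out)[1, 1, 1], expected,
                 tolerance = 1e-3 * 0.001)  # well inside 0.1 %
  }
})

test_that("the no-flux scheme conserves mass with rho = 0", {
  tm <- makePhantom(shape = c(32, 32, 32), cortexThickness = 4)
  df <- buildDiffusionMap(tm, 50)
  gp <- growthParams(Dw = 50, rho = 0)
  init <- seedInitialCondition(df, c(16, 16, 16), gp@K, K = gp@K)
  sim <- simulateGrowth(df, gp, init, tSpan = 1500)
  expect_gt(sim@steps, 1000)
  drift <- abs(totalCells(finalField(sim)) - totalCells(init)) /
    totalCells(init)
  expect_lt(drift, 1e-6)
})

test_that("simulated OER protection equals simulated dose reduction", {
  df <- cubeDomain(16, D = 20)
  gp <- growthParams(Dw = 20, rho = 10)
  rt <- radiosensitivity(0.055)
  init <- seedInitialCondition(df, c(8, 8, 8), 0.8 * gp@K, K = gp@K)
  mask <- ballMask(16, c(8, 8, 8), 4)
  oer <- 2.5
  grid <- array(1.8, c(16, 16, 16))
  plan1 <- dosePlanFromGrid(grid, days = c(5, 6, 7))
  gridEq <- grid; gridEq[mask] <- grid[mask] / oer
  plan2 <- dosePlanFromGrid(gridEq, days = c(5, 6, 7))
  a <- finalField(simulateGrowth(df, gp, init, tSpan = 10, plan = plan1,
                                 oerMap = buildOERMap(mask, oer), rt = rt))
  b <- finalField(simulateGrowth(df, gp, init, tSpan = 10, plan = plan2,
                                 rt = rt))
  expect_identical(fieldValues(a), fieldValues(b))
})

test_that("post-treatment burden is monotone in alpha and in OER", {
  df <- cubeDomain(16, D = 20)
  gp <- growthParams(Dw = 20, rho = 10)
  init <- seedInitialCondition(df, c(8, 8, 8), 0.8 * gp@K, K = gp@K)
  mask <- ballMask(16, c(8, 8, 8), 4)
  plan <- dosePlanFromGrid(array(1.8, c(16, 16, 16)), days = c(3, 4, 5))
  runWith <- function(alpha, oer) {
    totalCells(finalField(simulateGrowth(df, gp, init, tSpan = 8,
      plan = plan, oerMap = buildOERMap(mask, oer),
      rt = radiosensitivity(alpha))))
  }
  byAlpha <- vapply(c(0.02, 0.055, 0.1, 0.3), runWith, numeric(1), oer = 1)
  expect_true(all(diff(byAlpha) <= 0))
  byOer <- vapply(c(1, 1.5, 2, 2.5, 3), function(o) runWith(0.1, o),
                  numeric(1))
  expect_true(all(diff(byOer) >= 0))
})

test_that("halving the time step changes the final burden by < 0.5 %", {
  tm <- makePhantom(shape = c(32, 32, 32), cortexThickness = 4)
  df <- buildDiffusionMap(tm, 12.84)
  gp <- growthParams(Dw = 12.84, rho = 13.82)
  init <- seedInitialCondition(df, c(16, 16, 16), 0.8 * gp@K, K = gp@K)
  simA <- simulateGrowth(df, gp, init, tSpan = 90)
  simB <- simulateGrowth(df, gp, init, tSpan = 90, dtMax = simA@dt / 2)
  a <- totalCells(finalField(simA)); b <- totalCells(finalField(simB))
  expect_lt(abs(a - b) / b, 0.005)
})

test_that("an unstable user step errors unless auto-refined", {
  df <- cubeDomain(8, D = 100)
  gp <- growthParams(Dw = 100, rho = 10)
  init <- seedInitialCondition(df, c(4, 4, 4), 0.5 * gp@K, K = gp@K)
  expect_error(simulateGrowth(df, gp, init, tSpan = 10, dtMax = 50,
                              autoRefine = FALSE), "stability")
  sim <- simulateGrowth(df, gp, init, tSpan = 10, dtMax = 50)
  expect_lt(sim@dt, 50)
})

test_that("the 1D front advances at the Fisher velocity", {
  df <- barDomain(150, dx = 1, D = 12.84)
  gp <- growthParams(Dw = 12.84, rho = 13.82)
  init <- seedInitialCondition(df, c(1, 1, 1), gp@K, K = gp@K)
  ts <- seq(300, 1200, by = 100)
  sim <- simulateGrowth(df, gp, init, tSpan = 1200, outputTimes = ts)
  pos <- vapply(sim@fields, frontPosition, numeric(1), level = 0.16 * gp@K)
  speed <- slopeOf(ts, pos) * 365
  expect_lt(abs(speed - fisherVelocity(12.84, 13.82)) /
              fisherVelocity(12.84, 13.82), 0.05)
})
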