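# Forward solver for the proliferation-invasion model with radiotherapy:
#   dc/dt = div(D(x) grad c) + rho c (1 - c/K) - RT kill events
# Explicit flux-form central differences for the transport term (no-flux at
# the domain boundary), an exact logistic update for the reaction term via
# Lie splitting, and an instantaneous multiplicative linear-quadratic kill at
# each scheduled fraction time.

#' Linear-quadratic surviving fraction
#'
#' Survival probability of a cell receiving dose `d`:
#' `S = exp(-(alpha/oer) * d - (beta/oer^2) * d^2)` with
#' `beta = alpha / alphaBeta`. The oxygen enhancement ratio `oer` scales the
#' radiobiological parameters so that hypoxic tissue behaves as if it received
#' dose `d / oer`: `S(d; alpha/oer, beta/oer^2) = S(d/oer; alpha, beta)`.
#'
#' @param dose dose in Gy (scalar, vector or array, all >= 0).
#' @param rt a [RadiosensitivityParams-class].
#' @param oer oxygen enhancement ratio(s), >= 1; recycled against `dose`.
#' @return surviving fraction(s) in (0, 1], same shape as `dose`.
#' @examples
#' lqSurvival(1.8, radiosensitivity(alpha = 0.055))         # ~0.890
#' lqSurvival(1.8, radiosensitivity(alpha = 0.055), oer = 2.5)
#' @export
lqSurvival <- function(dose, rt, oer = 1) {
  stopifnot(is(rt, "RadiosensitivityParams"))
  if (any(dose < 0)) stop("dose must be non-negative")
  if (any(oer < 1)) stop("OER must be >= 1")
  beta <- rt@alpha / rt@alphaBeta
  exp(-(rt@alpha / oer) * dose - (beta / oer^2) * dose^2)
}

#' Apply one radiotherapy fraction to a density field
#'
#' The kill is an instantaneous, deterministic event. It follows the same
#' density-dependent logistic form as growth: the killed fraction is
#' `(1 - S(x)) * (1 - c/K)`, so cells at low density are killed in proportion
#' to `1 - S` while at carrying capacity (`c = K`, the necrotic core) there is
#' no radiation effect at all.
#'
#' @param field a [CellDensityField-class].
#' @param doseMap 3D array of dose in Gy for this fraction.
#' @param rt a [RadiosensitivityParams-class].
#' @param oerMap an [OERMap-class] or `NULL` for uniform sensitivity.
#' @return the updated [CellDensityField-class]; `0 <= c' <= c` everywhere.
#' @export
applyRtFraction <- function(field, doseMap, rt, oerMap = NULL) {
  stopifnot(is(field, "CellDensityField"))
  .stopIfGridMismatch(field@values, doseMap)
  if (min(doseMap) < 0) stop("dose must be non-negative")
  oer <- 1
  if (!is.null(oerMap)) {
    stopifnot(is(oerMap, "OERMap"))
    .stopIfGridMismatch(field@values, oerMap@mask)
    oer <- fieldValues(oerMap)
  }
  S <- lqSurvival(doseMap, rt, oer)
  cc <- field@values
  cc <- cc - (1 - S) * cc * (1 - cc / field@K)
  initialize(field, values = cc)
}

#' Seed a single-voxel initial condition
#'
#' The simulated tumour starts as a single voxel of cells, placed at (an
#' approximation of) the centre of mass of the observed bulk tumour.
#'
#' @param diffusion a [DiffusionField-class] defining the domain.
#' @param location integer voxel index `c(i, j, k)`; must be inside the domain.
#' @param c0 seed density in cells/mm^3; clamped to `K`.
#' @param K carrying capacity in cells/mm^3.
#' @param time initial time stamp in days.
#' @return a [CellDensityField-class] with one nonzero voxel.
#' @export
seedInitialCondition <- function(diffusion, location, c0,
                                 K = carryingCapacity(), time = 0) {
  stopifnot(is(diffusion, "DiffusionField"))
  location <- as.integer(round(location))
  d <- dim(diffusion)
  if (length(location) != 3L || any(location < 1L) || any(location > d))
    stop("seed location outside the grid")
  if (!diffusion@domain[location[1], location[2], location[3]])
    stop("seed location is outside the simulation domain (CSF or background)")
  if (c0 < 0) stop("seed density must be non-negative")
  vals <- array(0, d)
  vals[location[1], location[2], location[3]] <- min(c0, K)
  new("CellDensityField", values = vals, time = time, K = K,
      spacing = diffusion@spacing)
}

# face-centred diffusivities; zero across any face touching an off-domain
# voxel, which realises the no-flux boundary.
.faceDiffusivities <- function(diffusion, perDay = TRUE) {
  D <- diffusion@values
  if (perDay) D <- D / 365
  dom <- diffusion@domain
  n <- dim(D)
  fx <- fy <- fz <- NULL
  if (n[1] > 1)
    fx <- 0.5 * (D[-n[1], , , drop = FALSE] + D[-1, , , drop = FALSE]) *
      (dom[-n[1], , , drop = FALSE] & dom[-1, , , drop = FALSE])
  if (n[2] > 1)
    fy <- 0.5 * (D[, -n[2], , drop = FALSE] + D[, -1, , drop = FALSE]) *
      (dom[, -n[2], , drop = FALSE] & dom[, -1, , drop = FALSE])
  if (n[3] > 1)
    fz <- 0.5 * (D[, , -n[3], drop = FALSE] + D[, , -1, drop = FALSE]) *
      (dom[, , -n[3], drop = FALSE] & dom[, , -1, drop = FALSE])
  list(fx = fx, fy = fy, fz = fz)
}

# div(D grad c) with no-flux boundaries, flux form (discretely conservative)
.divDgrad <- function(cc, faces, sp) {
  n <- dim(cc)
  out <- array(0, n)
  if (!is.null(faces$fx)) {
    g <- faces$fx * (cc[-1, , , drop = FALSE] - cc[-n[1], , , drop = FALSE]) / sp[1]^2
    out[-n[1], , ] <- out[-n[1], , , drop = FALSE] + g
    out[-1, , ]    <- out[-1, , , drop = FALSE] - g
  }
  if (!is.null(faces$fy)) {
    g <- faces$fy * (cc[, -1, , drop = FALSE] - cc[, -n[2], , drop = FALSE]) / sp[2]^2
    out[, -n[2], ] <- out[, -n[2], , drop = FALSE] + g
    out[, -1, ]    <- out[, -1, , drop = FALSE] - g
  }
  if (!is.null(faces$fz)) {
    g <- faces$fz * (cc[, , -1, drop = FALSE] - cc[, , -n[3], drop = FALSE]) / sp[3]^2
    out[, , -n[3]] <- out[, , -n[3], drop = FALSE] + g
    out[, , -1]    <- out[, , -1, drop = FALSE] - g
  }
  out
}

# exact solution of dc/dt = rho c (1 - c/K) over a step of h days
.logisticStep <- function(cc, rhoDay, h, K) {
  if (rhoDay == 0) return(cc)
  E <- exp(rhoDay * h)
  K * cc * E / (K + cc * (E - 1))
}

#' Simulate tumour growth and radiotherapy response
#'
#' Integrates the proliferation-invasion equation forward in time on the
#' anatomical domain. Transport uses explicit flux-form central differences
#' with no-flux boundaries at CSF/background; the logistic reaction is applied
#' exactly over each half-step (Strang splitting, second-order in the step),
#' so with `D = 0` the solver reproduces the logistic closed form to
#' round-off. Radiotherapy fractions are instantaneous events applied after
#' the step that reaches each fraction day.
#'
#' The time step obeys `dt <= 0.9 * min(dx)^2 / (2 * ndim * max(D))` jointly
#' with `dt <= 0.1 / rho` (days). A coarser user-supplied `dtMax` is refined
#' automatically unless `autoRefine = FALSE`, in which case it is an error.
#'
#' @param diffusion a [DiffusionField-class] (or a [TissueMap-class], in which
#'   case the field is built with [buildDiffusionMap()] from `growth@Dw`).
#' @param growth a [GrowthParams-class].
#' @param init a [CellDensityField-class]; its `time` is the start time.
#' @param tSpan duration to simulate, days.
#' @param outputTimes absolute days at which snapshots are returned; default
#'   the end time only.
#' @param plan a [DosePlan-class] or `NULL` for untreated growth.
#' @param oerMap an [OERMap-class] or `NULL` (uniform sensitivity).
#' @param rt a [RadiosensitivityParams-class]; required when `plan` is given.
#' @param dtMax optional upper bound on the step, days.
#' @param autoRefine refine an unstable `dtMax` instead of failing.
#' @return a [SimulationResult-class].
#' @examples
#' tm <- makePhantom(shape = c(24, 24, 24))
#' df <- buildDiffusionMap(tm, D = 12.84)
#' gp <- growthParams(Dw = 12.84, rho = 13.82)
#' c0 <- seedInitialCondition(df, c(12, 12, 12), 0.8 * gp@K, K = gp@K)
#' sim <- simulateGrowth(df, gp, c0, tSpan = 30)
#' @export
simulateGrowth <- function(diffusion, growth, init, tSpan, outputTimes = NULL,
                           plan = NULL, oerMap = NULL, rt = NULL,
                           dtMax = NULL, autoRefine = TRUE) {
  if (is(diffusion, "TissueMap"))
    diffusion <- buildDiffusionMap(diffusion, growth@Dw)
  stopifnot(is(diffusion, "DiffusionField"), is(growth, "GrowthParams"),
            is(init, "CellDensityField"))
  .stopIfGridMismatch(diffusion@values, init@values)
  if (!is.numeric(tSpan) || tSpan <= 0) stop("tSpan must be positive (days)")
  if (!is.null(plan)) {
    if (is.null(rt))
      stop("a dose plan requires radiosensitivity parameters 'rt'")
    .stopIfGridMismatch(diffusion@values, plan@phases[[1]]$dose)
  }
  t0 <- init@time
  tEnd <- t0 + tSpan
  if (is.null(outputTimes)) outputTimes <- tEnd
  if (any(outputTimes < t0 - 1e-9) || any(outputTimes > tEnd + 1e-9))
    stop("outputTimes must lie within [start, start + tSpan]")
  outputTimes <- sort(unique(outputTimes))

  fracDays <- numeric()
  if (!is.null(plan)) {
    fd <- fractionDays(plan)
    fracDays <- fd[fd >= t0 - 1e-9 & fd <= tEnd + 1e-9]
  }
  events <- sort(unique(c(outputTimes[outputTimes > t0 + 1e-9],
                          fracDays[fracDays > t0 + 1e-9], tEnd)))

  # stable explicit step
  sp <- diffusion@spacing
  ndim <- sum(dim(diffusion) > 1L)
  maxD <- max(diffusion@values) / 365
  rhoDay <- growth@rho / 365
  dtStab <- if (maxD > 0) 0.9 * min(sp)^2 / (2 * max(ndim, 1) * maxD) else Inf
  dtRho <- if (rhoDay > 0) 0.1 / rhoDay else Inf
  dt <- min(dtStab, dtRho, tSpan)
  if (!is.null(dtMax)) {
    if (dtMax > min(dtStab, dtRho) + 1e-12 && !autoRefine)
      stop(sprintf(
        "dtMax = %g d violates the stability bound %g d (set autoRefine = TRUE)",
        dtMax, min(dtStab, dtRho)))
    dt <- min(dt, dtMax)
  }

  faces <- .faceDiffusivities(diffusion)
  cc <- init@values
  K <- init@K
  t <- t0
  nSteps <- 0L
  clamped <- 0
  snapshots <- list()
  times <- numeric()
  takeSnapshot <- function(tt, vals) {
    snapshots[[length(snapshots) + 1L]] <<- new("CellDensityField",
      values = vals, time = tt, K = K, spacing = sp)
    times[length(times) + 1L] <<- tt
  }
  if (any(abs(outputTimes - t0) <= 1e-9)) takeSnapshot(t0, cc)

  # a fraction scheduled exactly at the start is applied before stepping
  if (length(fracDays) && any(abs(fracDays - t0) <= 1e-9)) {
    fld <- new("CellDensityField", values = cc, time = t0, K = K, spacing = sp)
    cc <- applyRtFraction(fld, doseAt(plan, t0), rt, oerMap)@values
  }

  diffusing <- maxD > 0
  for (te in events) {
    span <- te - t
    n <- max(1L, ceiling(span / dt - 1e-9))
    h <- span / n
    for (s in seq_len(n)) {
      # Strang splitting: half an exact logistic step, an explicit diffusion
      # step, half a logistic step (second-order accurate in h)
      cc <- .logisticStep(cc, rhoDay, h / 2, K)
      if (diffusing) {
        cc <- cc + h * .divDgrad(cc, faces, sp)
        neg <- cc < 0
        if (any(neg)) {
          clamped <- clamped - sum(cc[neg]) * prod(sp)
          cc[neg] <- 0
        }
        over <- cc > K
        if (any(over)) cc[over] <- K
      }
      cc <- .logisticStep(cc, rhoDay, h / 2, K)
      nSteps <- nSteps + 1L
    }
    t <- te
    if (anyNA(cc) || any(!is.finite(cc)))
      stop(sprintf("numerical failure (NaN/Inf) at day %.3f after %d steps (dt = %g d)",
                   t, nSteps, h))
    if (length(fracDays) && any(abs(fracDays - te) <= 1e-9)) {
      fld <- new("CellDensityField", values = cc, time = t, K = K, spacing = sp)
      fld <- applyRtFraction(fld, doseAt(plan, te), rt, oerMap)
      cc <- fld@values
    }
    if (any(abs(outputTimes - te) <= 1e-9)) takeSnapshot(te, cc)
  }

  new("SimulationResult", fields = snapshots, times = times, dt = dt,
      steps = nSteps, clampedMass = clamped)
}

#' Fisher velocity of the travelling front
#'
#' The reaction-diffusion front expands asymptotically at `2 * sqrt(D * rho)`.
#'
#' @param D invasion rate, mm^2/year.
#' @param rho proliferation rate, 1/year.
#' @return front speed in mm/year.
#' @export
fisherVelocity <- function(D, rho) 2 * sqrt(D * rho)

#' Position of the density front along a profile
#'
#' Finds the outermost crossing of `c = level` along a 1D profile by linear
#' interpolation between voxel centres; used to measure the simulated front
#' speed against the Fisher value.
#'
#' @param x a [CellDensityField-class] (a profile along `axis` through the
#'   centre of the other axes is extracted) or a numeric vector.
#' @param level density threshold, cells/mm^3.
#' @param axis axis along which to extract the profile.
#' @param spacing voxel spacing in mm (taken from `x` when it is a field).
#' @return front position in mm from the grid edge, or `NA` if no crossing.
#' @export
frontPosition <- function(x, level, axis = 1, spacing = 1) {
  if (is(x, "CellDensityField")) {
    d <- dim(x)
    idx <- as.list(pmax(1L, ceiling(d / 2)))
    idx[[axis]] <- seq_len(d[axis])
    v <- do.call(`[`, c(list(x@values), idx))
    spacing <- x@spacing[axis]
  } else v <- as.numeric(x)
  n <- length(v)
  above <- v >= level
  if (!any(above)) return(NA_real_)
  i <- max(which(above))
  if (i == n) return((n - 0.5) * spacing)
  # interpolate between centres i and i+1
  frac <- (v[i] - level) / (v[i] - v[i + 1])
  (i - 0.5 + frac) * spacing
}
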