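.waveGapCache <- new.env(parent = emptyenv())

#' Dimensionless threshold gap of the minimal Fisher travelling wave
#'
#' Integrates the travelling-wave profile of the logistic reaction-diffusion
#' equation at the minimal (Fisher) speed -- in units where D = rho = 1 the
#' profile solves `U'' + 2 U' + U (1 - U) = 0` -- and returns the distance
#' between its crossings of `thetaHigh` and `thetaLow`, in units of the
#' infiltration length `lambda = sqrt(D / rho)`. For the standard imaging
#' thresholds 0.80 and 0.16 the gap is about 6.1 lambda, several times wider
#' than the far-tail value `log(thetaHigh / thetaLow)` because the thresholds
#' sit on the wave interface, not in its exponential tail.
#'
#' @param thetaHigh,thetaLow density thresholds, `0 < thetaLow < thetaHigh < 1`.
#' @return the dimensionless gap (multiples of lambda).
#' @examples
#' fisherWaveGap(0.80, 0.16)   # ~6.1
#' @export
fisherWaveGap <- function(thetaHigh = 0.80, thetaLow = 0.16) {
  if (!(thetaLow < thetaHigh && thetaLow > 0 && thetaHigh < 1))
    stop("need 0 < thetaLow < thetaHigh < 1")
  key <- paste(thetaHigh, thetaLow)
  if (!is.null(.waveGapCache[[key]])) return(.waveGapCache[[key]])
  # leave the U = 1 saddle along its unstable manifold, RK4
  f <- function(y) c(y[2], -2 * y[2] - y[1] * (1 - y[1]))
  s <- sqrt(2) - 1
  w0 <- 1e-7
  y <- c(1 - w0, -s * w0)
  h <- 0.005
  xs <- us <- numeric(0)
  x <- 0
  for (i in seq_len(200000)) {
    xs[i] <- x; us[i] <- y[1]
    k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    x <- x + h
    if (y[1] < thetaLow * 0.5) break
  }
  cross <- function(level) stats::approx(us, xs, xout = level)$y
  gap <- cross(thetaLow) - cross(thetaHigh)
  .waveGapCache[[key]] <- gap
  gap
}

#' Estimate net invasion and proliferation rates from imaging
#'
#' Two imageable quantities pin down (D, rho). The radial growth velocity of
#' the bulk tumour approaches the Fisher front speed `v = 2 * sqrt(D * rho)`,
#' and the gap between the T2 and T1Gd equivalent radii measures the width of
#' the infiltration profile, which scales with `lambda = sqrt(D / rho)`.
#' Inverting the pair gives `D = v * lambda / 2` and `rho = v / (2 * lambda)`,
#' so that both the Fisher relation and the invisibility index
#' `D / rho = lambda^2` hold exactly.
#'
#' Two conventions convert the radius gap to lambda. The default,
#' `"fisher-wave"`, divides by the dimensionless threshold gap of the model's
#' own travelling-wave profile ([fisherWaveGap()]), and is the convention
#' consistent with forward simulations of this package: estimates from
#' simulated tumours round-trip to the generating parameters.
#' `"exponential-tail"` divides by `log(theta_T1Gd / theta_T2)`, the value
#' obtained by placing both thresholds on the exponential far tail
#' `c ~ exp(-r / lambda)`; it is retained because published parameter sets
#' differ by O(1) factors in this conversion.
#'
#' The returned object reports both the supplied velocity and the one implied
#' by `2 * sqrt(D * rho)`; by construction of this estimator they coincide,
#' but when parameters come from elsewhere the two are printed side by side
#' and never silently reconciled.
#'
#' @param velocity radial growth velocity in cm/year (from T1Gd radii).
#' @param rT1Gd,rT2 equivalent spherical radii in mm, `rT2 > rT1Gd`.
#' @param thresholds named detection thresholds, fractions of K
#'   (see [detectionThresholds()]).
#' @param profile radius-gap-to-lambda convention, see Details.
#' @param alphaBeta alpha/beta ratio carried into the parameter set, Gy.
#' @return a [PatientParameters-class] (alpha is `NA` until calibrated).
#' @examples
#' p <- estimateDRho(velocity = 2.664, rT1Gd = 16.5, rT2 = 22.39)
#' p@D / p@rho            # invisibility index, mm^2
#' @export
estimateDRho <- function(velocity, rT1Gd, rT2,
                         thresholds = detectionThresholds(),
                         profile = c("fisher-wave", "exponential-tail"),
                         alphaBeta = 10) {
  profile <- match.arg(profile)
  if (velocity <= 0) stop("velocity must be positive (cm/year)")
  th1 <- thresholds[["T1Gd"]]; th2 <- thresholds[["T2"]]
  if (!(th2 < th1 && th2 > 0 && th1 < 1))
    stop("need 0 < theta_T2 < theta_T1Gd < 1")
  if (rT2 <= rT1Gd)
    stop("degenerate infiltration profile: T2 radius must exceed T1Gd radius")
  vMm <- velocity * 10                       # mm/year
  gapFactor <- if (profile == "fisher-wave") fisherWaveGap(th1, th2) else
    log(th1 / th2)
  lambda <- (rT2 - rT1Gd) / gapFactor        # mm
  D <- vMm * lambda / 2
  rho <- vMm / (2 * lambda)
  new("PatientParameters", D = D, rho = rho, lambda = lambda,
      velocity = velocity, velocityImplied = fisherVelocity(D, rho) / 10,
      alpha = NA_real_, alphaBeta = alphaBeta)
}

#' Patient parameters from two serial observation pairs
#'
#' Convenience wrapper: velocity from the two T1Gd observations, infiltration
#' length from the T1Gd/T2 radius gap at the later date.
#'
#' @param t1gd1,t1gd2 T1Gd [Observation-class] at the two pre-treatment dates.
#' @param t2at2 T2 [Observation-class] at the second date.
#' @param thresholds detection thresholds, fractions of K.
#' @param profile radius-gap convention, see [estimateDRho()].
#' @param alphaBeta alpha/beta ratio, Gy.
#' @return a [PatientParameters-class].
#' @export
estimateFromObservations <- function(t1gd1, t1gd2, t2at2,
                                     thresholds = detectionThresholds(),
                                     profile = c("fisher-wave",
                                                 "exponential-tail"),
                                     alphaBeta = 10) {
  v <- growthVelocity(t1gd1, t1gd2)
  estimateDRho(v, rT1Gd = t1gd2@radius, rT2 = t2at2@radius,
               thresholds = thresholds, profile = profile,
               alphaBeta = alphaBeta)
}

# one forward treatment simulation -> post-treatment virtual radius
.postRadiusForAlpha <- function(alpha, init, diffusion, growth, plan, oerMap,
                                postTime, sequence, thresholds, alphaBeta) {
  rt <- radiosensitivity(alpha, alphaBeta)
  sim <- simulateGrowth(diffusion, growth, init, tSpan = postTime - init@time,
                        outputTimes = postTime, plan = plan, oerMap = oerMap,
                        rt = rt)
  virtualMRI(finalField(sim), sequence, thresholds)@radius
}

#' @describeIn calibrateAlpha Calibrate alpha against an observed
#'   post-treatment size, starting the treatment simulation from the supplied
#'   density field (the tumour state at the first fraction day).
#'
#'   With alpha/beta fixed, the post-treatment size is monotone decreasing in
#'   alpha, so the one-to-one alpha-to-error relationship is solved by a
#'   deterministic bracketed bisection on the radius residual. If the observed
#'   size lies outside the range achievable over the bracket, the nearer
#'   bracket endpoint is returned with a warning and a flag.
#'
#' @param diffusion a [DiffusionField-class].
#' @param growth a [GrowthParams-class] (already calibrated (D, rho)).
#' @param plan a [DosePlan-class].
#' @param postObs observed post-treatment [Observation-class] (conventionally
#'   the first post-treatment T2), or a target radius in mm.
#' @param oerMap an [OERMap-class] or `NULL` for uniform sensitivity.
#' @param postTime evaluation day; defaults to the observation date.
#' @param sequence MRI sequence of the target size.
#' @param thresholds detection thresholds, fractions of K.
#' @param alphaBeta fixed alpha/beta ratio, Gy.
#' @param bracket search interval for alpha, 1/Gy.
#' @param tol radius tolerance in mm.
#' @return list with `alpha` (1/Gy), `radius` (mm, achieved), `flag`
#'   (`"converged"`, `"at_lower"` or `"at_upper"`) and `evaluations`.
#' @export
setMethod("calibrateAlpha", "CellDensityField",
  function(x, diffusion, growth, plan, postObs, oerMap = NULL,
           postTime = NULL, sequence = "T2",
           thresholds = detectionThresholds(), alphaBeta = 10,
           bracket = c(1e-4, 0.5), tol = 1e-3) {
    target <- if (is(postObs, "Observation")) postObs@radius else postObs
    if (is.null(postTime))
      postTime <- if (is(postObs, "Observation")) postObs@date else
        stop("postTime required when postObs is a bare radius")
    if (postTime <= x@time) stop("evaluation time must follow the RT start")
    f <- function(a) .postRadiusForAlpha(a, x, diffusion, growth, plan,
                                         oerMap, postTime, sequence,
                                         thresholds, alphaBeta)
    nEval <- 0L
    lo <- bracket[1]; hi <- bracket[2]
    rLo <- f(lo); rHi <- f(hi); nEval <- 2L
    if (target >= rLo - tol) {
      if (target > rLo + tol)
        warning("observed size at or above the least-sensitive simulation; ",
                "alpha fixed at the lower bracket endpoint")
      return(list(alpha = lo, radius = rLo, flag = "at_lower",
                  evaluations = nEval))
    }
    if (target <= rHi + tol) {
      if (target < rHi - tol)
        warning("observed size below the most sensitive simulation; ",
                "alpha fixed at the upper bracket endpoint")
      return(list(alpha = hi, radius = rHi, flag = "at_upper",
                  evaluations = nEval))
    }
    for (i in seq_len(60)) {
      mid <- 0.5 * (lo + hi)
      rMid <- f(mid); nEval <- nEval + 1L
      if (abs(rMid - target) <= tol || (hi - lo) < 1e-6)
        return(list(alpha = mid, radius = rMid, flag = "converged",
                    evaluations = nEval))
      if (rMid > target) lo <- mid else hi <- mid   # radius decreasing in alpha
    }
    list(alpha = 0.5 * (lo + hi), radius = rMid, flag = "converged",
         evaluations = nEval)
  })

#' @describeIn calibrateAlpha Calibrate alpha for a virtual patient from its
#'   own stored pre-treatment state, plan and first post-treatment T2
#'   observation (parameter-recovery use).
#' @export
setMethod("calibrateAlpha", "VirtualPatient",
  function(x, oerMap = NULL, sequence = "T2", bracket = c(1e-4, 0.5),
           tol = 1e-3) {
    postObs <- Filter(function(o) o@sequence == sequence, x@obsPost)[[1]]
    calibrateAlpha(x@stateAtRTStart, x@diffusion, x@growth, x@plan,
                   postObs = postObs, oerMap = oerMap, sequence = sequence,
                   thresholds = x@thresholds, alphaBeta = x@rt@alphaBeta,
                   bracket = bracket, tol = tol)
  })
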