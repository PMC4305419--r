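#' Weekday fraction schedule
#'
#' Daily fractionation is delivered on consecutive weekdays (Monday-Friday).
#' Day 0 of the simulation clock is taken to be a Monday by convention; pass
#' `weekdaysOnly = FALSE` for strictly consecutive calendar days.
#'
#' @param start first candidate day.
#' @param n number of fractions.
#' @param weekdaysOnly skip Saturdays and Sundays.
#' @return numeric vector of `n` strictly increasing days.
#' @export
fractionSchedule <- function(start, n, weekdaysOnly = TRUE) {
  if (n < 1) stop("need at least one fraction")
  days <- numeric(n)
  d <- start
  for (i in seq_len(n)) {
    if (weekdaysOnly) while ((floor(d) %% 7) >= 5) d <- d + 1
    days[i] <- d
    d <- d + 1
  }
  days
}

#' Build an idealised two-phase conformal radiotherapy plan
#'
#' Standard-of-care glioblastoma dosing: a primary phase delivering a uniform
#' fraction dose inside the T2-defined abnormality expanded by a clinical
#' margin (default 54 Gy in 30 fractions of 1.8 Gy to T2 + 2.5 cm), followed
#' sequentially by a boost phase to the contrast-enhancing region plus its
#' margin (default 7.2 Gy in 4 fractions of 1.8 Gy to T1Gd + 2 cm), for 61.2
#' Gy total in the boost region. The dose is an idealised step function: full
#' prescription inside the dilated target, zero outside, no penumbra.
#'
#' @param t2Mask,t1gdMask 3D logical masks on a common grid.
#' @param marginPrimary,marginBoost margins in mm realised by Euclidean
#'   distance dilation ([dilateMask()]).
#' @param dosePrimary,doseBoost total phase doses in Gy; each must divide
#'   evenly into its fraction count (1.8 Gy/fraction by default).
#' @param nPrimary,nBoost fraction counts.
#' @param fractionDose dose per fraction in Gy; both phase prescriptions must
#'   equal their fraction count times this value.
#' @param startDate day of the first fraction.
#' @param spacing voxel size in mm.
#' @param weekdaysOnly schedule fractions on weekdays only (see
#'   [fractionSchedule()]).
#' @return a [DosePlan-class] with two phases.
#' @examples
#' t2 <- array(FALSE, c(32, 32, 32)); t2[12:20, 12:20, 12:20] <- TRUE
#' t1 <- array(FALSE, c(32, 32, 32)); t1[14:18, 14:18, 14:18] <- TRUE
#' plan <- buildConformalPlan(t2, t1, marginPrimary = 3, marginBoost = 2)
#' max(cumulativeDose(plan))   # 61.2 Gy
#' @export
buildConformalPlan <- function(t2Mask, t1gdMask, marginPrimary = 25,
                               marginBoost = 20, dosePrimary = 54,
                               nPrimary = 30, doseBoost = 7.2, nBoost = 4,
                               fractionDose = 1.8, startDate = 0,
                               spacing = c(1, 1, 1), weekdaysOnly = TRUE) {
  .stopIfGridMismatch(t2Mask, t1gdMask)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (marginPrimary < 0 || marginBoost < 0) stop("margins must be >= 0 (mm)")
  if (fractionDose <= 0) stop("fraction dose must be positive (Gy)")
  if (abs(dosePrimary - nPrimary * fractionDose) > 1e-9 ||
      abs(doseBoost - nBoost * fractionDose) > 1e-9)
    stop("phase dose must equal fraction count times the fraction dose")
  fxPrimary <- fxBoost <- fractionDose

  targetPrimary <- dilateMask(t2Mask, marginPrimary, spacing)
  targetBoost <- dilateMask(t1gdMask, marginBoost, spacing)

  dosePrimaryGrid <- array(0, dim(t2Mask))
  dosePrimaryGrid[targetPrimary] <- fxPrimary
  doseBoostGrid <- array(0, dim(t2Mask))
  doseBoostGrid[targetBoost] <- fxBoost

  daysPrimary <- fractionSchedule(startDate, nPrimary, weekdaysOnly)
  daysBoost <- fractionSchedule(max(daysPrimary) + 1, nBoost, weekdaysOnly)

  new("DosePlan",
      phases = list(
        list(dose = dosePrimaryGrid, days = daysPrimary, label = "primary"),
        list(dose = doseBoostGrid, days = daysBoost, label = "boost")),
      spacing = spacing)
}

#' Build a single-phase plan from an arbitrary dose grid
#'
#' Escape hatch for externally computed (e.g. planning-system) dose grids that
#' bypass the idealised conformal builder.
#'
#' @param doseGrid 3D array, dose in Gy per fraction.
#' @param days fraction days (strictly increasing).
#' @param spacing voxel size in mm.
#' @param label phase label.
#' @return a [DosePlan-class].
#' @export
dosePlanFromGrid <- function(doseGrid, days, spacing = c(1, 1, 1),
                             label = "custom") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("DosePlan", phases = list(list(dose = doseGrid, days = days,
                                     label = label)),
      spacing = spacing)
}
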