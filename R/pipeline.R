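# Orchestration: OER treatment scenarios and the OER sensitivity sweep.

# one forward treatment simulation from the RT-start state
.runTreatment <- function(patient, oerValue, alpha = NULL) {
  rt <- if (is.null(alpha)) patient@rt else
    radiosensitivity(alpha, patient@rt@alphaBeta)
  oerMap <- buildOERMap(hypoxicMask(patient@oerMap), oerValue,
                        threshold = patient@oerMap@threshold,
                        spacing = voxelSpacing(patient@oerMap))
  sim <- simulateGrowth(patient@diffusion, patient@growth,
                        patient@stateAtRTStart,
                        tSpan = patient@postTime - patient@stateAtRTStart@time,
                        outputTimes = patient@postTime, plan = patient@plan,
                        oerMap = oerMap, rt = rt)
  finalField(sim)
}

#' Run uniform-sensitivity and hypoxia-resistance treatment scenarios
#'
#' Simulates the delivered plan once with spatially uniform radiosensitivity
#' (OER = 1 everywhere) and once per requested OER value applied inside the
#' patient's hypoxic volume, then compares tumour burden: percent of
#' pre-treatment cells killed, and surviving cells relative to the uniform
#' run (hypoxia protects, so this ratio is >= 1 and grows with OER).
#' Equivalent-radius errors against the patient's stored post-treatment
#' observations are attached per sequence.
#'
#' @param patient a [VirtualPatient-class] (any object with the same slots
#'   works identically for real data assembled into one).
#' @param oerValues OER values for the hypoxia scenarios, each in \[1, 3\].
#' @param alpha optional radiosensitivity override, 1/Gy; default the
#'   patient's stored (ground-truth or calibrated) alpha.
#' @return named list of [ScenarioResult-class], `"uniform"` first.
#' @export
runScenarios <- function(patient, oerValues = c(1.5, 2, 2.5, 3),
                         alpha = NULL) {
  stopifnot(is(patient, "VirtualPatient"))
  if (any(oerValues < 1 | oerValues > 3))
    stop("OER values must lie in [1, 3]")
  pre <- totalCells(patient@stateAtRTStart)
  thresholds <- patient@thresholds

  makeResult <- function(label, oerValue, final, postUniform) {
    post <- totalCells(final)
    obs <- list(T1Gd = virtualMRI(final, "T1Gd", thresholds),
                T2 = virtualMRI(final, "T2", thresholds))
    errs <- c(T1Gd_relative_pct = NA_real_, T1Gd_absolute_mm = NA_real_,
              T2_relative_pct = NA_real_, T2_absolute_mm = NA_real_)
    for (truth in patient@obsPost) {
      e <- radiusErrors(obs[[truth@sequence]], truth)
      errs[paste0(truth@sequence, "_relative_pct")] <- e[["relative_pct"]]
      errs[paste0(truth@sequence, "_absolute_mm")] <- e[["absolute_mm"]]
    }
    new("ScenarioResult", label = label, oerValue = oerValue,
        preCells = pre, postCells = post,
        percentKilled = 100 * (1 - post / pre),
        survivalRatio = post / postUniform, postObs = obs,
        radiusErrors = errs)
  }

  finalUniform <- .runTreatment(patient, 1, alpha)
  postUniform <- totalCells(finalUniform)
  out <- list(uniform = makeResult("uniform", 1, finalUniform, postUniform))
  for (v in oerValues) {
    lab <- sprintf("OER=%g", v)
    out[[lab]] <- makeResult(lab, v, .runTreatment(patient, v, alpha),
                             postUniform)
  }
  out
}

#' Sweep the OER and measure model-data agreement
#'
#' Runs one treatment simulation per OER value and reports the relative
#' equivalent-radius error of the predicted post-treatment size against the
#' supplied truth (default the patient's stored post-treatment observation).
#' The grid value minimising the error is attached as attribute `"argmin"`.
#'
#' @param patient a [VirtualPatient-class].
#' @param oerGrid OER values to test, each in \[1, 3\].
#' @param sequence MRI sequence used for the error (`"T1Gd"` by convention).
#' @param truth observed post-treatment [Observation-class]; default the
#'   patient's stored one for `sequence`.
#' @param alpha optional radiosensitivity override, 1/Gy.
#' @return data.frame with columns `oer`, `relative_error_pct`,
#'   `absolute_error_mm`; attribute `"argmin"` holds the best OER.
#' @export
oerSweep <- function(patient, oerGrid = c(1, 1.5, 2, 2.5, 3),
                     sequence = "T1Gd", truth = NULL, alpha = NULL) {
  stopifnot(is(patient, "VirtualPatient"))
  if (any(oerGrid < 1 | oerGrid > 3))
    stop("the OER grid must lie within [1, 3]")
  if (is.null(truth))
    truth <- Filter(function(o) o@sequence == sequence, patient@obsPost)[[1]]
  rows <- lapply(oerGrid, function(v) {
    final <- .runTreatment(patient, v, alpha)
    pred <- virtualMRI(final, sequence, patient@thresholds)
    e <- radiusErrors(pred, truth)
    data.frame(oer = v, relative_error_pct = e[["relative_pct"]],
               absolute_error_mm = e[["absolute_mm"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "argmin") <- out$oer[which.min(out$relative_error_pct)]
  out
}

#' Tabulate scenario results
#'
#' @param scenarios list returned by [runScenarios()].
#' @return data.frame, one row per scenario.
#' @export
scenarioTable <- function(scenarios) {
  do.call(rbind, lapply(scenarios, function(s)
    data.frame(label = s@label, oer = s@oerValue,
               percent_killed = s@percentKilled,
               survival_ratio = s@survivalRatio,
               t1gd_rel_err_pct = s@radiusErrors[["T1Gd_relative_pct"]],
               t2_rel_err_pct = s@radiusErrors[["T2_relative_pct"]])))
}
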