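# Accessor and show methods for the core classes.

.spacingOf <- function(x) x@spacing

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "TissueMap", .spacingOf)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "DiffusionField", .spacingOf)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "CellDensityField", .spacingOf)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "DosePlan", .spacingOf)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "TBImage", .spacingOf)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "OERMap", .spacingOf)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "Observation", .spacingOf)

.volOf <- function(x) prod(x@spacing)
#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "TissueMap", .volOf)
#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "CellDensityField", .volOf)
#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "DiffusionField", .volOf)
#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "Observation", .volOf)

#' @export
setMethod("dim", "TissueMap", function(x) dim(x@grey))
#' @export
setMethod("dim", "DiffusionField", function(x) dim(x@values))
#' @export
setMethod("dim", "CellDensityField", function(x) dim(x@values))
#' @export
setMethod("dim", "TBImage", function(x) dim(x@values))
#' @export
setMethod("dim", "OERMap", function(x) dim(x@mask))
#' @export
setMethod("dim", "Observation", function(x) dim(x@mask))
#' @export
setMethod("dim", "DosePlan", function(x) dim(x@phases[[1]]$dose))

#' @rdname TissueMap-class
#' @export
setMethod("greyFraction", "TissueMap", function(x) x@grey)
#' @rdname TissueMap-class
#' @export
setMethod("whiteFraction", "TissueMap", function(x) x@white)
#' @rdname TissueMap-class
#' @export
setMethod("csfFraction", "TissueMap", function(x) x@csf)

#' @rdname fieldValues
#' @export
setMethod("fieldValues", "DiffusionField", function(x) x@values)
#' @rdname fieldValues
#' @export
setMethod("fieldValues", "CellDensityField", function(x) x@values)
#' @rdname fieldValues
#' @export
setMethod("fieldValues", "TBImage", function(x) x@values)
#' @rdname fieldValues
#' @export
setMethod("fieldValues", "OERMap", function(x) {
  out <- array(1, dim(x@mask))
  out[x@mask] <- x@oerValue
  out
})

#' @rdname domainMask
#' @export
setMethod("domainMask", "DiffusionField", function(x) x@domain)

#' @rdname hypoxicMask
#' @export
setMethod("hypoxicMask", "OERMap", function(x) x@mask)

#' @rdname timePoint
#' @export
setMethod("timePoint", "CellDensityField", function(x) x@time)
#' @rdname timePoint
#' @export
setMethod("timePoint", "Observation", function(x) x@date)

#' @rdname totalCells
#' @export
setMethod("totalCells", "CellDensityField",
          function(x) sum(x@values) * prod(x@spacing))

#' @rdname cumulativeDose
#' @export
setMethod("cumulativeDose", "DosePlan", function(x) {
  out <- array(0, dim(x@phases[[1]]$dose))
  for (ph in x@phases) out <- out + ph$dose * length(ph$days)
  out
})

#' @rdname fractionDays
#' @export
setMethod("fractionDays", "DosePlan",
          function(x) sort(unlist(lapply(x@phases, `[[`, "days"))))

#' @rdname doseAt
#' @export
setMethod("doseAt", "DosePlan", function(x, t, tol = 1e-6) {
  for (ph in x@phases)
    if (any(abs(ph$days - t) <= tol)) return(ph$dose)
  array(0, dim(x@phases[[1]]$dose))
})

#' @rdname Observation-class
#' @export
setMethod("obsMask", "Observation", function(x) x@mask)
#' @rdname Observation-class
#' @export
setMethod("obsVolume", "Observation", function(x) x@volume)
#' @rdname Observation-class
#' @export
setMethod("obsRadius", "Observation", function(x) x@radius)

# -- show methods -------------------------------------------------------------

.fmtDim <- function(d) paste(d, collapse = " x ")

#' @export
setMethod("show", "TissueMap", function(object) {
  cat("TissueMap:", .fmtDim(dim(object)), "voxels,",
      paste(object@spacing, collapse = "x"), "mm\n")
  s <- object@grey + object@white + object@csf
  cat("  head voxels (tissue sum > 0.5):", sum(s > 0.5), "\n")
})

#' @export
setMethod("show", "DiffusionField", function(object) {
  cat("DiffusionField:", .fmtDim(dim(object)), "voxels\n")
  cat(sprintf("  Dw = %.4g, Dg = %.4g mm^2/yr; domain voxels: %d\n",
              object@Dw, object@Dg, sum(object@domain)))
})

#' @export
setMethod("show", "CellDensityField", function(object) {
  cat("CellDensityField at t =", round(object@time, 3), "days:",
      .fmtDim(dim(object)), "voxels\n")
  cat(sprintf("  total cells %.4g, max density %.4g of K\n",
              totalCells(object), max(object@values) / object@K))
})

#' @export
setMethod("show", "DosePlan", function(object) {
  cat("DosePlan with", length(object@phases), "phase(s),",
      length(fractionDays(object)), "fractions\n")
  for (ph in object@phases)
    cat(sprintf("  %s: %d fractions of max %.3g Gy, days %g..%g\n",
                if (is.null(ph$label)) "phase" else ph$label,
                length(ph$days), max(ph$dose), min(ph$days), max(ph$days)))
  cat("  max cumulative dose:", max(cumulativeDose(object)), "Gy\n")
})

#' @export
setMethod("show", "TBImage", function(object) {
  v <- object@values[object@values > 0]
  cat("TBImage:", .fmtDim(dim(object)), "voxels; blood activity",
      object@bloodActivity, "\n")
  if (length(v))
    cat(sprintf("  nonzero T/B: mean %.3f, sd %.3f, max %.3f\n",
                mean(v), stats::sd(v), max(v)))
})

#' @export
setMethod("show", "OERMap", function(object) {
  cat(sprintf("OERMap: OER = %.2f on %d hypoxic voxels (threshold %.2f)\n",
              object@oerValue, sum(object@mask), object@threshold))
})

#' @export
setMethod("show", "Observation", function(object) {
  cat(sprintf("Observation [%s] day %.1f: V = %.3f cm^3, r = %.2f mm\n",
              object@sequence, object@date, object@volume, object@radius))
})

#' @export
setMethod("show", "SimilarityReport", function(object) {
  cat("SimilarityReport (counts within evaluation region)\n")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", object@tp, object@fp,
              object@fn, object@tn))
  cat(sprintf("  PPV %.3f  sens %.3f  spec %.3f  Jaccard %.3f  VS %.3f\n",
              object@ppv, object@sensitivity, object@specificity,
              object@jaccard, object@volumeSimilarity))
})

#' @export
setMethod("show", "PatientParameters", function(object) {
  cat("PatientParameters\n")
  cat(sprintf("  D = %.3f mm^2/yr, rho = %.3f /yr, D/rho = %.3f mm^2\n",
              object@D, object@rho, object@D / object@rho))
  cat(sprintf("  velocity (supplied) = %.3f cm/yr; 2*sqrt(D*rho) = %.3f cm/yr\n",
              object@velocity, object@velocityImplied))
  if (!is.na(object@alpha))
    cat(sprintf("  alpha = %.4f /Gy (alpha/beta = %g Gy)\n", object@alpha,
                object@alphaBeta))
})

#' @export
setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d snapshots over days %.1f..%.1f (%d steps, dt %.3g d)\n",
              length(object@fields), min(object@times), max(object@times),
              object@steps, object@dt))
})

#' @export
setMethod("show", "ScenarioResult", function(object) {
  cat(sprintf("ScenarioResult '%s': %.1f%% of cells killed; survival ratio vs uniform %.3f\n",
              object@label, object@percentKilled, object@survivalRatio))
})

#' @export
setMethod("show", "VirtualPatient", function(object) {
  cat("VirtualPatient (seed", object@seed, ")\n")
  cat(sprintf("  D = %.2f mm^2/yr, rho = %.2f /yr, alpha = %.4g /Gy, OER = %.2f\n",
              object@growth@Dw, object@growth@rho, object@rt@alpha,
              object@oerValue))
  for (o in c(object@obsPre, object@obsPost))
    cat(sprintf("  obs [%s] day %.1f: V = %.2f cm^3\n", o@sequence, o@date,
                o@volume))
})

# extract the last field of a simulation
#' Final density field of a simulation
#' @param x a `SimulationResult`.
#' @return the last [CellDensityField-class] snapshot.
#' @export
finalField <- function(x) {
  stopifnot(is(x, "SimulationResult"))
  x@fields[[length(x@fields)]]
}
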