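#' Build the spatially varying invasion-rate field from a tissue map
#'
#' Glioma cells migrate about 100-fold faster along myelinated white-matter
#' tracts than through grey matter, and do not migrate through CSF. The
#' invasion rate at a partial-volume voxel is the linear blend of the pure
#' tissue rates, `D(x) = Dw * f_white(x) + (Dw/100) * f_grey(x)`, and the
#' simulation domain is the set of voxels that are majority brain parenchyma
#' (`f_grey + f_white > 0.5`); CSF and background act as no-flux obstacles
#' with `D = 0`.
#'
#' @param tissue a [TissueMap-class].
#' @param D scalar invasion rate in mm^2/year. By default interpreted as the
#'   white-matter rate `Dw`; set `dIsWhite = FALSE` to interpret it as the
#'   grey-matter rate instead (then `Dw = 100 * D`). Published net invasion
#'   rates do not always state which tissue they refer to, so both
#'   interpretations are selectable.
#' @param dIsWhite logical flag, see `D`.
#' @return A [DiffusionField-class].
#' @examples
#' tm <- makePhantom(shape = c(24, 24, 24))
#' df <- buildDiffusionMap(tm, D = 12.84)
#' @export
buildDiffusionMap <- function(tissue, D, dIsWhite = TRUE) {
  stopifnot(is(tissue, "TissueMap"))
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("invasion rate D must be a positive scalar (mm^2/year)")
  Dw <- if (dIsWhite) D else 100 * D
  Dg <- Dw / 100
  domain <- (tissue@grey + tissue@white) > 0.5
  if (!any(domain))
    stop("empty simulation domain: no voxel is majority grey/white matter")
  values <- Dw * tissue@white + Dg * tissue@grey
  values[!domain] <- 0
  new("DiffusionField", values = values, domain = domain, Dw = Dw, Dg = Dg,
      spacing = tissue@spacing)
}
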