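#' Voxel spacing and area
#'
#' @param x a [PhaseImageSet-class] or [PhantomSpec-class].
#' @return `voxelSpacing`: numeric(2), mm per voxel along each axis;
#'   `voxelArea`: single number, mm^2 per voxel.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
#' @export
setGeneric("voxelArea", function(x) standardGeneric("voxelArea"))

#' Extract one phase image
#'
#' @param x a [PhaseImageSet-class].
#' @param phase one of `"ip"`, `"oop"`, `"nc"`, `"art"`, `"pv"`, `"del"`.
#' @return the numeric matrix for that phase.
#' @export
setGeneric("phaseImage", function(x, phase) standardGeneric("phaseImage"))

#' @rdname phaseImage
#' @return `phaseNames`: the six phase identifiers.
#' @export
setGeneric("phaseNames", function(x) standardGeneric("phaseNames"))

#' Label image and label map of a MaskSet
#'
#' @param x a [MaskSet-class].
#' @return `maskLabels`: the integer label matrix; `labelMap`: the named
#'   integer map from structure name to label value.
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

#' @rdname maskLabels
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' ROI summary table of a RoiPanel
#'
#' @param x a [RoiPanel-class].
#' @return data.frame, one row per structure.
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))

setMethod("voxelSpacing", "PhaseImageSet", function(x) x@spacing)
setMethod("voxelSpacing", "PhantomSpec", function(x) x@spacing)
setMethod("voxelArea", "PhaseImageSet", function(x) prod(x@spacing))
setMethod("voxelArea", "PhantomSpec", function(x) prod(x@spacing))

setMethod("phaseImage", "PhaseImageSet", function(x, phase) {
  phase <- match.arg(phase, .PHASES)
  x@images[[phase]]
})
setMethod("phaseNames", "PhaseImageSet", function(x) .PHASES)

setMethod("maskLabels", "MaskSet", function(x) x@labels)
setMethod("labelMap", "MaskSet", function(x) x@labelMap)

setMethod("roiTable", "RoiPanel", function(x) x@stats)

setMethod("show", "PhaseImageSet", function(object) {
  d <- dim(object@images[[1L]])
  cat("PhaseImageSet:", paste(d, collapse = " x "), "voxels,",
      paste(format(object@spacing), collapse = " x "), "mm spacing\n")
  rng <- vapply(object@images, function(im) range(im), numeric(2))
  cat("  phases:", paste(sprintf("%s [%.3g, %.3g]", .PHASES, rng[1, ], rng[2, ]),
                         collapse = ", "), "\n")
})

setMethod("show", "MaskSet", function(object) {
  counts <- vapply(object@labelMap, function(l) sum(object@labels == l), integer(1))
  cat("MaskSet:", paste(dim(object@labels), collapse = " x "), "voxels\n")
  cat("  ", paste(sprintf("%s(=%d): %d vox", names(object@labelMap),
                          object@labelMap, counts), collapse = ", "), "\n", sep = "")
})

setMethod("show", "RoiPanel", function(object) {
  cat("RoiPanel with", nrow(object@stats), "structures\n")
  print(object@stats, digits = 4, row.names = FALSE)
})

setMethod("show", "BiomarkerPanel", function(object) {
  cat(sprintf(paste0("BiomarkerPanel: sFF = %.4f, CEFR(art/pv/del) = ",
                     "%.4f/%.4f/%.4f, SMI = %.3f cm2/m2\n"),
              object@sff, object@cefrArt, object@cefrPv, object@cefrDel,
              object@smi))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(object@dim, collapse = " x "), "grid,",
      paste(format(object@spacing), collapse = " x "), "mm,",
      length(object@structures), "structures,",
      sprintf("noise %s sd=%g, seed=%d", object@noiseModel, object@noiseSd,
              object@seed), "\n")
})

#' Coerce a BiomarkerPanel to a one-row data.frame
#'
#' @param x a [BiomarkerPanel-class].
#' @param ... ignored.
#' @return data.frame with columns `sff`, `cefr_art`, `cefr_pv`,
#'   `cefr_del`, `smi`, `flags`.
#' @export
as.data.frame.BiomarkerPanel <- function(x, ...) {
  data.frame(sff = x@sff, cefr_art = x@cefrArt, cefr_pv = x@cefrPv,
             cefr_del = x@cefrDel, smi = x@smi,
             flags = paste(x@flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
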