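#' @import methods
NULL

.PHASES <- c("ip", "oop", "nc", "art", "pv", "del")
.CE_PHASES <- c("art", "pv", "del")
.ROI_LABELS <- c(psm_left = 1L, psm_right = 2L, aorta = 3L)

#' StructureSpec: one geometric structure of a synthetic phantom
#'
#' Describes an elliptical structure on a 2-D phantom slice by its tissue
#' composition and enhancement behaviour. Water and fat densities are in
#' arbitrary signal units; the ground-truth fat fraction of the structure is
#' \code{F/(W+F)}. The fat-saturated baseline \code{S0} is the non-contrast
#' signal, and each contrast phase multiplies it by \code{1 + E}.
#'
#' @slot label character; one of \code{psm_left}, \code{psm_right},
#'   \code{aorta}, \code{background}, \code{subcutaneous_fat}.
#' @slot center numeric(2); ellipse centre in mm (x, y).
#' @slot semiAxes numeric(2); ellipse semi-axes in mm.
#' @slot waterDensity,fatDensity non-negative signal densities W and F.
#' @slot baselineSignal fat-sat baseline S0 (> 0 for non-background).
#' @slot enhancement named numeric(3) \code{c(art=, pv=, del=)}, each >= -1.
#'
#' @seealso [structureSpec()], [phantomSpec()], [renderPhantom()]
#' @export
setClass("StructureSpec",
  representation(
    label = "character",
    center = "numeric",
    semiAxes = "numeric",
    waterDensity = "numeric",
    fatDensity = "numeric",
    baselineSignal = "numeric",
    enhancement = "numeric"
  )
)

setValidity("StructureSpec", function(object) {
  msg <- character()
  labels <- c("psm_left", "psm_right", "aorta", "background", "subcutaneous_fat")
  if (length(object@label) != 1L || !object@label %in% labels)
    msg <- c(msg, sprintf("label must be one of: %s", paste(labels, collapse = ", ")))
  if (length(object@center) != 2L || anyNA(object@center))
    msg <- c(msg, "center must be numeric(2) in mm")
  if (length(object@semiAxes) != 2L || any(!is.finite(object@semiAxes)) ||
      any(object@semiAxes <= 0))
    msg <- c(msg, "semiAxes must be two positive lengths in mm")
  W <- object@waterDensity; F <- object@fatDensity
  if (length(W) != 1L || length(F) != 1L || !is.finite(W) || !is.finite(F) ||
      W < 0 || F < 0)
    msg <- c(msg, "water and fat densities must be single non-negative numbers")
  else if (!identical(object@label, "background") && W + F <= 0)
    msg <- c(msg, "non-background structures need water + fat density > 0")
  if (length(object@baselineSignal) != 1L || !is.finite(object@baselineSignal) ||
      (!identical(object@label, "background") && object@baselineSignal <= 0))
    msg <- c(msg, "baselineSignal S0 must be a single positive number")
  if (length(object@enhancement) != 3L ||
      !identical(names(object@enhancement), .CE_PHASES) ||
      any(!is.finite(object@enhancement)) || any(object@enhancement < -1))
    msg <- c(msg, "enhancement must be named c(art=, pv=, del=), each >= -1")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: full description of a synthetic multi-phase phantom slice
#'
#' @slot dim integer(2); grid rows x cols.
#' @slot spacing numeric(2); voxel spacing in mm (row, col directions).
#' @slot structures list of [StructureSpec-class] objects; non-background
#'   structures must not overlap (checked at render time on the voxel grid).
#' @slot noiseSd additive noise standard deviation in signal units (>= 0).
#' @slot noiseModel \code{"gaussian"} (additive) or \code{"rician"}
#'   (magnitude of complex Gaussian perturbation).
#' @slot seed integer RNG seed for the noise field.
#'
#' @seealso [phantomSpec()], [renderPhantom()]
#' @export
setClass("PhantomSpec",
  representation(
    dim = "integer",
    spacing = "numeric",
    structures = "list",
    noiseSd = "numeric",
    noiseModel = "character",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@dim) != 2L || any(object@dim < 1L))
    msg <- c(msg, "dim must be two positive integers (rows, cols)")
  if (length(object@spacing) != 2L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be two positive voxel sizes in mm")
  if (!all(vapply(object@structures, is, logical(1), class2 = "StructureSpec")))
    msg <- c(msg, "structures must all be StructureSpec objects")
  if (length(object@noiseSd) != 1L || !is.finite(object@noiseSd) ||
      object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be a single non-negative number")
  if (length(object@noiseModel) != 1L ||
      !object@noiseModel %in% c("gaussian", "rician"))
    msg <- c(msg, "noiseModel must be 'gaussian' or 'rician'")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' PhaseImageSet: the six co-registered phase images of one examination
#'
#' Holds the in-phase (\code{ip}) and out-of-phase (\code{oop}) Dixon
#' gradient-echo images and the four fat-saturated T1 images: non-contrast
#' (\code{nc}), arterial (\code{art}), portal-venous (\code{pv}) and delayed
#' (\code{del}). All six share shape and voxel spacing. Values can be
#' negative under additive Gaussian noise; no silent clipping is performed.
#'
#' @slot images named list of six numeric matrices, names
#'   \code{c("ip","oop","nc","art","pv","del")}.
#' @slot spacing numeric(2); voxel spacing in mm.
#'
#' @seealso [phaseImage()], [voxelSpacing()], [roiStats()],
#'   [writePhaseImageSet()]
#' @export
setClass("PhaseImageSet",
  representation(images = "list", spacing = "numeric")
)

setValidity("PhaseImageSet", function(object) {
  msg <- character()
  if (!identical(names(object@images), .PHASES))
    msg <- c(msg, sprintf("images must be named exactly: %s",
                          paste(.PHASES, collapse = ", ")))
  dims <- lapply(object@images, dim)
  if (length(unique(dims)) != 1L)
    msg <- c(msg, "all phase images must share the same shape")
  if (length(object@spacing) != 2L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be two positive voxel sizes in mm")
  if (length(msg)) msg else TRUE
})

#' MaskSet: integer label image aligned with a PhaseImageSet
#'
#' Labels follow the fixed map \code{c(psm_left = 1, psm_right = 2,
#' aorta = 3)}; 0 is unlabelled. Being a single label image, regions are
#' disjoint by construction; validity requires every mapped label to cover
#' at least one voxel.
#'
#' @slot labels integer matrix of region labels.
#' @slot labelMap named integer vector mapping structure name to label.
#'
#' @seealso [roiStats()], [writeMaskSet()]
#' @export
setClass("MaskSet",
  representation(labels = "matrix", labelMap = "integer")
)

setValidity("MaskSet", function(object) {
  msg <- character()
  if (!is.integer(object@labels))
    msg <- c(msg, "labels must be an integer matrix")
  if (is.null(names(object@labelMap)) || anyNA(object@labelMap) ||
      anyDuplicated(object@labelMap))
    msg <- c(msg, "labelMap must be a named integer vector with unique labels")
  else {
    present <- object@labelMap %in% object@labels
    if (!all(present))
      msg <- c(msg, sprintf("label(s) with no voxels: %s",
                            paste(names(object@labelMap)[!present], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' RoiPanel: per-structure ROI summary statistics
#'
#' One row per structure (left PSM, right PSM, aorta) with the arithmetic
#' mean signal on each of the six phases, the voxel count and the region
#' area in cm^2. The aorta means are retained even though no downstream
#' biomarker consumes them.
#'
#' @slot stats data.frame with columns \code{structure}, \code{n_voxels},
#'   \code{area_cm2} and \code{mean_<phase>} for the six phases.
#'
#' @seealso [roiStats()], [measureBiomarkers()]
#' @export
setClass("RoiPanel", representation(stats = "data.frame"))

setValidity("RoiPanel", function(object) {
  msg <- character()
  need <- c("structure", "n_voxels", "area_cm2", paste0("mean_", .PHASES))
  if (!all(need %in% names(object@stats)))
    msg <- c(msg, sprintf("stats is missing column(s): %s",
                          paste(setdiff(need, names(object@stats)), collapse = ", ")))
  else {
    if (any(object@stats$area_cm2 <= 0)) msg <- c(msg, "areas must be > 0")
    if (any(object@stats$n_voxels < 1L)) msg <- c(msg, "voxel counts must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' BiomarkerPanel: the per-patient imaging biomarkers
#'
#' sFF is the two-point Dixon signal fat fraction of the bilateral PSMs
#' (dimensionless; physically in [0, 0.5] for water-dominant muscle, but
#' out-of-range values are flagged, never altered). The three CEFR values
#' are the contrast enhancement fractions on the arterial, portal-venous
#' and delayed phases. SMI is the height-normalised mean bilateral PSM
#' cross-sectional area (cm^2 m^-2).
#'
#' @slot sff,cefrArt,cefrPv,cefrDel,smi numeric(1) biomarker values.
#' @slot flags character vector of quality flags raised during computation
#'   (e.g. a fat-fraction outside [0, 0.5]).
#'
#' @seealso [measureBiomarkers()], [computeSFF()], [computeCEFR()],
#'   [computeSMI()]
#' @export
setClass("BiomarkerPanel",
  representation(
    sff = "numeric", cefrArt = "numeric", cefrPv = "numeric",
    cefrDel = "numeric", smi = "numeric", flags = "character"
  )
)

setValidity("BiomarkerPanel", function(object) {
  msg <- character()
  for (s in c("sff", "cefrArt", "cefrPv", "cefrDel", "smi"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("%s must be a single finite number", s))
  if (length(object@smi) == 1L && is.finite(object@smi) && object@smi <= 0)
    msg <- c(msg, "smi must be > 0")
  if (length(object@cefrArt) == 1L && is.finite(object@cefrArt)) {
    ce <- c(object@cefrArt, object@cefrPv, object@cefrDel)
    if (any(is.finite(ce) & ce < -1))
      msg <- c(msg, "CEFR values cannot fall below -1")
  }
  if (length(msg)) msg else TRUE
})
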