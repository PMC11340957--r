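#' Write and read a PhaseImageSet as NIfTI files
#'
#' The six phases are written as separate NIfTI volumes with the suffixes
#' `_IP`, `_OOP`, `_NC`, `_ART`, `_PV`, `_DEL` appended to `prefix`, with
#' the voxel spacing recorded in the header. `readPhaseImageSet()` reverses
#' the operation, taking the spacing from the `_IP` header. No value
#' clipping is applied in either direction: Gaussian-noise images keep
#' their negative voxels.
#'
#' @param x a [PhaseImageSet-class].
#' @param prefix path prefix for the six output files.
#' @param gz write `.nii.gz` (default) or plain `.nii`.
#' @return `writePhaseImageSet()`: invisibly, the named vector of file
#'   paths; `readPhaseImageSet()`: a [PhaseImageSet-class].
#' @export
writePhaseImageSet <- function(x, prefix, gz = TRUE) {
  stopifnot(is(x, "PhaseImageSet"))
  ext <- if (gz) ".nii.gz" else ".nii"
  suffix <- c(ip = "_IP", oop = "_OOP", nc = "_NC",
              art = "_ART", pv = "_PV", del = "_DEL")
  files <- stats::setNames(paste0(prefix, suffix, ext), .PHASES)
  for (p in .PHASES) {
    img <- RNifti::asNifti(x@images[[p]], internal = FALSE)
    RNifti::pixdim(img) <- x@spacing
    RNifti::writeNifti(img, files[[p]])
  }
  invisible(files)
}

#' @rdname writePhaseImageSet
#' @export
readPhaseImageSet <- function(prefix, gz = TRUE) {
  ext <- if (gz) ".nii.gz" else ".nii"
  suffix <- c(ip = "_IP", oop = "_OOP", nc = "_NC",
              art = "_ART", pv = "_PV", del = "_DEL")
  files <- stats::setNames(paste0(prefix, suffix, ext), .PHASES)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("missing phase image file(s): ", paste(missing, collapse = ", "))
  imgs <- lapply(files, function(f) {
    img <- RNifti::readNifti(f)
    array(as.numeric(img), dim = dim(img))  # strip NIfTI attributes
  })
  spacing <- RNifti::pixdim(RNifti::readNifti(files[["ip"]]))[1:2]
  new("PhaseImageSet", images = imgs, spacing = as.numeric(spacing))
}

#' Write and read a MaskSet as a single integer NIfTI volume
#'
#' @param x a [MaskSet-class].
#' @param file output path (`.nii` or `.nii.gz`).
#' @param labelMap named integer label map used when reading back; defaults
#'   to the standard `c(psm_left = 1, psm_right = 2, aorta = 3)`.
#' @return `writeMaskSet()`: invisibly, `file`; `readMaskSet()`: a
#'   [MaskSet-class].
#' @export
writeMaskSet <- function(x, file) {
  stopifnot(is(x, "MaskSet"))
  img <- RNifti::asNifti(x@labels, internal = FALSE)
  img <- RNifti::asNifti(img, datatype = "int16")
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname writeMaskSet
#' @export
readMaskSet <- function(file, labelMap = c(psm_left = 1L, psm_right = 2L,
                                           aorta = 3L)) {
  img <- RNifti::readNifti(file)
  m <- matrix(as.integer(round(img)), nrow(img), ncol(img))
  new("MaskSet", labels = m, labelMap = as.integer(labelMap) |>
        stats::setNames(names(labelMap)))
}
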