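#' ROI statistics over a label mask
#'
#' Computes, for each labelled structure (left PSM, right PSM, aorta), the
#' arithmetic mean voxel signal on each of the six phases, the voxel count
#' and the region area (voxel count x voxel area, reported in cm^2).
#'
#' @param images a [PhaseImageSet-class].
#' @param masks a [MaskSet-class] aligned with `images`.
#' @return a [RoiPanel-class].
#' @examples
#' ph <- renderPhantom(psmPhantomSpec())
#' roiStats(ph$images, ph$masks)
#' @export
roiStats <- function(images, masks) {
  stopifnot(is(images, "PhaseImageSet"), is(masks, "MaskSet"))
  if (!identical(dim(images@images[[1L]]), dim(masks@labels)))
    stop("shape mismatch: images are ",
         paste(dim(images@images[[1L]]), collapse = "x"),
         " but mask is ", paste(dim(masks@labels), collapse = "x"))
  lm <- .ROI_LABELS
  inMap <- names(lm) %in% names(masks@labelMap)
  inImg <- lm %in% masks@labels
  absent <- names(lm)[!(inMap & inImg)]
  if (length(absent))
    stop("missing ROI label(s) in mask: ", paste(absent, collapse = ", "))
  vox_mm2 <- prod(images@spacing)
  rows <- lapply(names(lm), function(nm) {
    sel <- masks@labels == lm[[nm]]
    n <- sum(sel)
    means <- vapply(images@images, function(im) mean(im[sel]), numeric(1))
    cbind(data.frame(structure = nm, n_voxels = n,
                     area_cm2 = n * vox_mm2 / 100, stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(means, paste0("mean_", .PHASES)))))
  })
  new("RoiPanel", stats = do.call(rbind, rows))
}

#' Two-point Dixon signal fat fraction
#'
#' `sFF = (SI_in - SI_out) / (2 * SI_in)` from the in-phase and
#' out-of-phase signal intensities. For the bilateral-PSM biomarker the
#' inputs are the averaged left/right ROI mean signals. The result is not
#' clipped: `SI_out > SI_in` yields a negative fraction (physically
#' impossible for magnitude Dixon data) and raises a warning, and values
#' above 0.5 cannot occur since `SI_out >= 0`. Note the magnitude Dixon
#' pair is symmetric in water and fat, so a fat-dominant tissue with true
#' fat fraction `ff > 0.5` is reported as `1 - ff` (aliasing).
#'
#' @param siIn in-phase signal intensity (> 0); vectorised.
#' @param siOut out-of-phase signal intensity (>= 0); vectorised.
#' @return the signal fat fraction(s).
#' @examples
#' computeSFF(100, 80)  # 0.10
#' computeSFF(100, 0)   # 0.50, the equal water/fat upper bound
#' @export
computeSFF <- function(siIn, siOut) {
  if (any(!is.finite(siIn)) || any(siIn <= 0))
    stop("in-phase signal must be finite and > 0")
  if (any(!is.finite(siOut)) || any(siOut < 0))
    stop("out-of-phase signal must be finite and >= 0")
  if (any(siOut > siIn))
    warning("SI_out > SI_in: negative fat fraction implied; value not clipped")
  (siIn - siOut) / (2 * siIn)
}

#' Contrast enhancement fraction
#'
#' `CEFR = (SI_enhanced - SI_noncontrast) / SI_noncontrast`, computed per
#' post-contrast phase from the fat-saturated T1 signals. A non-positive
#' non-contrast signal is rejected (the analysis treats non-enhancing
#' studies as excluded, never as a silent NaN).
#'
#' @param siNoncontrast non-contrast signal intensity (> 0); vectorised.
#' @param siEnhanced post-contrast signal intensity; vectorised.
#' @return the enhancement fraction(s); negative values (signal drop) are
#'   legitimate outputs.
#' @examples
#' computeCEFR(200, 220)  #  0.10
#' computeCEFR(100, 90)   # -0.10
#' @export
computeCEFR <- function(siNoncontrast, siEnhanced) {
  if (any(!is.finite(siNoncontrast)) || any(siNoncontrast <= 0))
    stop("non-contrast signal must be finite and > 0 ",
         "(non-enhancing studies are excluded, not propagated as NaN)")
  if (any(!is.finite(siEnhanced)))
    stop("enhanced signal must be finite")
  (siEnhanced - siNoncontrast) / siNoncontrast
}

#' Skeletal muscle index
#'
#' Mean of the two paraspinous muscle cross-sectional areas divided by the
#' patient's height squared: `SMI = ((A_left + A_right) / 2) / height^2`,
#' in cm^2 m^-2.
#'
#' @param areaLeft,areaRight muscle areas in cm^2 (> 0).
#' @param height patient height in m (> 0).
#' @return the skeletal muscle index (cm^2 m^-2); vectorised.
#' @examples
#' computeSMI(8.0, 9.0, 1.8)  # 8.5 / 3.24 = 2.623
#' @export
computeSMI <- function(areaLeft, areaRight, height) {
  if (any(!is.finite(areaLeft)) || any(!is.finite(areaRight)) ||
      any(areaLeft <= 0) || any(areaRight <= 0))
    stop("muscle areas must be finite and > 0")
  if (any(!is.finite(height)) || any(height <= 0))
    stop("height must be finite and > 0 (in metres)")
  ((areaLeft + areaRight) / 2) / height^2
}

#' Classic (pre-sodium) MELD score
#'
#' The standard UNOS Model for End-Stage Liver Disease equation:
#' each laboratory value is clamped below at 1.0, creatinine is capped at
#' 4.0 mg/dL (and set to 4.0 under dialysis), and
#' `MELD = 10 * (0.957 ln(Cr) + 0.378 ln(Tbili) + 1.12 ln(INR) + 0.643)`,
#' rounded to the nearest integer and bounded to `[6, 40]`.
#'
#' @param creatinine serum creatinine, mg/dL (> 0); vectorised.
#' @param tbili total bilirubin, mg/dL (> 0); vectorised.
#' @param inr international normalised ratio (> 0); vectorised.
#' @param dialysis logical; dialysis within the scoring window forces
#'   creatinine to 4.0.
#' @return integer MELD score(s) in `[6, 40]`.
#' @examples
#' computeMELD(1.0, 1.0, 1.0)      # 6 (lower bound)
#' computeMELD(0.93, 1.64, 1.25)   # 11
#' @export
computeMELD <- function(creatinine, tbili, inr, dialysis = FALSE) {
  if (any(!is.finite(creatinine)) || any(creatinine <= 0) ||
      any(!is.finite(tbili)) || any(tbili <= 0) ||
      any(!is.finite(inr)) || any(inr <= 0))
    stop("MELD labs (creatinine, tbili, INR) must be finite and > 0")
  n <- max(length(creatinine), length(tbili), length(inr), length(dialysis))
  cr <- rep_len(creatinine, n); tb <- rep_len(tbili, n)
  ir <- rep_len(inr, n); dia <- rep_len(as.logical(dialysis), n)
  cr[dia] <- 4.0
  cr <- pmin(pmax(cr, 1.0), 4.0)
  tb <- pmax(tb, 1.0)
  ir <- pmax(ir, 1.0)
  score <- 10 * (0.957 * log(cr) + 0.378 * log(tb) + 1.12 * log(ir) + 0.643)
  as.integer(pmin(pmax(round(score), 6L), 40L))
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement between two measurement series as
#' `rho_c = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`,
#' with population (1/n) moments. Unlike Pearson's r it penalises both
#' scale and location shifts, so `|rho_c| <= |r|` with equality iff the
#' two series share mean and variance.
#'
#' @param x,y numeric vectors of equal length >= 3, finite values.
#' @return the concordance coefficient in `[-1, 1]`.
#' @examples
#' linCCC(1:10, 1:10)               # 1
#' linCCC(c(1, 2, 3, 4), c(1.1, 2.1, 2.9, 4.2))
#' @export
linCCC <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  denom <- vx + vy + (mx - my)^2
  if (denom == 0)
    stop("concordance undefined: both series constant with equal means")
  2 * mean((x - mx) * (y - my)) / denom
}

#' Full imaging-biomarker panel from images and masks
#'
#' Chains [roiStats()] with the biomarker formulas. Following the bilateral
#' averaging convention, the left and right PSM ROI mean signals are
#' averaged per phase first and the sFF/CEFR formulas applied to the
#' averaged signals (`averaging = "pooled"`, the default); the alternative
#' `"per_muscle"` applies the formulas per muscle and averages the two
#' biomarker values.
#'
#' @param images a [PhaseImageSet-class].
#' @param masks a [MaskSet-class].
#' @param height patient height in m.
#' @param averaging `"pooled"` or `"per_muscle"` (see Details).
#' @return a [BiomarkerPanel-class]; out-of-range fat fractions are noted
#'   in its `flags` slot rather than altered.
#' @examples
#' ph <- renderPhantom(psmPhantomSpec(ff = 0.1))
#' measureBiomarkers(ph$images, ph$masks, height = 1.75)
#' @export
measureBiomarkers <- function(images, masks, height,
                              averaging = c("pooled", "per_muscle")) {
  averaging <- match.arg(averaging)
  panel <- roiStats(images, masks)
  st <- panel@stats
  left <- st[st$structure == "psm_left", ]
  right <- st[st$structure == "psm_right", ]
  flags <- character()

  if (averaging == "pooled") {
    m <- (unlist(left[paste0("mean_", .PHASES)]) +
          unlist(right[paste0("mean_", .PHASES)])) / 2
    names(m) <- .PHASES
    sff <- computeSFF(m[["ip"]], m[["oop"]])
    cefr <- vapply(.CE_PHASES, function(p) computeCEFR(m[["nc"]], m[[p]]),
                   numeric(1))
  } else {
    sffs <- c(computeSFF(left$mean_ip, left$mean_oop),
              computeSFF(right$mean_ip, right$mean_oop))
    sff <- mean(sffs)
    cefr <- vapply(.CE_PHASES, function(p)
      mean(c(computeCEFR(left$mean_nc, left[[paste0("mean_", p)]]),
             computeCEFR(right$mean_nc, right[[paste0("mean_", p)]]))),
      numeric(1))
  }
  if (sff < 0 || sff > 0.5)
    flags <- c(flags, sprintf("sFF %.4f outside the water-dominant range [0, 0.5]",
                              sff))
  smi <- computeSMI(left$area_cm2, right$area_cm2, height)
  new("BiomarkerPanel", sff = unname(sff),
      cefrArt = unname(cefr[["art"]]), cefrPv = unname(cefr[["pv"]]),
      cefrDel = unname(cefr[["del"]]), smi = smi, flags = flags)
}
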