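## Gaussian-copula synthetic cohort generator.
##
## Continuous variables are drawn from a Gaussian copula whose latent
## correlations are back-computed so that the OBSERVED-scale Pearson
## correlations match the configured targets (closed-form inversion for
## the log-normal marginals). CMCS binaries are thresholded projections of
## a shared latent severity score (the MELD-weighted laboratory z-scores),
## so group differences in the biomarkers emerge jointly rather than being
## painted on per column. The MELD column is recomputed from the simulated
## labs, never drawn.

# moment-matched log-normal parameters
.lnormPars <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

# Latent (copula-scale) correlation that yields observed Pearson r after
# the marginal transforms. sigma* are the log-scale SDs (NA for normal
# marginals, for which the correlation passes through unchanged).
.latentFromObserved <- function(r, sigma1 = NA, sigma2 = NA) {
  if (is.na(sigma1) && is.na(sigma2)) return(r)
  if (is.na(sigma1) != is.na(sigma2)) {  # one normal, one log-normal
    s <- if (is.na(sigma1)) sigma2 else sigma1
    rho <- r * sqrt(exp(s^2) - 1) / s
  } else {
    arg <- 1 + r * sqrt((exp(sigma1^2) - 1) * (exp(sigma2^2) - 1))
    if (arg <= 0) stop("target correlation ", r, " unattainable for these marginals")
    rho <- log(arg) / (sigma1 * sigma2)
  }
  if (abs(rho) > 1)
    stop("target correlation ", r, " unattainable for these marginals ",
         "(latent value ", round(rho, 3), ")")
  rho
}

# Nearest-PSD repair by eigenvalue clipping, rescaled to unit diagonal.
# Returns the repaired matrix with an attribute reporting the largest
# entry-wise adjustment; errors if that exceeds maxAdjust.
.nearPSDCorr <- function(R, maxAdjust = 0.05, eigFloor = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 0) {
    attr(R, "psd_adjust") <- 0
    return(R)
  }
  v <- pmax(e$values, eigFloor)
  R2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / outer(d, d)
  diag(R2) <- 1
  adj <- max(abs(R2 - R))
  if (adj > maxAdjust)
    stop(sprintf(paste0("correlation matrix is not positive semi-definite and ",
                        "the nearest-PSD repair changes entries by up to %.3f ",
                        "(> %.3f); the targets are mutually inconsistent"),
                 adj, maxAdjust))
  dimnames(R2) <- dimnames(R)
  attr(R2, "psd_adjust") <- adj
  R2
}

#' Default parameters for the synthetic patient cohort
#'
#' The defaults encode the published cohort: marginal means/SDs of the
#' demographics, laboratory values and imaging biomarkers; the signed
#' biomarker-covariate correlation targets; the prevalence of each
#' clinical measure of cirrhosis severity (CMCS); and the loading of each
#' binary on the shared latent severity score. Creatinine, total bilirubin
#' and INR use log-normal marginals (their printed SDs imply strong right
#' skew, e.g. Tbili 1.64 +/- 2.11) and share a latent correlation of 0.6,
#' chosen so the MELD recomputed from the simulated labs reproduces the
#' cohort's MELD distribution (10.9 +/- 5.3).
#'
#' @param n number of patients.
#' @param seed RNG seed.
#' @return a classed list of generator parameters; every component can be
#'   overridden by assignment before passing to [simulateCohort()].
#' @export
cohortSimParams <- function(n = 224, seed = 1L) {
  marginals <- data.frame(
    variable = c("age", "bmi", "albumin", "creatinine", "tbili", "inr",
                 "smi", "sff", "cefr_art", "cefr_pv", "cefr_del"),
    mean = c(59.6, 31, 3.55, 0.93, 1.64, 1.25,
             5.26, 0.13, 0.10, 0.22, 0.25),
    sd = c(9.7, 7.3, 0.65, 0.38, 2.11, 0.35,
           1.95, 0.08, 0.13, 0.14, 0.16),
    dist = c("normal", "normal", "normal", "lognormal", "lognormal",
             "lognormal", "normal", "normal", "normal", "normal", "normal"),
    stringsAsFactors = FALSE)

  biomarkers <- c("sff", "smi", "cefr_art", "cefr_pv", "cefr_del")
  covariates <- c("albumin", "creatinine", "tbili", "inr", "bmi")
  target <- rbind(
    data.frame(var1 = "albumin",    var2 = biomarkers,
               r = c(-0.03, 0.10, 0.06, 0.15, 0.13)),
    data.frame(var1 = "creatinine", var2 = biomarkers,
               r = c(-0.05, 0.08, -0.06, -0.04, -0.04)),
    data.frame(var1 = "tbili",      var2 = biomarkers,
               r = c(-0.12, -0.15, -0.12, -0.22, -0.20)),
    data.frame(var1 = "inr",        var2 = biomarkers,
               r = c(-0.02, -0.01, -0.07, -0.15, -0.10)),
    data.frame(var1 = "bmi",        var2 = biomarkers,
               r = c(0.34, 0.36, 0.04, 0.02, 0.05)),
    data.frame(var1 = "sff", var2 = c("cefr_pv", "cefr_del"),
               r = c(0.13, 0.15)))

  # latent-scale design correlations (shared hepatic-dysfunction severity
  # couples the three MELD labs; value chosen so derived MELD ~ 10.9 +/- 5.3)
  latentDesign <- data.frame(
    var1 = c("creatinine", "creatinine", "tbili"),
    var2 = c("tbili", "inr", "inr"),
    rho = c(0.6, 0.6, 0.6), stringsAsFactors = FALSE)

  prevalence <- c(sex_f = 89 / 224, api = 83 / 224, ph = 47 / 224,
                  vpi = 164 / 224, vbh = 38 / 224, sbp = 18 / 224,
                  tips = 15 / 224, diabetes = 103 / 224, thyroid = 19 / 224)
  loading <- c(sex_f = 0, api = 0.7, ph = 0.8, vpi = 0.5, vbh = 0.6,
               sbp = 0.6, tips = 0.5, diabetes = 0, thyroid = 0)

  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    marginals = marginals, targetCorr = target,
    latentDesign = latentDesign,
    prevalence = prevalence, loading = loading,
    # weights of the latent lab z-scores in the severity score: the MELD
    # equation's own coefficients
    severityWeights = c(creatinine = 0.957, tbili = 0.378, inr = 1.12),
    ascitesGradeProb = c(trace = 32, small = 23, moderate = 19, large = 9) / 83,
    varicesGradeProb = c(small = 128, moderate = 18, large = 18) / 164,
    etiologyProb = c(VIRAL = 69, NASH = 66, ETOH = 61, OTHER = 11,
                     `ETOH+VIRAL` = 11, `ETOH+NASH` = 3, `NASH+VIRAL` = 2,
                     `VIRAL+OTHER` = 1) / 224,
    heightBySex = list(M = c(mean = 1.77, sd = 0.07),
                       F = c(mean = 1.63, sd = 0.07)),
    maxPsdAdjust = 0.05
  ), class = "CohortSimParams")
}

#' @export
print.CohortSimParams <- function(x, ...) {
  cat("CohortSimParams: n =", x$n, ", seed =", x$seed, "\n")
  cat("  continuous variables:", paste(x$marginals$variable, collapse = ", "), "\n")
  cat("  configured correlations:", nrow(x$targetCorr),
      "| CMCS binaries:", length(x$prevalence), "\n")
  invisible(x)
}

# Assemble the latent correlation matrix over the continuous variables.
.latentCorrMatrix <- function(params) {
  m <- params$marginals
  p <- nrow(m)
  sig <- ifelse(m$dist == "lognormal",
                vapply(seq_len(p), function(i)
                  .lnormPars(m$mean[i], m$sd[i])[["sigma"]], numeric(1)),
                NA_real_)
  R <- diag(p)
  dimnames(R) <- list(m$variable, m$variable)
  for (k in seq_len(nrow(params$targetCorr))) {
    a <- params$targetCorr$var1[k]; b <- params$targetCorr$var2[k]
    i <- match(a, m$variable); j <- match(b, m$variable)
    if (is.na(i) || is.na(j)) stop("unknown variable in target correlations: ",
                                   if (is.na(i)) a else b)
    R[i, j] <- R[j, i] <- .latentFromObserved(params$targetCorr$r[k],
                                              sig[i], sig[j])
  }
  for (k in seq_len(nrow(params$latentDesign))) {
    i <- match(params$latentDesign$var1[k], m$variable)
    j <- match(params$latentDesign$var2[k], m$variable)
    R[i, j] <- R[j, i] <- params$latentDesign$rho[k]
  }
  .nearPSDCorr(R, maxAdjust = params$maxPsdAdjust)
}

#' Simulate a synthetic patient cohort datasheet
#'
#' Draws a cohort of `n` patients whose continuous variables follow a
#' Gaussian copula with the configured observed-scale correlations and
#' marginals (normal, or moment-matched log-normal for the right-skewed
#' labs), whose CMCS binaries are thresholded from a shared latent severity
#' score at the quantile matching each prevalence, and whose MELD column is
#' recomputed from the simulated labs via [computeMELD()] (never drawn
#' independently). The same seed yields an identical datasheet.
#'
#' @param params a [cohortSimParams()] list.
#' @param n,seed convenience overrides of `params$n` and `params$seed`.
#' @return data.frame, one row per patient, in the canonical cohort schema
#'   (see [cohortSchema()]); attributes `psd_adjust` (largest entry change
#'   from the nearest-PSD repair) and `params` carry the generator truth.
#' @examples
#' coh <- simulateCohort(cohortSimParams(n = 50, seed = 7))
#' summary(coh$meld)
#' @export
simulateCohort <- function(params = cohortSimParams(), n = params$n,
                           seed = params$seed) {
  stopifnot(inherits(params, "CohortSimParams"))
  m <- params$marginals
  R <- .latentCorrMatrix(params)

  .withSeed(seed, function() {
    p <- nrow(m)
    Z <- matrix(stats::rnorm(n * p), n, p) %*% chol(R)
    colnames(Z) <- m$variable

    cont <- lapply(seq_len(p), function(i) {
      if (m$dist[i] == "lognormal") {
        lp <- .lnormPars(m$mean[i], m$sd[i])
        exp(lp[["mu"]] + lp[["sigma"]] * Z[, i])
      } else {
        m$mean[i] + m$sd[i] * Z[, i]
      }
    })
    names(cont) <- m$variable

    # latent severity: MELD-weighted lab z-scores, standardised
    w <- params$severityWeights
    labIdx <- match(names(w), m$variable)
    sevVar <- drop(t(w) %*% R[labIdx, labIdx] %*% w)
    sev <- drop(Z[, labIdx] %*% w) / sqrt(sevVar)

    bins <- lapply(names(params$prevalence), function(b) {
      lam <- params$loading[[b]]
      lat <- lam * sev + sqrt(1 - lam^2) * stats::rnorm(n)
      lat > stats::qnorm(1 - params$prevalence[[b]])
    })
    names(bins) <- names(params$prevalence)

    ascites <- rep("no", n)
    nApi <- sum(bins$api)
    if (nApi) ascites[bins$api] <- sample(names(params$ascitesGradeProb), nApi,
                                          replace = TRUE,
                                          prob = params$ascitesGradeProb)
    varices <- rep("no", n)
    nVpi <- sum(bins$vpi)
    if (nVpi) varices[bins$vpi] <- sample(names(params$varicesGradeProb), nVpi,
                                          replace = TRUE,
                                          prob = params$varicesGradeProb)
    etiology <- sample(names(params$etiologyProb), n, replace = TRUE,
                       prob = params$etiologyProb)
    sex <- ifelse(bins$sex_f, "F", "M")
    hb <- params$heightBySex
    height <- ifelse(sex == "F",
                     stats::rnorm(n, hb$F[["mean"]], hb$F[["sd"]]),
                     stats::rnorm(n, hb$M[["mean"]], hb$M[["sd"]]))
    height <- pmin(pmax(height, 1.2), 2.2)

    labs <- lapply(cont[c("albumin", "creatinine", "tbili", "inr")],
                   function(v) pmax(v, 0.01))
    df <- data.frame(
      id = sprintf("SYN-%04d", seq_len(n)),
      sex = sex,
      age = round(cont$age, 1),
      height = round(height, 2),
      bmi = cont$bmi,
      albumin = labs$albumin,
      creatinine = labs$creatinine,
      tbili = labs$tbili,
      inr = labs$inr,
      meld = computeMELD(labs$creatinine, labs$tbili, labs$inr),
      ascites_grade = ascites,
      varices_grade = varices,
      ph = bins$ph, sbp = bins$sbp, vbh = bins$vbh, tips = bins$tips,
      diabetes = bins$diabetes, thyroid = bins$thyroid,
      etiology = etiology,
      sff = cont$sff,
      smi = pmax(cont$smi, 0.2),
      cefr_art = cont$cefr_art,
      cefr_pv = cont$cefr_pv,
      cefr_del = cont$cefr_del,
      stringsAsFactors = FALSE)
    attr(df, "psd_adjust") <- attr(R, "psd_adjust")
    attr(df, "params") <- params
    df
  })
}

#' Write a simulated cohort to CSV with a JSON parameter sidecar
#'
#' @param cohort data.frame from [simulateCohort()].
#' @param file output CSV path; the sidecar is written next to it as
#'   `<file>.params.json`.
#' @return invisibly, the CSV path.
#' @export
writeCohort <- function(cohort, file) {
  utils::write.csv(cohort, file, row.names = FALSE)
  params <- attr(cohort, "params")
  if (!is.null(params)) {
    side <- paste0(file, ".params.json")
    jsonlite::write_json(
      list(n = params$n, seed = params$seed, marginals = params$marginals,
           target_correlations = params$targetCorr,
           latent_design = params$latentDesign,
           prevalence = as.list(params$prevalence),
           loading = as.list(params$loading),
           psd_adjust = attr(cohort, "psd_adjust")),
      side, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
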