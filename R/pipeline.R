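.BIOMARKERS <- c("sff", "smi", "cefr_art", "cefr_pv", "cefr_del")
.TABLE3_COVARIATES <- c("albumin", "creatinine", "tbili", "inr", "meld", "bmi")

#' Canonical cohort table schema
#'
#' The per-patient datasheet columns the pipeline understands, with types,
#' units and default header aliases. Real exports rarely use these exact
#' headers; [loadCohort()] resolves them through the alias map (extendable
#' via its `aliasMap` argument).
#'
#' @return data.frame with columns `column`, `type`, `unit`, `required`,
#'   `aliases` (comma-separated).
#' @export
cohortSchema <- function() {
  s <- function(column, type, unit, required, aliases)
    data.frame(column = column, type = type, unit = unit,
               required = required, aliases = aliases,
               stringsAsFactors = FALSE)
  rbind(
    s("id", "character", "", FALSE, "patient_id,subject,mrn_anon"),
    s("sex", "factor(M/F)", "", TRUE, "gender,sex_assigned_at_birth"),
    s("age", "numeric", "years", TRUE, "age_years,age_at_scan"),
    s("height", "numeric", "m", FALSE, "height_m,height_cm,ht"),
    s("bmi", "numeric", "kg/m2", TRUE, "body_mass_index"),
    s("albumin", "numeric", "g/dL", TRUE, "alb"),
    s("creatinine", "numeric", "mg/dL", TRUE, "cr,creat"),
    s("tbili", "numeric", "mg/dL", TRUE, "total_bilirubin,bilirubin,tbil"),
    s("inr", "numeric", "", TRUE, "international_normalized_ratio"),
    s("meld", "integer", "", FALSE, "meld_score"),
    s("ascites_grade", "factor", "", TRUE,
      "ascites,ascites_volume,api_grade"),
    s("varices_grade", "factor", "", TRUE,
      "varices,variceal_size,vpi_grade"),
    s("ph", "logical", "", TRUE, "paracentesis,paracentesis_history"),
    s("sbp", "logical", "", FALSE, "spontaneous_bacterial_peritonitis"),
    s("vbh", "logical", "", TRUE, "variceal_bleed,variceal_bleed_history"),
    s("tips", "logical", "", FALSE, "tips_history"),
    s("diabetes", "logical", "", FALSE, "dm,diabetes_mellitus"),
    s("thyroid", "logical", "", FALSE, "thyroid_dysfunction"),
    s("etiology", "factor", "", FALSE, "cirrhosis_etiology"),
    s("sff", "numeric", "", TRUE, "psm_sff,signal_fat_fraction"),
    s("smi", "numeric", "cm2/m2", TRUE, "psm_smi,skeletal_muscle_index"),
    s("cefr_art", "numeric", "", TRUE, "psm_cefr_art,cefr_arterial"),
    s("cefr_pv", "numeric", "", TRUE, "psm_cefr_pv,cefr_portal_venous"),
    s("cefr_del", "numeric", "", TRUE, "psm_cefr_del,cefr_delayed"))
}

.normHeader <- function(x) gsub("_+", "_", gsub("[^a-z0-9]+", "_", tolower(x)))

.asLogical <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[v %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

#' Load and validate a cohort datasheet
#'
#' Reads a CSV (or takes a data.frame), resolves column headers through
#' the schema's alias map, checks units and value ranges, and computes the
#' derived columns: `api` (any ascites, trace included), `vpi` (any
#' varices, small included), `meld_computed` (from the labs via
#' [computeMELD()]) and `high_meld` (MELD above `meldCutoff`, using the
#' stored MELD column where present, which is also reconciled against the
#' recomputed score). Heights with a median above 3 are taken to be in cm
#' and converted to m with a warning. Out-of-range values raise per-column
#' warnings but rows are retained; analyses are complete-case per cell.
#'
#' @param path CSV file path, or a data.frame already in memory.
#' @param aliasMap named list of extra header aliases, canonical name ->
#'   character vector of accepted headers (merged over the schema's own).
#' @param meldCutoff MELD dichotomy threshold (default 17).
#' @return validated data.frame; `attr(, "audit")` records the column
#'   mapping, unit conversions, range findings and MELD discrepancies.
#' @export
loadCohort <- function(path, aliasMap = list(), meldCutoff = 17) {
  df <- if (is.data.frame(path)) path
        else utils::read.csv(path, stringsAsFactors = FALSE)
  schema <- cohortSchema()
  names(df) <- .normHeader(names(df))
  audit <- list(n_rows = nrow(df), mapping = list(), conversions = character(),
                range_warnings = character())

  for (i in seq_len(nrow(schema))) {
    canon <- schema$column[i]
    cands <- unique(c(canon, strsplit(schema$aliases[i], ",")[[1]],
                      aliasMap[[canon]]))
    cands <- .normHeader(cands)
    hit <- cands[cands %in% names(df)][1]
    if (is.na(hit)) {
      if (schema$required[i])
        stop("required column '", canon, "' not found; accepted headers: ",
             paste(cands, collapse = ", "),
             ". Available: ", paste(names(df), collapse = ", "))
      next
    }
    if (!identical(hit, canon)) {
      names(df)[names(df) == hit] <- canon
      audit$mapping[[canon]] <- hit
    }
  }

  for (col in c("ph", "sbp", "vbh", "tips", "diabetes", "thyroid"))
    if (col %in% names(df)) df[[col]] <- .asLogical(df[[col]])
  for (col in c("ascites_grade", "varices_grade"))
    df[[col]] <- tolower(trimws(as.character(df[[col]])))

  if ("height" %in% names(df) &&
      isTRUE(stats::median(df$height, na.rm = TRUE) > 3)) {
    df$height <- df$height / 100
    warning("height column appears to be in cm; converted to m")
    audit$conversions <- c(audit$conversions, "height: cm -> m")
  }

  rangeCheck <- function(col, lo, hi) {
    if (!col %in% names(df)) return()
    bad <- which(is.finite(df[[col]]) & (df[[col]] < lo | df[[col]] > hi))
    if (length(bad)) {
      msg <- sprintf("%s: %d value(s) outside [%g, %g] (rows retained)",
                     col, length(bad), lo, hi)
      warning(msg)
      audit$range_warnings <<- c(audit$range_warnings, msg)
    }
  }
  rangeCheck("height", 0.5, 2.5); rangeCheck("bmi", 10, 80)
  rangeCheck("albumin", 0.5, 7); rangeCheck("creatinine", 0.1, 15)
  rangeCheck("tbili", 0.05, 50); rangeCheck("inr", 0.5, 12)
  rangeCheck("sff", -0.25, 0.75); rangeCheck("smi", 0.1, 25)

  df$api <- df$ascites_grade != "no"
  df$vpi <- df$varices_grade != "no"
  complete <- is.finite(df$creatinine) & is.finite(df$tbili) &
    is.finite(df$inr) & df$creatinine > 0 & df$tbili > 0 & df$inr > 0
  df$meld_computed <- NA_integer_
  df$meld_computed[complete] <- computeMELD(df$creatinine[complete],
                                            df$tbili[complete],
                                            df$inr[complete])
  if (!"meld" %in% names(df)) {
    df$meld <- df$meld_computed
    audit$meld_source <- "computed_from_labs"
  } else {
    mism <- sum(df$meld != df$meld_computed, na.rm = TRUE)
    audit$meld_source <- "stored_column"
    audit$meld_discrepancies <- mism
  }
  df$high_meld <- df$meld > meldCutoff
  attr(df, "audit") <- audit
  df
}

.md5OfObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' Run the full cohort analysis
#'
#' Recomputes the study's three result tables from a loaded cohort:
#' descriptive statistics (table 1), the two-group comparison of each
#' imaging biomarker against each clinical measure of cirrhosis severity
#' (table 2: sex, API, PH, VPI, VBH, MELD dichotomy), Pearson correlations
#' of each biomarker with the laboratory covariates, MELD and BMI plus all
#' biomarker-biomarker pairs (table 3), and ROC analysis of the three CEFR
#' phases for the high-MELD group (low enhancement oriented as predicting
#' high MELD). Every cell carries the complete-case n and the test
#' provenance; a Benjamini-Hochberg column is appended to tables 2 and 3
#' as supplementary output (the primary analysis applies no
#' multiple-testing correction).
#'
#' @param cohort data.frame from [loadCohort()] or [simulateCohort()].
#' @param meldCutoff MELD dichotomy threshold (default 17).
#' @return list of class `psmAnalysisReport`: `table1`, `table2`,
#'   `table3`, `roc`, `meta`.
#' @export
runAnalysis <- function(cohort, meldCutoff = 17) {
  if (!"api" %in% names(cohort)) cohort <- loadCohort(cohort,
                                                      meldCutoff = meldCutoff)
  if (!"high_meld" %in% names(cohort) || meldCutoff != 17)
    cohort$high_meld <- cohort$meld > meldCutoff

  contVars <- c("age", "bmi", "meld", "albumin", "creatinine", "tbili",
                "inr", .BIOMARKERS)
  contVars <- intersect(contVars, names(cohort))
  table1_cont <- do.call(rbind, lapply(contVars, function(v) {
    x <- cohort[[v]][is.finite(cohort[[v]])]
    data.frame(variable = v, mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x), n = length(x),
               stringsAsFactors = FALSE)
  }))
  catVars <- intersect(c("sex", "ascites_grade", "varices_grade", "etiology",
                         "ph", "sbp", "vbh", "tips", "diabetes", "thyroid",
                         "api", "vpi", "high_meld"), names(cohort))
  table1_cat <- do.call(rbind, lapply(catVars, function(v) {
    tb <- table(cohort[[v]], useNA = "no")
    data.frame(variable = v, level = names(tb), count = as.integer(tb),
               percent = 100 * as.integer(tb) / sum(tb),
               stringsAsFactors = FALSE)
  }))

  groupings <- list(
    sex = list(sel = cohort$sex == "M", labels = c("M", "F")),
    api = list(sel = cohort$api, labels = c("yes", "no")),
    ph = list(sel = cohort$ph, labels = c("yes", "no")),
    vpi = list(sel = cohort$vpi, labels = c("yes", "no")),
    vbh = list(sel = cohort$vbh, labels = c("yes", "no")),
    high_meld = list(sel = cohort$high_meld, labels = c(">17", "<=17")))
  table2 <- do.call(rbind, lapply(names(groupings), function(g) {
    sel <- groupings[[g]]$sel
    do.call(rbind, lapply(.BIOMARKERS, function(bm) {
      ok <- !is.na(sel)
      res <- tryCatch(
        compareGroups(cohort[[bm]][ok & sel], cohort[[bm]][ok & !sel],
                      variable = bm, labels = groupings[[g]]$labels),
        error = function(e) NULL)
      if (is.null(res)) {  # empty/degenerate group: cell not computable
        res <- data.frame(variable = bm, group_a = groupings[[g]]$labels[1],
                          group_b = groupings[[g]]$labels[2],
                          mean_a = NA_real_, sd_a = NA_real_,
                          n_a = sum(ok & sel),
                          mean_b = NA_real_, sd_b = NA_real_,
                          n_b = sum(ok & !sel), n_missing_a = 0L,
                          n_missing_b = 0L, normality_p_a = NA_real_,
                          normality_p_b = NA_real_,
                          test_used = "not_computable", statistic = NA_real_,
                          p = NA_real_, p_welch = NA_real_,
                          p_mann_whitney = NA_real_, decision_flips = NA,
                          stringsAsFactors = FALSE)
      }
      cbind(grouping = g, res, stringsAsFactors = FALSE)
    }))
  }))
  table2$p_bh_supplementary <- stats::p.adjust(table2$p, method = "BH")

  pairs3 <- rbind(
    expand.grid(var1 = .TABLE3_COVARIATES, var2 = .BIOMARKERS,
                stringsAsFactors = FALSE),
    do.call(rbind, do.call(c, lapply(seq_along(.BIOMARKERS)[-1], function(j)
      lapply(seq_len(j - 1), function(i)
        data.frame(var1 = .BIOMARKERS[i], var2 = .BIOMARKERS[j],
                   stringsAsFactors = FALSE))))))
  table3 <- do.call(rbind, lapply(seq_len(nrow(pairs3)), function(k) {
    v1 <- pairs3$var1[k]; v2 <- pairs3$var2[k]
    tryCatch(pearsonCI(cohort[[v1]], cohort[[v2]], pair = c(v1, v2)),
             error = function(e)
               data.frame(var1 = v1, var2 = v2, r = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p = NA_real_, n = NA_integer_,
                          stringsAsFactors = FALSE))
  }))
  table3$p_bh_supplementary <- stats::p.adjust(table3$p, method = "BH")

  roc <- lapply(c("cefr_art", "cefr_pv", "cefr_del"), function(bm) {
    ok <- is.finite(cohort[[bm]]) & !is.na(cohort$high_meld)
    res <- tryCatch(rocAuc(cohort[[bm]][ok], cohort$high_meld[ok],
                           direction = "lower"),
                    error = function(e) list(auc = NA_real_,
                                             direction = "lower",
                                             n_pos = sum(cohort$high_meld[ok]),
                                             n_neg = sum(!cohort$high_meld[ok]),
                                             points = NULL))
    res$marker <- bm
    res
  })
  names(roc) <- c("cefr_art", "cefr_pv", "cefr_del")

  structure(list(
    table1 = list(continuous = table1_cont, categorical = table1_cat),
    table2 = table2, table3 = table3, roc = roc,
    meta = list(n = nrow(cohort), meld_cutoff = meldCutoff,
                package_version = as.character(utils::packageVersion("psmEnhance")),
                input_hash = .md5OfObject(cohort[order(names(cohort))]))
  ), class = "psmAnalysisReport")
}

#' @export
print.psmAnalysisReport <- function(x, ...) {
  cat("psmAnalysisReport: n =", x$meta$n, "patients, MELD cutoff",
      x$meta$meld_cutoff, "\n")
  sig2 <- sum(x$table2$p < 0.05, na.rm = TRUE)
  sig3 <- sum(x$table3$p < 0.05, na.rm = TRUE)
  cat("  table2:", nrow(x$table2), "comparisons,", sig2, "with p < 0.05\n")
  cat("  table3:", nrow(x$table3), "correlations,", sig3, "with p < 0.05\n")
  aucs <- vapply(x$roc, function(r) r$auc, numeric(1))
  cat("  ROC AUC (low CEFR predicts high MELD):",
      paste(sprintf("%s %.3f", names(aucs), aucs), collapse = ", "), "\n")
  invisible(x)
}

#' Write an analysis report to CSV files and one JSON document
#'
#' CSV outputs round for display the way the published tables do
#' (biomarker means and r to 2 decimals, p to 3); the JSON keeps full
#' precision. Output is deterministic: the same cohort and configuration
#' produce byte-identical JSON.
#'
#' @param report a `psmAnalysisReport` from [runAnalysis()].
#' @param dir output directory (created if needed).
#' @return invisibly, the path of the JSON report.
#' @export
writeAnalysisReport <- function(report, dir) {
  stopifnot(inherits(report, "psmAnalysisReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r2 <- function(x) round(x, 2)
  t2 <- report$table2
  for (col in c("mean_a", "sd_a", "mean_b", "sd_b")) t2[[col]] <- r2(t2[[col]])
  t2$p <- round(t2$p, 3)
  t3 <- report$table3
  for (col in c("r", "ci_low", "ci_high")) t3[[col]] <- r2(t3[[col]])
  t3$p <- round(t3$p, 3)
  utils::write.csv(report$table1$continuous,
                   file.path(dir, "table1_continuous.csv"), row.names = FALSE)
  utils::write.csv(report$table1$categorical,
                   file.path(dir, "table1_categorical.csv"), row.names = FALSE)
  utils::write.csv(t2, file.path(dir, "table2.csv"), row.names = FALSE)
  utils::write.csv(t3, file.path(dir, "table3.csv"), row.names = FALSE)
  json <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(json)
}

#' Published reference values for the three result tables
#'
#' The transcribed cell values of the published cohort analysis (group
#' means, SDs and p-values; correlations with confidence intervals;
#' descriptive statistics), bundled as plain JSON. Used by
#' [reproduceTables()] to compare a recomputed analysis against the
#' printed values at their printed precision.
#'
#' @return nested list mirroring the three tables.
#' @export
referenceTables <- function() {
  f <- system.file("extdata", "reference_tables.json", package = "psmEnhance",
                   mustWork = TRUE)
  jsonlite::read_json(f, simplifyVector = TRUE)
}

.printedTol <- function(x) {
  # half a unit in the last printed decimal, from the value's string form
  s <- sub("0+$", "", sub("^-", "", format(x, scientific = FALSE)))
  dec <- if (grepl("\\.", s)) nchar(strsplit(s, "\\.")[[1]][2]) else 0L
  0.5 * 10^(-dec) + 1e-9
}

#' Reproduce the published tables from a cohort datasheet
#'
#' Runs the full analysis on a cohort CSV (or data.frame) and compares
#' every recomputed cell against the bundled printed reference values,
#' each at half a unit in its last printed decimal. Discrepancies are
#' reported cell by cell, never hidden: with the study's own datasheet the
#' comparison should agree within rounding (residual differences traceable
#' to per-cell missing-data n or to the t vs Mann-Whitney choice, both of
#' which the report records); with a simulated cohort the comparison
#' quantifies how far the emergent cells sit from the printed ones.
#'
#' @param cohort CSV path or data.frame.
#' @param aliasMap passed to [loadCohort()].
#' @param reference reference values, default [referenceTables()].
#' @return list with `report` (the `psmAnalysisReport`) and `comparison`
#'   (data.frame: `table`, `cell`, `expected`, `observed`, `difference`,
#'   `tolerance`, `within_rounding`).
#' @export
reproduceTables <- function(cohort, aliasMap = list(),
                            reference = referenceTables()) {
  if (!is.data.frame(cohort) || !"api" %in% names(cohort))
    cohort <- loadCohort(cohort, aliasMap = aliasMap)
  report <- runAnalysis(cohort)

  rows <- list()
  addRow <- function(table, cell, expected, observed) {
    tol <- .printedTol(expected)
    rows[[length(rows) + 1L]] <<- data.frame(
      table = table, cell = cell, expected = expected, observed = observed,
      difference = observed - expected, tolerance = tol,
      within_rounding = is.finite(observed) &&
        abs(observed - expected) <= tol,
      stringsAsFactors = FALSE)
  }

  t1 <- report$table1$continuous
  for (v in names(reference$table1$continuous)) {
    ref <- reference$table1$continuous[[v]]
    obs <- t1[t1$variable == v, ]
    if (nrow(obs)) {
      addRow("table1", paste0(v, ".mean"), ref$mean, obs$mean)
      addRow("table1", paste0(v, ".sd"), ref$sd, obs$sd)
    }
  }
  for (v in names(reference$table1$counts)) {
    ref <- reference$table1$counts[[v]]
    cat1 <- report$table1$categorical
    obs <- cat1[cat1$variable == ref$variable & cat1$level == ref$level, ]
    if (nrow(obs)) addRow("table1", paste0(v, ".count"), ref$count, obs$count)
  }

  t2 <- report$table2
  for (k in seq_len(nrow(reference$table2))) {
    ref <- reference$table2[k, ]
    obs <- t2[t2$grouping == ref$grouping & t2$variable == ref$variable, ]
    if (!nrow(obs)) next
    cell <- paste(ref$grouping, ref$variable, sep = ".")
    addRow("table2", paste0(cell, ".mean_yes"), ref$mean_yes, obs$mean_a)
    addRow("table2", paste0(cell, ".mean_no"), ref$mean_no, obs$mean_b)
    addRow("table2", paste0(cell, ".sd_yes"), ref$sd_yes, obs$sd_a)
    addRow("table2", paste0(cell, ".sd_no"), ref$sd_no, obs$sd_b)
  }

  t3 <- report$table3
  for (k in seq_len(nrow(reference$table3))) {
    ref <- reference$table3[k, ]
    obs <- t3[(t3$var1 == ref$var1 & t3$var2 == ref$var2) |
              (t3$var1 == ref$var2 & t3$var2 == ref$var1), ]
    if (!nrow(obs)) next
    cell <- paste(ref$var1, ref$var2, sep = ".")
    addRow("table3", paste0(cell, ".r"), ref$r, obs$r)
    addRow("table3", paste0(cell, ".ci_low"), ref$ci_low, obs$ci_low)
    addRow("table3", paste0(cell, ".ci_high"), ref$ci_high, obs$ci_high)
  }

  list(report = report, comparison = do.call(rbind, rows))
}
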