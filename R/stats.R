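## Cohort statistics: normality-driven two-group comparison, Pearson
## correlation with Fisher-z intervals, categorical tests and ROC analysis.
## Test machinery is delegated to the standard R implementations
## (shapiro.test, t.test, wilcox.test, chisq.test, fisher.test); this layer
## owns the decision rules and the reporting contract.

# Shapiro-Wilk normality p-value, robust to the implementation's n-range
# (3..5000): larger groups are thinned to an evenly spaced subsample of the
# sorted values (deterministic); constant groups return p = 0 (treated as
# non-normal, with the caller warning about exactness).
.normalityP <- function(x) {
  if (length(unique(x)) < 3L) return(0)
  if (length(x) > 5000L)
    x <- sort(x)[round(seq(1, length(x), length.out = 5000L))]
  stats::shapiro.test(x)$p.value
}

#' Two-group comparison with normality-driven test selection
#'
#' Applies the Shapiro-Wilk test to each group at alpha = 0.05; if both
#' groups are consistent with normality a Welch t test is used, otherwise
#' a Mann-Whitney U test (normal approximation with tie correction and
#' continuity correction). Group means and SDs are always reported, even
#' for nonparametric comparisons. Both candidate p-values are computed so
#' downstream reports can flag comparisons whose significance at 0.05
#' depends on the test choice.
#'
#' @param valuesA,valuesB numeric vectors (missing values dropped, counts
#'   recorded); each group needs >= 3 non-missing values.
#' @param variable,labels optional variable name and group labels carried
#'   into the result.
#' @param alpha normality-decision level (default 0.05).
#' @return one-row data.frame with columns `variable`, `group_a`,
#'   `group_b`, `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`,
#'   `normality_p_a`, `normality_p_b`, `test_used`, `statistic`, `p`,
#'   `p_welch`, `p_mann_whitney`, `decision_flips` and the dropped-value
#'   counts `n_missing_a`, `n_missing_b`.
#' @examples
#' compareGroups(rnorm(30), rnorm(30, 1), variable = "smi",
#'               labels = c("no", "yes"))
#' @export
compareGroups <- function(valuesA, valuesB, variable = NA_character_,
                          labels = c("a", "b"), alpha = 0.05) {
  missA <- sum(!is.finite(valuesA)); missB <- sum(!is.finite(valuesB))
  a <- valuesA[is.finite(valuesA)]; b <- valuesB[is.finite(valuesB)]
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 finite values (got ",
         length(a), " and ", length(b), ")")
  constant <- length(unique(a)) == 1L || length(unique(b)) == 1L
  if (constant)
    warning("constant group: Mann-Whitney used; normal-approximation ",
            "p-value is not exact here")
  pa <- .normalityP(a); pb <- .normalityP(b)

  pWelch <- if (constant) NA_real_ else stats::t.test(a, b)$p.value
  mw <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  useT <- !constant && pa > alpha && pb > alpha
  data.frame(
    variable = variable, group_a = labels[1L], group_b = labels[2L],
    mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
    mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
    n_missing_a = missA, n_missing_b = missB,
    normality_p_a = pa, normality_p_b = pb,
    test_used = if (useT) "welch_t" else "mann_whitney",
    statistic = if (useT) unname(stats::t.test(a, b)$statistic)
                else unname(mw$statistic),
    p = if (useT) pWelch else mw$p.value,
    p_welch = pWelch, p_mann_whitney = mw$p.value,
    decision_flips = !constant &&
      ((pWelch < alpha) != (mw$p.value < alpha)),
    stringsAsFactors = FALSE)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Sample Pearson correlation on complete pairs, with the confidence
#' interval `tanh(atanh(r) +/- z_(1-alpha/2) / sqrt(n - 3))` and the
#' p-value from `t = r sqrt((n-2) / (1-r^2))` on `n - 2` degrees of
#' freedom. A perfectly collinear pair (|r| = 1) is handled by clamping
#' the `atanh` argument to `1 - 1e-12` with a warning.
#'
#' @param x,y numeric vectors; pairs with a missing member are dropped.
#' @param level confidence level (default 0.95).
#' @param pair optional length-2 character vector naming the pair.
#' @return one-row data.frame: `var1`, `var2`, `r`, `ci_low`, `ci_high`,
#'   `p`, `n`.
#' @examples
#' pearsonCI(rnorm(100), rnorm(100))
#' @export
pearsonCI <- function(x, y, level = 0.95, pair = c(NA, NA)) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs (got ", n, ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  r <- stats::cor(x, y)
  rz <- r
  if (abs(rz) >= 1 - 1e-12) {
    warning("|r| = 1: Fisher-z interval degenerate, atanh argument clamped")
    rz <- sign(rz) * (1 - 1e-12)
  }
  z <- atanh(rz)
  half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tstat <- rz * sqrt((n - 2) / (1 - rz^2))
  data.frame(var1 = pair[1L], var2 = pair[2L], r = r,
             ci_low = tanh(z - half), ci_high = tanh(z + half),
             p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n,
             stringsAsFactors = FALSE)
}

#' Categorical association test with expected-count rule
#'
#' Pearson's chi-squared test (without continuity correction) when every
#' expected cell count is at least 5, otherwise Fisher's exact test. For
#' 2 x k tables with small cells no collapsing is applied: the exact test
#' handles the full table (network algorithm).
#'
#' @param tab matrix of non-negative integer counts (typically 2 x k).
#' @return list with `statistic` (chi-squared statistic, NA for exact
#'   test), `p`, `test_used`, `min_expected`.
#' @examples
#' categoricalTest(matrix(c(10, 10, 10, 10), 2))  # chi-squared, p = 1
#' categoricalTest(matrix(c(5, 0, 0, 5), 2))      # Fisher exact
#' @export
categoricalTest <- function(tab) {
  tab <- as.matrix(tab)
  if (any(!is.finite(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("table must contain non-negative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has an all-zero row or column")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p = ct$p.value,
         test_used = "chi_squared", min_expected = min(expected))
  } else {
    ft <- stats::fisher.test(tab)
    list(statistic = NA_real_, p = ft$p.value,
         test_used = "fisher_exact", min_expected = min(expected))
  }
}

#' ROC analysis via the rank (Mann-Whitney) AUC estimator
#'
#' The area under the ROC curve computed with midranks:
#' `AUC = (sum of positive-class ranks - n1 (n1 + 1) / 2) / (n1 n0)`,
#' identical to `U / (n1 n0)` from the Mann-Whitney statistic. With
#' `direction = "lower"` the score is negated before ranking, for markers
#' where LOW values predict the positive class (e.g. low contrast
#' enhancement predicting a high MELD score); the orientation used is
#' recorded in the result.
#'
#' @param scores numeric predictor.
#' @param labels logical (or 0/1) class labels; both classes required.
#' @param direction `"higher"` (default: larger score predicts positive)
#'   or `"lower"`.
#' @return list with `auc`, `direction`, `n_pos`, `n_neg` and a `points`
#'   data.frame of the ROC curve (`threshold`, `fpr`, `tpr` computed on
#'   the oriented score).
#' @examples
#' rocAuc(c(0.1, 0.2, 0.3, 0.4), c(1, 1, 0, 0), direction = "lower")$auc
#' @export
rocAuc <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present in the labels")
  s <- if (direction == "lower") -scores else scores
  rk <- rank(s)  # midranks for ties
  auc <- (sum(rk[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  points <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(s[!labels] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(s[labels] >= t), numeric(1)))
  list(auc = auc, direction = direction, n_pos = nPos, n_neg = nNeg,
       points = points)
}
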