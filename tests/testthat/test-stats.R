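test_that("identical samples compare as exchangeable: U = n^2/2 and p = 1", {
  # right-skewed data so the nonparametric branch is exercised
  x <- c(0.1, 0.2, 0.3, 0.5, 0.9, 1.7, 3.3, 6.5, 13, 26, 52, 104)
  res <- compareGroups(x, x)
  expect_identical(res$test_used, "mann_whitney")
  expect_equal(res$statistic, length(x)^2 / 2)
  expect_equal(res$p, 1.0)
  expect_equal(res$p_mann_whitney, 1.0)
})

test_that("well-separated large samples give vanishing p-values", {
  set.seed(11)
  a <- rnorm(5000); b <- rnorm(5000, mean = 1)
  res <- compareGroups(a, b)
  expect_lt(res$p, 1e-10)
  expect_lt(res$p_welch, 1e-10)
  expect_lt(res$p_mann_whitney, 1e-10)
})

test_that("the reported U statistic equals exhaustive pair counting", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  expect_equal(bruteU(a, b), 6 + 0.5 * 4)   # 25 pairs enumerated by hand
  # heavy-tailed fixtures drive the selector to the Mann-Whitney branch,
  # whose reported statistic must equal the enumerated U
  cases <- list(
    list(a = c(0.1, 0.4, 0.9, 2, 8, 40), b = c(0.2, 0.3, 1, 5, 60, 400)),
    list(a = c(1, 1, 2, 3, 50, 1000), b = c(2, 2, 4, 9, 700)),
    list(a = c(0.01, 0.02, 0.5, 30, 31, 3000), b = c(0.04, 0.6, 20, 5000)))
  for (cs in cases) {
    res <- compareGroups(cs$a, cs$b)
    expect_identical(res$test_used, "mann_whitney")
    expect_equal(res$statistic, bruteU(cs$a, cs$b))
  }
})

test_that("normal-approximation Mann-Whitney p tracks exact enumeration for small groups", {
  set.seed(5)
  for (i in 1:12) {
    na <- sample(4:8, 1); nb <- sample(4:8, 1)
    pool <- sample(1:100, na + nb)   # distinct values: no ties
    a <- pool[1:na]; b <- pool[-(1:na)]
    res <- compareGroups(a, b)
    # the continuity-corrected normal approximation is good to ~0.02-0.03
    # in the mid-p region at these group sizes
    expect_lt(abs(res$p_mann_whitney - exactMannWhitneyP(a, b)), 0.03)
  }
})

test_that("normality decides the test: Welch for Gaussian, Mann-Whitney for skewed data", {
  set.seed(29)
  a <- rnorm(80); b <- rnorm(80, 0.3)
  expect_identical(compareGroups(a, b)$test_used, "welch_t")
  expect_identical(compareGroups(exp(rnorm(80, sd = 1.5)), exp(rnorm(80)))$test_used,
                   "mann_whitney")
  # means and SDs are reported either way
  res <- compareGroups(exp(rnorm(50)), exp(rnorm(50)))
  expect_true(is.finite(res$mean_a) && is.finite(res$sd_b))
})

test_that("degenerate group inputs are handled explicitly", {
  expect_error(compareGroups(c(1, 2), c(1, 2, 3)), "at least 3")
  expect_warning(res <- compareGroups(rep(5, 10), c(1, 2, 3, 7, 9)),
                 "constant group")
  expect_identical(res$test_used, "mann_whitney")
  # missing values are dropped and the counts logged
  res <- compareGroups(c(1, 2, 3, NA, 4), c(5, 6, 7, NaN))
  expect_identical(res$n_missing_a, 1L)
  expect_identical(res$n_missing_b, 1L)
  expect_identical(res$n_a + res$n_b, 7L)
})

test_that("Welch t equals pooled t for equal-variance equal-n groups", {
  set.seed(2)
  a <- rnorm(50); b <- rnorm(50)
  welch <- stats::t.test(a, b)$p.value
  pooled <- stats::t.test(a, b, var.equal = TRUE)$p.value
  expect_equal(welch, pooled, tolerance = 1e-4)
  expect_equal(compareGroups(a, b)$p_welch, welch)
})

test_that("Fisher-z interval matches the closed form and cor.test", {
  set.seed(41)
  x <- rnorm(60); y <- 0.4 * x + rnorm(60)
  res <- pearsonCI(x, y)
  r <- cor(x, y)
  expect_equal(res$r, r)
  expect_equal(c(res$ci_low, res$ci_high),
               tanh(atanh(r) + c(-1, 1) * qnorm(0.975) / sqrt(60 - 3)))
  ct <- cor.test(x, y)
  expect_equal(c(res$ci_low, res$ci_high), as.numeric(ct$conf.int),
               tolerance = 1e-10)
  expect_equal(res$p, ct$p.value)
})

test_that("perfect collinearity is clamped with a warning, constants rejected", {
  x <- 1:10
  expect_warning(res <- pearsonCI(x, 2 * x), "clamp")
  expect_equal(res$r, 1.0)
  expect_true(res$ci_low <= 1 && res$ci_high <= 1)
  expect_error(pearsonCI(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearsonCI(1:3, 1:3), "at least 4")
  # incomplete pairs are dropped and n reported
  res <- pearsonCI(c(1, 2, 3, 4, NA, 6), c(2, 1, 4, 3, 5, NA))
  expect_identical(res$n, 4L)
})

test_that("categorical tests follow the expected-count rule", {
  res <- categoricalTest(matrix(c(10, 10, 10, 10), 2))
  expect_identical(res$test_used, "chi_squared")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  res <- categoricalTest(matrix(c(5, 0, 0, 5), 2))
  expect_identical(res$test_used, "fisher_exact")
  expect_equal(res$p, 2 / 252, tolerance = 1e-10)  # 0.0079 two-sided
  expect_error(categoricalTest(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "all-zero")
  expect_error(categoricalTest(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("Fisher exact p equals hypergeometric enumeration on random 2x2 tables", {
  set.seed(6)
  for (i in 1:15) {
    tab <- matrix(rpois(4, 3), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- categoricalTest(tab)
    if (res$test_used == "fisher_exact")
      expect_equal(res$p, exactFisherP(tab), tolerance = 1e-9)
  }
})

test_that("AUC equals U/(n1 n2) and brute-force pair counting, with orientation", {
  expect_equal(rocAuc(c(0.1, 0.2, 0.3, 0.4), c(1, 1, 0, 0),
                      direction = "lower")$auc, 1.0)
  expect_equal(rocAuc(c(0.1, 0.2, 0.3, 0.4), c(1, 1, 0, 0))$auc, 0.0)
  set.seed(9)
  for (i in 1:10) {
    scores <- round(rnorm(30), 1)   # rounding induces ties
    labels <- runif(30) < 0.4
    if (!any(labels) || all(labels)) next
    auc <- rocAuc(scores, labels)$auc
    # brute force over all (positive, negative) pairs with tie credit 1/2
    expect_equal(auc, bruteU(scores[labels], scores[!labels]) /
                   (sum(labels) * sum(!labels)))
    # identity with the Mann-Whitney U statistic
    u <- suppressWarnings(stats::wilcox.test(scores[labels],
                                             scores[!labels],
                                             exact = FALSE)$statistic[[1]])
    expect_equal(auc, u / (sum(labels) * sum(!labels)))
  }
  expect_error(rocAuc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- rnorm(120)
  labels <- runif(120) < plogis(scores)
  ours <- rocAuc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("random labels give chance-level AUC and ROC points span the unit square", {
  set.seed(27)
  res <- rocAuc(rnorm(4000), runif(4000) < 0.3)
  expect_equal(res$auc, 0.5, tolerance = 0.03)
  expect_equal(res$points$fpr[1], 0)
  expect_equal(res$points$tpr[1], 0)
  expect_equal(res$points$fpr[nrow(res$points)], 1)
  expect_equal(res$points$tpr[nrow(res$points)], 1)
  expect_true(all(diff(res$points$fpr) >= 0))
})
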