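test_that("signal fat fraction follows (SI_in - SI_out) / (2 SI_in)", {
  expect_equal(computeSFF(100, 80), 0.10)
  expect_equal(computeSFF(150, 150), 0.0)   # pure water
  expect_equal(computeSFF(100, 0), 0.5)     # equal water/fat upper bound
  expect_error(computeSFF(0, 10), "in-phase")
  expect_error(computeSFF(-5, 10), "in-phase")
  # SI_out > SI_in is arithmetic nonsense physically: flagged, not altered
  expect_warning(v <- computeSFF(100, 120), "not clipped")
  expect_equal(v, -0.1)
})

test_that("contrast enhancement fraction is (SI_ce - SI_nc) / SI_nc, signal drops allowed", {
  expect_equal(computeCEFR(200, 220), 0.10)
  expect_equal(computeCEFR(200, 200), 0.0)
  expect_equal(computeCEFR(100, 90), -0.10)
  # non-enhancement maps to a rejection, never a silent NaN
  expect_error(computeCEFR(0, 100), "non-contrast")
  expect_error(computeCEFR(-3, 100), "non-contrast")
})

test_that("sFF and CEFR are invariant to global signal scaling", {
  set.seed(31)
  for (i in 1:25) {
    si_in <- runif(1, 50, 500)
    si_out <- runif(1, 0, si_in)
    k <- runif(1, 0.1, 40)
    expect_equal(computeSFF(k * si_in, k * si_out), computeSFF(si_in, si_out))
    nc <- runif(1, 50, 400); ce <- runif(1, 20, 600)
    expect_equal(computeCEFR(k * nc, k * ce), computeCEFR(nc, ce))
  }
})

test_that("skeletal muscle index averages bilateral areas and normalises by height squared", {
  expect_equal(computeSMI(8.0, 9.0, 1.8), 8.5 / 3.24)
  expect_equal(computeSMI(7.3, 7.3, 1.0), 7.3)      # unit-height identity
  expect_equal(computeSMI(16.2, 16.2, 1.75), 16.2 / 3.0625)  # ~5.29 cm2/m2
  expect_error(computeSMI(0, 5, 1.7), "areas")
  expect_error(computeSMI(5, 5, 0), "height")
})

test_that("MELD applies the standard clamps, caps, rounding and bounds", {
  expect_identical(computeMELD(1.0, 1.0, 1.0), 6L)   # all logs zero, floor
  expect_identical(computeMELD(0.93, 1.64, 1.25), 11L)
  # creatinine cap: dialysis equals an uncapped 4.0 input
  expect_identical(computeMELD(4.0, 4.0, 2.0, dialysis = TRUE),
                   computeMELD(4.0, 4.0, 2.0, dialysis = FALSE))
  expect_identical(computeMELD(9.9, 4.0, 2.0), computeMELD(4.0, 4.0, 2.0))
  expect_identical(computeMELD(0.4, 4.0, 2.0, dialysis = TRUE),
                   computeMELD(4.0, 4.0, 2.0))
  expect_identical(computeMELD(30, 60, 9), 40L)      # upper bound
  expect_error(computeMELD(0, 1, 1), "labs")
})

test_that("MELD is monotone nondecreasing in each lab above its clamp", {
  base <- c(cr = 1.4, tb = 2.0, inr = 1.6)
  grid <- seq(1.0, 4.0, by = 0.1)
  for (lab in names(base)) {
    vals <- vapply(grid, function(g) {
      args <- as.list(base); args[[lab]] <- g
      computeMELD(args$cr, args$tb, args$inr)
    }, integer(1))
    expect_true(all(diff(vals) >= 0), info = lab)
  }
})

test_that("Lin's concordance coefficient matches its population-moment definition", {
  expect_equal(linCCC(1:10, 1:10), 1.0)
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(linCCC(x, -x), -1.0)
  # frozen value from direct evaluation of the formula
  expect_equal(linCCC(c(1, 2, 3, 4), c(1.1, 2.1, 2.9, 4.2)), 0.99311694,
               tolerance = 1e-7)
  expect_error(linCCC(rep(2, 5), rep(2, 5)), "undefined")
  expect_error(linCCC(1:4, 1:5), "equal length")
})

test_that("concordance never exceeds Pearson correlation in magnitude", {
  set.seed(19)
  for (i in 1:30) {
    x <- rnorm(20); y <- 0.5 * x + rnorm(20, sd = runif(1, 0.2, 2)) +
      runif(1, -1, 1)
    ccc <- linCCC(x, y)
    # brute-force re-evaluation, independent of the implementation
    mx <- mean(x); my <- mean(y)
    brute <- 2 * mean((x - mx) * (y - my)) /
      (mean((x - mx)^2) + mean((y - my)^2) + (mx - my)^2)
    expect_equal(ccc, brute)
    expect_lte(abs(ccc), abs(cor(x, y)) + 1e-12)
  }
  # equality holds iff means and variances agree
  x <- rnorm(50); y <- 2 + x[sample(50)]
  expect_lt(abs(linCCC(x, y)), abs(cor(x, y)))
})

test_that("ROI statistics compute per-structure means and areas", {
  imgs <- uniformImageSet(100, dim = c(10, 10), spacing = c(2, 2))
  masks <- maskWithAllLabels(c(10, 10))
  panel <- roiStats(imgs, masks)
  st <- roiTable(panel)
  expect_equal(nrow(st), 3L)
  expect_true(all(st$mean_ip == 100) && all(st$mean_del == 100))
  expect_equal(st$area_cm2, rep(3 * 4 / 100, 3))  # 3 voxels x 4 mm2

  # arithmetic mean over an explicit 10-voxel region
  imgs2 <- uniformImageSet(0, dim = c(10, 10))
  imgs2@images$ip[1, 1:10] <- 0:9
  m <- matrix(0L, 10, 10); m[1, 1:10] <- 1L; m[2, 1] <- 2L; m[3, 1] <- 3L
  masks2 <- new("MaskSet", labels = m,
                labelMap = c(psm_left = 1L, psm_right = 2L, aorta = 3L))
  st2 <- roiTable(roiStats(imgs2, masks2))
  expect_equal(st2$mean_ip[st2$structure == "psm_left"], 4.5)
})

test_that("ROI statistics reject missing labels and shape mismatches", {
  imgs <- uniformImageSet(100, dim = c(10, 10))
  m <- matrix(0L, 10, 10); m[1, 1] <- 1L; m[2, 1] <- 2L
  masks <- new("MaskSet", labels = m,
               labelMap = c(psm_left = 1L, psm_right = 2L))
  expect_error(roiStats(imgs, masks), "aorta")
  expect_error(roiStats(uniformImageSet(1, dim = c(8, 8)),
                        maskWithAllLabels(c(10, 10))), "shape mismatch")
})

test_that("bilateral averaging order matches the pooled-signal convention", {
  # asymmetric muscles: pooled-then-formula differs from per-muscle average
  imgs <- uniformImageSet(0, dim = c(6, 6))
  m <- matrix(0L, 6, 6); m[1, 1:2] <- 1L; m[2, 1:2] <- 2L; m[3, 1] <- 3L
  masks <- new("MaskSet", labels = m,
               labelMap = c(psm_left = 1L, psm_right = 2L, aorta = 3L))
  for (p in phaseNames(imgs)) imgs@images[[p]][] <- 1
  imgs@images$ip[m == 1L] <- 100; imgs@images$oop[m == 1L] <- 80
  imgs@images$ip[m == 2L] <- 200; imgs@images$oop[m == 2L] <- 40
  imgs@images$nc[m == 1L] <- 100; imgs@images$art[m == 1L] <- 120
  imgs@images$nc[m == 2L] <- 200; imgs@images$art[m == 2L] <- 210
  pooled <- measureBiomarkers(imgs, masks, 1.7)
  per <- measureBiomarkers(imgs, masks, 1.7, averaging = "per_muscle")
  expect_equal(pooled@sff, computeSFF(150, 60))
  expect_equal(per@sff, mean(c(computeSFF(100, 80), computeSFF(200, 40))))
  expect_equal(pooled@cefrArt, computeCEFR(150, 165))
  expect_equal(per@cefrArt, mean(c(0.2, 0.05)))
  expect_false(isTRUE(all.equal(pooled@sff, per@sff)))
})
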