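test_that("Gumbel-min distribution functions are mutually consistent", {
  expect_equal(pgumbelMin(0, 0, 1), 1 - exp(-1))
  expect_equal(qgumbelMin(pgumbelMin(1.3, 2, 0.5), 2, 0.5), 1.3)
  # density integrates CDF: numeric derivative check
  eps <- 1e-6
  expect_equal((pgumbelMin(0.7 + eps) - pgumbelMin(0.7 - eps)) / (2 * eps),
               dgumbelMin(0.7), tolerance = 1e-6)
  set.seed(8)
  x <- rgumbelMin(2e5, 3, 1.5)
  expect_equal(mean(x), 3 - 0.5772156649 * 1.5, tolerance = 0.02)
})

test_that("maximum likelihood recovers Gumbel-min parameters", {
  set.seed(2)
  x <- rgumbelMin(10000, 10, 2)
  fit <- fitEVD(x)
  expect_gt(fit@location, 9.9); expect_lt(fit@location, 10.1)
  expect_gt(fit@scale, 1.94); expect_lt(fit@scale, 2.06)
  # bias shrinks with sample size
  errs <- vapply(c(100, 1000, 10000), function(n) {
    e <- vapply(1:20, function(s) {
      set.seed(1000 + 17 * s + n)
      f <- fitEVD(rgumbelMin(n, 10, 2))
      abs(f@location - 10) + abs(f@scale - 2)
    }, 0)
    mean(e)
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("the fit is location equivariant and rejects degenerate input", {
  set.seed(4)
  x <- rgumbelMin(200, 0, 1)
  f0 <- fitEVD(x)
  f5 <- fitEVD(x + 5)
  expect_equal(f5@location, f0@location + 5, tolerance = 1e-4)
  expect_equal(f5@scale, f0@scale, tolerance = 1e-4)
  expect_error(fitEVD(rep(1, 20)), "degenerate")
  expect_error(fitEVD(rnorm(7)), "insufficient")
  # maximum-type convention mirrors the minimum-type fit
  fx <- fitEVD(x, type = "max")
  fm <- fitEVD(-x)
  expect_equal(fx@location, -fm@location, tolerance = 1e-6)
  expect_equal(fx@scale, fm@scale, tolerance = 1e-6)
})

test_that("location-parameter thresholding flags the low-complexity tail", {
  fit <- new("EVDFit", patientId = "p", layer = 1L, location = 5,
             scale = 1, n = 100L)
  expect_false(any(thresholdPOI(c(5, 5.1, 9), fit)))
  expect_true(thresholdPOI(5 - 1e-9, fit))
  # flagged fraction converges to 1 - exp(-1) under the fitted model
  set.seed(12)
  x <- rgumbelMin(10000, 4, 0.8)
  f <- fitEVD(x)
  expect_lt(abs(mean(thresholdPOI(x, f)) - (1 - exp(-1))), 0.02)
})

test_that("group splits partition patients 7/7/6 with balanced classes", {
  set.seed(31)
  pats <- rep(sprintf("P%02d", 1:20), each = 90)
  inEZ <- as.logical(rbinom(length(pats), 1, 0.4))
  sp <- makeGroupSplits(pats, inEZ, seed = 3)
  sizes <- sort(as.integer(table(factor(sp@fold, 1:3))), decreasing = TRUE)
  expect_identical(sizes, c(7L, 7L, 6L))
  expect_setequal(names(sp@fold), unique(pats))
  fracs <- sp@classCounts[, "inside"] / rowSums(sp@classCounts)
  expect_true(all(abs(fracs - mean(inEZ)) < 0.1))
  # determinism
  expect_identical(makeGroupSplits(pats, inEZ, seed = 3)@fold, sp@fold)
  expect_error(makeGroupSplits(pats[1:90], inEZ[1:90]), "at least 3")
  expect_error(makeGroupSplits(pats, rep(FALSE, length(pats))), "both classes")
})

test_that("the grouped SVM separates constructed classes out of fold", {
  set.seed(41)
  nPat <- 9; perPat <- 30
  pats <- rep(sprintf("P%02d", 1:nPat), each = perPat)
  inEZ <- as.logical(rbinom(length(pats), 1, 0.35))
  feats <- matrix(rnorm(length(pats) * 13), ncol = 13)
  feats[inEZ, c(3, 8, 12)] <- feats[inEZ, c(3, 8, 12)] - 6 # separable shift
  sp <- makeGroupSplits(pats, inEZ, seed = 5)
  pred <- svmPOI(feats, inEZ, pats, sp)
  expect_identical(pred, inEZ) # 100% held-out accuracy by construction
  expect_identical(svmPOI(feats, inEZ, pats, sp), pred) # deterministic
})

test_that("the grouped SVM is at chance under permuted labels", {
  set.seed(42)
  nPat <- 6; perPat <- 100 # 600 contacts
  pats <- rep(sprintf("P%02d", 1:nPat), each = perPat)
  inEZ <- as.logical(rbinom(length(pats), 1, 0.4))
  feats <- matrix(rnorm(length(pats) * 13), ncol = 13)
  sp <- makeGroupSplits(pats, inEZ, seed = 7)
  pred <- svmPOI(feats, inEZ, pats, sp)
  acc <- mean(pred == inEZ)
  prior <- max(mean(inEZ), 1 - mean(inEZ))
  expect_lt(abs(acc - prior), 0.05 + 0.03) # chance-level within sampling noise
})

test_that("POI summaries match a brute-force recomputation", {
  geo <- data.frame(distance_mm = c(0, 0, 2, 7, 12, 30),
                    in_ez = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  s <- summarizePOI(rep(TRUE, 6), geo)
  expect_identical(s$n_poi, 6L)
  expect_equal(s$median_mm, median(geo$distance_mm))
  expect_equal(s$pct_in_ez, 50)
  expect_equal(s$pct_within_10mm, 100 * 4 / 6)
  s2 <- summarizePOI(c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE), geo)
  expect_equal(s2$median_mm, 7)
  expect_equal(s2$iqr_mm, quantile(c(2, 7, 12), 0.75)[[1]] -
                 quantile(c(2, 7, 12), 0.25)[[1]])
  allZero <- data.frame(distance_mm = c(0, 0), in_ez = c(TRUE, TRUE))
  s3 <- summarizePOI(c(TRUE, TRUE), allZero)
  expect_equal(s3$median_mm, 0)
  expect_equal(s3$pct_in_ez, 100)
  expect_error(summarizePOI(c(FALSE, FALSE), allZero), "no contacts")
})
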