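test_that("the signed-rank p-value matches exhaustive sign permutation", {
  set.seed(21)
  a <- rnorm(10, 0.4)
  b <- rnorm(10)
  expect_equal(wilcoxonSignedRank(a, b), signPermWilcoxon(a, b),
               tolerance = 1e-12)
  # and for a second draw with the opposite direction
  a2 <- rnorm(12, -0.6)
  b2 <- rnorm(12)
  expect_equal(wilcoxonSignedRank(a2, b2), signPermWilcoxon(a2, b2),
               tolerance = 1e-12)
})

test_that("all-same-sign differences give the two-sided sign-extreme p", {
  n <- 20
  b <- seq_len(n)
  a <- b + 0.1 * seq_len(n) # all positive, distinct magnitudes (no ties)
  expect_equal(wilcoxonSignedRank(a, b), 2 * 2^-n, tolerance = 1e-12)
  expect_error(wilcoxonSignedRank(b, b), "degenerate")
  expect_error(wilcoxonSignedRank(c(1, 2, 3, 4), c(0, 1, 2, 3)), "at least 5")
})

test_that("paired Cohen's d and its noncentral-t interval behave", {
  set.seed(7)
  b <- rnorm(15)
  a <- b + rnorm(15, mean = 1, sd = 0.5)
  res <- cohensDPaired(a, b)
  expect_equal(res$d, mean(a - b) / sd(a - b))
  expect_lt(res$ci[1], res$d)
  expect_gt(res$ci[2], res$d)
  expect_identical(res$ci_method, "noncentral-t")
  # a strong effect excludes zero; swapping arguments flips the sign
  expect_gt(res$ci[1], 0)
  flip <- cohensDPaired(b, a)
  expect_equal(flip$d, -res$d)
  expect_equal(flip$ci, -rev(res$ci), tolerance = 1e-6)
  # interval widens as n shrinks
  res5 <- cohensDPaired(a[1:5], b[1:5])
  expect_gt(diff(res5$ci), 0)
  expect_error(cohensDPaired(c(1, 2), c(0, 0)), "at least 3")
  expect_error(cohensDPaired(c(1, 2, 3), c(0, 1, 2)), "degenerate")
})

test_that("the Bonferroni correction multiplies by 13 and caps at 1", {
  p <- c(0.001, 0.01, 0.05, 0.2, 1)
  expect_equal(bonferroni(p), pmin(13 * p, 1))
  expect_equal(bonferroni(0), 0)
  expect_equal(bonferroni(1), 1)
  # monotone
  ps <- sort(runif(50))
  expect_true(all(diff(bonferroni(ps)) >= 0))
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the method comparison pairs per-patient medians over 13 layers", {
  set.seed(3)
  pats <- sprintf("P%02d", 1:8)
  svmD <- setNames(lapply(pats, function(p) runif(5, 0, 4)), pats)
  layD <- lapply(1:13, function(l)
    setNames(lapply(pats, function(p) runif(5, 6, 20)), pats))
  out <- compareMethods(svmD, layD)
  expect_identical(nrow(out), 13L)
  expect_identical(out$layer, 1:13)
  expect_true(all(out$n_pairs == 8))
  expect_true(all(out$median_svm_mm < out$median_layer_mm))
  # every layer's medians dominate => sign-extreme exact p = 2 * 2^-8
  expect_true(all(abs(out$p_value - 2 * 2^-8) < 1e-12))
  # patients missing from one method are dropped from the pairing
  layD[[1]][["P01"]] <- NULL
  out2 <- compareMethods(svmD, layD)
  expect_identical(out2$n_pairs[1], 7L)
  expect_error(compareMethods(svmD, layD[1:5]), "13")
  # identical methods: every paired difference is zero, so the p is NA
  same <- compareMethods(svmD, lapply(1:13, function(l) svmD))
  expect_true(all(is.na(same$p_value)))
  expect_true(all(same$median_svm_mm == same$median_layer_mm))
})
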