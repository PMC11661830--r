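## Statistical comparisons: paired Wilcoxon signed-rank tests on per-patient
## summaries, paired Cohen's d with noncentral-t confidence interval, and
## Bonferroni correction over the 13 layers.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired values: exact for up to 25 nonzero
#' pairs, normal approximation with continuity correction above. Pairs with
#' zero difference are dropped (the standard convention).
#'
#' @param a,b paired numeric vectors of equal length.
#' @return the two-sided p-value.
#' @export
wilcoxonSignedRank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  nz <- sum(d != 0)
  if (nz == 0) stop("degenerate test: all paired differences are zero")
  if (nz < 5) stop("at least 5 pairs with nonzero difference are required")
  res <- suppressWarnings(
    wilcox.test(a, b, paired = TRUE, exact = nz <= 25, correct = TRUE))
  unname(res$p.value)
}

#' Paired Cohen's d with confidence interval
#'
#' d = mean(differences) / sd(differences). The 95% confidence interval is
#' derived from the noncentral-t distribution of t = d * sqrt(n): the
#' noncentrality bounds are found such that the observed t is the 97.5th and
#' 2.5th percentile, then divided by sqrt(n). Emitted as (lower, upper).
#'
#' @param a,b paired numeric vectors (at least 3 pairs).
#' @param conf confidence level (default 0.95).
#' @return list with `d`, `ci` (length-2: lower, upper), `n`,
#'   `ci_method = "noncentral-t"`.
#' @export
cohensDPaired <- function(a, b, conf = 0.95) {
  stopifnot(length(a) == length(b))
  d <- a - b
  n <- length(d)
  if (n < 3) stop("at least 3 pairs are required")
  s <- sd(d)
  if (s == 0) stop("degenerate: zero variance of the differences")
  dEff <- mean(d) / s
  tObs <- dEff * sqrt(n)
  alpha <- (1 - conf) / 2
  ncpBound <- function(p) {
    f <- function(ncp) # pt warns about pnt precision at extreme ncp; benign here
      suppressWarnings(pt(tObs, df = n - 1, ncp = ncp)) - p
    lo <- tObs - 10 - 10 * abs(tObs); hi <- tObs + 10 + 10 * abs(tObs)
    uniroot(f, c(lo, hi), extendInt = "yes")$root
  }
  ci <- c(ncpBound(1 - alpha), ncpBound(alpha)) / sqrt(n)
  list(d = dEff, ci = ci, n = n, ci_method = "noncentral-t")
}

#' Bonferroni correction over the 13 network layers
#'
#' Adjusted p = min(13 * p, 1) for each layer.
#'
#' @param p numeric vector of 13 raw p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bonferroni <- function(p) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  pmin(13 * p, 1)
}

#' Per-layer SOZ versus non-SOZ comparison of activation energy
#'
#' For each convolutional layer, pairs each patient's mean UAE over
#' inside-SOZ contacts with the mean over outside-SOZ contacts (only patients
#' with at least one contact in each group contribute a pair), tests the
#' paired difference with the Wilcoxon signed-rank test, computes paired
#' Cohen's d, and Bonferroni-adjusts the 13 p-values.
#'
#' @param x a [ContactExperiment-class].
#' @return data.frame with one row per layer: `layer`, `n_pairs`,
#'   `mean_inside`, `mean_outside`, `p_raw`, `p_bonferroni`, `cohens_d`,
#'   `d_ci_lower`, `d_ci_upper`.
#' @export
layerComparisons <- function(x) {
  stopifnot(is(x, "ContactExperiment"))
  feats <- uaeMatrix(x)
  info <- contactInfo(x)
  pats <- unique(info$patient)
  usable <- pats[vapply(pats, function(p) {
    s <- info$soz[info$patient == p]
    any(s) && any(!s)
  }, TRUE)]
  rows <- lapply(1:13, function(l) {
    inside <- vapply(usable, function(p) {
      sel <- info$patient == p & info$soz
      mean(feats[l, sel])
    }, 0)
    outside <- vapply(usable, function(p) {
      sel <- info$patient == p & !info$soz
      mean(feats[l, sel])
    }, 0)
    p <- wilcoxonSignedRank(inside, outside)
    dd <- cohensDPaired(inside, outside)
    data.frame(layer = l, n_pairs = length(usable),
               mean_inside = mean(inside), mean_outside = mean(outside),
               p_raw = p, cohens_d = dd$d,
               d_ci_lower = dd$ci[1], d_ci_upper = dd$ci[2])
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni(out$p_raw)
  out[, c("layer", "n_pairs", "mean_inside", "mean_outside", "p_raw",
          "p_bonferroni", "cohens_d", "d_ci_lower", "d_ci_upper")]
}

#' Compare localization error across POI methods
#'
#' Pairs the per-patient median POI distances of the SVM method with those of
#' each per-layer threshold method and tests each pairing with the Wilcoxon
#' signed-rank test. The pairing unit is the patient; only patients with at
#' least one POI under both methods contribute. When the test is undefined —
#' fewer than five informative pairs, e.g. because the two methods' medians
#' coincide for every patient — the p-value is `NA`.
#'
#' @param svmDistances named list: patient -> vector of POI distances (mm)
#'   under the SVM.
#' @param layerDistances list of 13 elements (one per layer), each a named
#'   list patient -> vector of POI distances under that layer's threshold.
#' @return data.frame with `layer`, `n_pairs`, `median_svm_mm`,
#'   `median_layer_mm`, `p_value` (`NA` when undefined).
#' @export
compareMethods <- function(svmDistances, layerDistances) {
  stopifnot(length(layerDistances) == 13L)
  svmMed <- vapply(svmDistances, median, 0)
  rows <- lapply(1:13, function(l) {
    layMed <- vapply(layerDistances[[l]], median, 0)
    common <- intersect(names(svmMed), names(layMed))
    p <- tryCatch(wilcoxonSignedRank(svmMed[common], layMed[common]),
                  error = function(e) NA_real_)
    data.frame(layer = l, n_pairs = length(common),
               median_svm_mm = median(svmMed[common]),
               median_layer_mm = median(layMed[common]),
               p_value = p)
  })
  do.call(rbind, rows)
}
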