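## Point-of-interest identification: per-patient, per-layer extreme-value
## thresholds on the activation-energy values, and an all-layer linear SVM
## with patient-distinct three-fold cross-validation.

#' Minimum-type Gumbel distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the minimum-type (left-skewed) Gumbel distribution with density
#' p(x) = (1/scale) exp(z) exp(-exp(z)), z = (x - location)/scale. Its CDF is
#' F(x) = 1 - exp(-exp(z)); at x = location, F = 1 - exp(-1) ~ 0.632.
#'
#' @param x,q,p,n usual distribution-function arguments.
#' @param location,scale parameters; `scale > 0`.
#' @name gumbelMin
#' @export
dgumbelMin <- function(x, location = 0, scale = 1) {
  z <- (x - location) / scale
  exp(z - exp(z)) / scale
}

#' @rdname gumbelMin
#' @export
pgumbelMin <- function(q, location = 0, scale = 1) {
  1 - exp(-exp((q - location) / scale))
}

#' @rdname gumbelMin
#' @export
qgumbelMin <- function(p, location = 0, scale = 1) {
  location + scale * log(-log(1 - p))
}

#' @rdname gumbelMin
#' @export
rgumbelMin <- function(n, location = 0, scale = 1) {
  location + scale * log(-log(runif(n)))
}

#' Fit the extreme-value distribution to one patient-layer's UAE values
#'
#' Maximum-likelihood fit of the minimum-type Gumbel density
#' by quasi-Newton optimization of (location,
#' log scale), started at the method-of-moments estimates. The `"max"`
#' convention fits the maximum-type family instead (negate, fit, negate
#' back); the minimum type is the default since the low-complexity tail sits
#' on the left.
#'
#' @param values numeric vector of at least 8 finite values, not all equal.
#' @param patientId,layer identifiers carried into the result.
#' @param type `"min"` (default) or `"max"`.
#' @return an [EVDFit-class].
#' @export
fitEVD <- function(values, patientId = "unknown", layer = 1L,
                   type = c("min", "max")) {
  type <- match.arg(type)
  values <- values[is.finite(values)]
  if (length(values) < 8L)
    stop("insufficient data: at least 8 finite values are required")
  if (max(values) == min(values))
    stop("degenerate fit: all values are equal")
  x <- if (type == "max") -values else values
  gamma <- 0.5772156649015329
  s0 <- sd(x) * sqrt(6) / pi
  m0 <- mean(x) + gamma * s0 # Gumbel-min mean is location - gamma * scale
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    z <- (x - mu) / sigma
    length(x) * log(sigma) - sum(z) + sum(exp(z))
  }
  fit <- optim(c(m0, log(s0)), nll, method = "BFGS")
  mu <- fit$par[1]; sigma <- exp(fit$par[2])
  if (type == "max") mu <- -mu
  new("EVDFit", patientId = as.character(patientId), layer = as.integer(layer),
      location = mu, scale = sigma, n = length(x))
}

#' Flag points of interest below the extreme-value location parameter
#'
#' A contact is a point of interest when its UAE value is strictly lower
#' than the fitted distribution's location parameter — the low-complexity
#' tail. Under the fitted minimum-type model the flagged fraction converges
#' to 1 - exp(-1) ~ 0.632.
#'
#' @param values numeric UAE values.
#' @param fit an [EVDFit-class].
#' @return logical vector of flags.
#' @export
thresholdPOI <- function(values, fit) {
  stopifnot(is(fit, "EVDFit"))
  values < fit@location
}

#' Patient-distinct three-fold split with balanced class fractions
#'
#' Seeded greedy search over random patient partitions: among many balanced
#' random assignments (fold sizes differing by at most one patient), keep the
#' one minimizing the spread of fold-level inside-EZ contact fractions.
#'
#' @param patients per-contact patient identifiers.
#' @param inEZ per-contact logical inside-EZ labels.
#' @param seed integer seed.
#' @param nRestarts number of random partitions searched.
#' @return a [GroupSplit-class].
#' @export
makeGroupSplits <- function(patients, inEZ, seed = 1L, nRestarts = 200L) {
  stopifnot(length(patients) == length(inEZ))
  ids <- unique(patients)
  if (length(ids) < 3L) stop("at least 3 patients are required")
  if (!any(inEZ) || all(inEZ))
    stop("both classes (inside and outside EZ) must be present")
  nIn <- vapply(ids, function(p) sum(inEZ[patients == p]), 0)
  nTot <- vapply(ids, function(p) sum(patients == p), 0)
  n <- length(ids)
  sizes <- rep(n %/% 3L, 3L) + (seq_len(3L) <= n %% 3L)
  .withSeed(seed, {
    best <- NULL; bestSpread <- Inf
    for (r in seq_len(nRestarts)) {
      perm <- sample(n)
      fold <- integer(n)
      fold[perm] <- rep.int(1:3, times = sizes)
      frac <- vapply(1:3, function(g)
        sum(nIn[fold == g]) / sum(nTot[fold == g]), 0)
      spread <- max(frac) - min(frac)
      if (spread < bestSpread) { bestSpread <- spread; best <- fold }
    }
    counts <- t(vapply(1:3, function(g) c(
      inside = sum(nIn[best == g]),
      outside = sum(nTot[best == g]) - sum(nIn[best == g])), c(0, 0)))
    rownames(counts) <- paste0("G", 1:3)
    new("GroupSplit", fold = structure(as.integer(best), names = ids),
        classCounts = counts)
  })
}

#' Linear SVM point-of-interest classification with grouped cross-validation
#'
#' For each of the three patient folds, trains a linear support vector
#' machine (cost 1, no class weighting) on the contacts of the other two
#' folds — features z-scored by the training folds' mean and standard
#' deviation — and predicts the held-out fold. Every contact receives exactly
#' one out-of-fold prediction; a contact is a point of interest when
#' predicted inside-EZ.
#'
#' @param features contacts x 13 numeric matrix of per-layer UAE values.
#' @param inEZ per-contact logical ground-truth labels.
#' @param patients per-contact patient identifiers.
#' @param split a [GroupSplit-class] over these patients.
#' @return logical vector of out-of-fold POI predictions.
#' @export
svmPOI <- function(features, inEZ, patients, split) {
  stopifnot(is(split, "GroupSplit"), nrow(features) == length(inEZ),
            length(inEZ) == length(patients))
  foldOf <- split@fold[as.character(patients)]
  if (any(is.na(foldOf))) stop("split does not cover all patients")
  pred <- logical(length(inEZ))
  for (g in 1:3) {
    testIdx <- which(foldOf == g)
    trainIdx <- which(foldOf != g)
    yTrain <- inEZ[trainIdx]
    if (length(unique(yTrain)) < 2L)
      stop("training folds must contain both classes")
    mu <- colMeans(features[trainIdx, , drop = FALSE])
    sdv <- apply(features[trainIdx, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    zTrain <- sweep(sweep(features[trainIdx, , drop = FALSE], 2, mu), 2, sdv, "/")
    zTest <- sweep(sweep(features[testIdx, , drop = FALSE], 2, mu), 2, sdv, "/")
    model <- e1071::svm(zTrain, factor(yTrain, c(FALSE, TRUE)),
                        kernel = "linear", cost = 1, scale = FALSE)
    pred[testIdx] <- as.logical(as.character(predict(model, zTest)))
  }
  pred
}

#' Summarize point-of-interest proximity to the EZ
#'
#' Median and inter-quartile range of the flagged contacts' distance to the
#' resection margin, the percentage of flagged contacts inside the EZ, and
#' the percentage within a 10 mm radius.
#'
#' @param flags logical POI flags.
#' @param geometry data.frame with per-contact `distance_mm` and `in_ez`
#'   (rows aligned with `flags`).
#' @return list with `n_poi`, `median_mm`, `q25_mm`, `q75_mm`, `iqr_mm`,
#'   `pct_in_ez`, `pct_within_10mm`.
#' @export
summarizePOI <- function(flags, geometry) {
  stopifnot(length(flags) == nrow(geometry))
  if (!any(flags)) stop("no contacts flagged: empty summary")
  d <- geometry$distance_mm[flags]
  q <- unname(quantile(d, c(0.25, 0.5, 0.75)))
  list(
    n_poi = sum(flags),
    median_mm = q[2],
    q25_mm = q[1],
    q75_mm = q[3],
    iqr_mm = q[3] - q[1],
    pct_in_ez = 100 * mean(geometry$in_ez[flags]),
    pct_within_10mm = 100 * mean(d <= 10)
  )
}
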