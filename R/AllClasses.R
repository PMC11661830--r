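#' Class definitions
#'
#' @name iEEGComplexity-classes
#' @keywords internal
NULL

#' Multi-channel interictal iEEG recording
#'
#' Holds one patient's multi-channel iEEG segment: a channels-by-samples
#' signal matrix in microvolts, the sampling rate, channel labels, and an
#' optional list of channel labels to exclude (continuous-artifact channels
#' identified by clinical review; exclusion is never automated here).
#'
#' @slot patientId single character identifier.
#' @slot labels character vector of channel labels (one per row of `signals`).
#' @slot signals numeric matrix, channels x samples, in microvolts.
#' @slot samplingRate sampling rate in Hz.
#' @slot excludedChannels labels of channels to drop before analysis; must be
#'   a subset of `labels` (unknown labels are tolerated with a warning at
#'   [selectChannels()] time).
#'
#' @seealso [selectChannels()], [bandpassFilter()], [epochSignal()]
#' @export
setClass("IEEGRecording",
  representation(
    patientId = "character",
    labels = "character",
    signals = "matrix",
    samplingRate = "numeric",
    excludedChannels = "character"
  ),
  prototype(excludedChannels = character())
)

setValidity("IEEGRecording", function(object) {
  msg <- character()
  if (length(object@patientId) != 1L) msg <- c(msg, "patientId must be length 1")
  if (nrow(object@signals) != length(object@labels))
    msg <- c(msg, "signals must have one row per channel label")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "channel labels must be unique")
  if (length(msg)) msg else TRUE
})

#' Morlet time-frequency grid parameters
#'
#' The fixed analysis grid: 224 linearly spaced frequencies at 0.30 Hz
#' resolution starting at 1 Hz (1.0--67.9 Hz) and 224 time points at 8.9 ms
#' resolution, centered within each 3 s epoch. The wavelet width is set in
#' cycles; the Gaussian envelope's standard deviation at frequency f is
#' sigma = nCycles / (2 * pi * f).
#'
#' @slot nCycles wavelet width in cycles (default 7).
#' @slot freqs strictly increasing frequency grid in Hz, length 224, within
#'   \[1, 70\] Hz.
#' @slot timeStep time grid step in seconds (8.9 ms).
#'
#' @seealso [morletParams()], [morletSpectrogram()]
#' @export
setClass("MorletParams",
  representation(nCycles = "numeric", freqs = "numeric", timeStep = "numeric")
)

setValidity("MorletParams", function(object) {
  msg <- character()
  if (length(object@nCycles) != 1L || object@nCycles <= 0)
    msg <- c(msg, "nCycles must be a single positive number")
  if (length(object@freqs) != 224L)
    msg <- c(msg, "frequency grid must have exactly 224 bins")
  if (any(diff(object@freqs) <= 0))
    msg <- c(msg, "frequency grid must be strictly increasing")
  if (min(object@freqs) < 1 || max(object@freqs) > 70)
    msg <- c(msg, "frequency grid must lie within [1, 70] Hz")
  if (length(object@timeStep) != 1L || object@timeStep <= 0)
    msg <- c(msg, "timeStep must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Time-frequency image of one 3 s epoch
#'
#' A 224 x 224 Morlet amplitude grid (rows = frequency ascending, columns =
#' time ascending) together with its jet-colormap RGB encoding (224 x 224 x 3,
#' values in \[0, 1\]) and the axes in Hz and seconds.
#'
#' @slot amplitude non-negative 224 x 224 amplitude grid |S_w(f, t)|.
#' @slot rgb 224 x 224 x 3 array in \[0, 1\]: the unit-normalized amplitude
#'   grid passed through the piecewise-linear jet map.
#' @slot freqs frequency axis (Hz), one value per row.
#' @slot times time axis (s, relative to epoch start), one value per column.
#'
#' @seealso [makeTFImage()], [jetRGB()]
#' @export
setClass("TFImage",
  representation(
    amplitude = "matrix",
    rgb = "array",
    freqs = "numeric",
    times = "numeric"
  )
)

setValidity("TFImage", function(object) {
  msg <- character()
  d <- dim(object@amplitude)
  if (!identical(d, c(224L, 224L)))
    msg <- c(msg, "amplitude grid must be 224 x 224")
  if (any(object@amplitude < 0)) msg <- c(msg, "amplitude must be non-negative")
  if (!identical(dim(object@rgb), c(224L, 224L, 3L)))
    msg <- c(msg, "rgb must be 224 x 224 x 3")
  if (any(object@rgb < -1e-12) || any(object@rgb > 1 + 1e-12))
    msg <- c(msg, "rgb values must lie in [0, 1]")
  if (length(object@freqs) != d[1L]) msg <- c(msg, "freqs must match rows")
  if (length(object@times) != d[2L]) msg <- c(msg, "times must match columns")
  if (length(msg)) msg else TRUE
})

#' VGG16-style backbone for activation-energy extraction
#'
#' The 13-convolutional-layer, 16-layer VGG configuration (conv blocks
#' 64-64 / 128-128 / 256-256-256 / 512-512-512 / 512-512-512 with 2x2 max
#' pooling between blocks). Only the convolutional stack is represented; the
#' fully connected head plays no role in activation-energy features.
#'
#' @slot weights list of 13 elements, each `list(W, b)` where `W` is a
#'   3 x 3 x inChannels x outChannels array and `b` a length-outChannels bias.
#' @slot weightsSource `"seeded-random(<seed>)"` or a user-supplied label for
#'   externally loaded (e.g. ImageNet-pretrained) weights.
#' @slot inputMean,inputStd per-channel centering applied to the \[0, 1\] RGB
#'   image before the first layer (defaults: the ImageNet convention).
#'
#' @seealso [vggBackbone()], [extractFeatureMaps()], [contactUAE()]
#' @export
setClass("VGGBackbone",
  representation(
    weights = "list",
    weightsSource = "character",
    inputMean = "numeric",
    inputStd = "numeric"
  )
)

.vggChannels <- function() {
  list(
    inC  = c(3L, 64L, 64L, 128L, 128L, 256L, 256L, 256L, 512L, 512L, 512L, 512L, 512L),
    outC = c(64L, 64L, 128L, 128L, 256L, 256L, 256L, 512L, 512L, 512L, 512L, 512L, 512L)
  )
}

setValidity("VGGBackbone", function(object) {
  msg <- character()
  ch <- .vggChannels()
  if (length(object@weights) != 13L)
    msg <- c(msg, "backbone must expose exactly 13 convolutional layers")
  else for (l in seq_len(13L)) {
    w <- object@weights[[l]]
    if (!is.list(w) || !all(c("W", "b") %in% names(w))) {
      msg <- c(msg, sprintf("layer %d weights must be list(W, b)", l)); next
    }
    dW <- dim(w$W)
    if (!identical(dW, c(3L, 3L, ch$inC[l], ch$outC[l])))
      msg <- c(msg, sprintf("layer %d kernel must be 3x3x%dx%d", l, ch$inC[l], ch$outC[l]))
    if (length(w$b) != ch$outC[l])
      msg <- c(msg, sprintf("layer %d bias must have length %d", l, ch$outC[l]))
  }
  if (length(object@inputMean) != 3L || length(object@inputStd) != 3L)
    msg <- c(msg, "inputMean and inputStd must each have length 3")
  if (any(object@inputStd <= 0)) msg <- c(msg, "inputStd must be positive")
  if (length(msg)) msg else TRUE
})

#' Fitted extreme-value (minimum-type Gumbel) distribution
#'
#' Maximum-likelihood location and scale of the minimum-type Gumbel density
#' p(x) = (1/sigma) exp(z) exp(-exp(z)), z = (x - mu)/sigma, fitted to one
#' patient's per-layer activation-energy values. The location parameter is the
#' point-of-interest threshold: contacts with values strictly below `location`
#' fall in the low-complexity tail.
#'
#' @slot patientId patient identifier.
#' @slot layer convolutional layer index in 1..13.
#' @slot location location parameter (mu).
#' @slot scale scale parameter (sigma), strictly positive.
#' @slot n number of values used in the fit (at least 8).
#'
#' @seealso [fitEVD()], [thresholdPOI()]
#' @export
setClass("EVDFit",
  representation(
    patientId = "character",
    layer = "integer",
    location = "numeric",
    scale = "numeric",
    n = "integer"
  )
)

setValidity("EVDFit", function(object) {
  msg <- character()
  if (length(object@scale) != 1L || object@scale <= 0)
    msg <- c(msg, "scale must be a single positive number")
  if (length(object@location) != 1L || !is.finite(object@location))
    msg <- c(msg, "location must be a single finite number")
  if (object@n < 8L) msg <- c(msg, "fit requires at least 8 values")
  if (length(msg)) msg else TRUE
})

#' Patient-level three-fold split for grouped cross-validation
#'
#' Assigns each patient to exactly one of three folds such that folds are
#' patient-disjoint, fold sizes differ by at most one patient, and fold-level
#' inside-EZ class fractions are as similar as possible (seeded greedy search
#' over random balanced partitions).
#'
#' @slot fold named integer vector: patient id -> fold in 1..3.
#' @slot classCounts 3 x 2 matrix of contact counts per fold
#'   (columns `inside`, `outside`).
#'
#' @seealso [makeGroupSplits()], [svmPOI()]
#' @export
setClass("GroupSplit",
  representation(fold = "integer", classCounts = "matrix")
)

setValidity("GroupSplit", function(object) {
  msg <- character()
  if (is.null(names(object@fold))) msg <- c(msg, "fold must be named by patient")
  if (!all(object@fold %in% 1:3)) msg <- c(msg, "folds must be in 1..3")
  if (max(table(factor(object@fold, 1:3))) -
      min(table(factor(object@fold, 1:3))) > 1L)
    msg <- c(msg, "fold sizes must differ by at most one patient")
  if (length(msg)) msg else TRUE
})

#' Synthetic iEEG cohort
#'
#' A generated cohort of patients, each with background (1/f) channels, a
#' spatially clustered subset of discharge-bearing channels inside a spherical
#' resection volume, 3-D contact coordinates in millimeters, the binary
#' resection mask with its voxel-to-mm affine, and ground-truth epileptogenic
#' flags (standing in for clinical SOZ flags).
#'
#' @slot patients list; each element has `recording` (an
#'   [IEEGRecording-class]), `coords` (contacts x 3 matrix, mm),
#'   `sozFlag` (logical), `eventTimes` (list of per-channel discharge times),
#'   `mask` (`list(volume, affine)`), and `centroid` (resection center, mm).
#' @slot config the [syntheticConfig()] list used for generation.
#'
#' @seealso [generateCohort()], [writeCohort()]
#' @export
setClass("SyntheticCohort",
  representation(patients = "list", config = "list")
)

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  for (p in object@patients) {
    if (!is(p$recording, "IEEGRecording")) {
      msg <- c(msg, "each patient needs an IEEGRecording"); break
    }
    if (nrow(p$coords) != length(p$recording@labels)) {
      msg <- c(msg, "coords must have one row per channel"); break
    }
    if (!any(p$mask$volume)) { msg <- c(msg, "resection mask must be non-empty"); break }
  }
  if (length(msg)) msg else TRUE
})

#' Per-contact feature container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay `"uae"`
#' (13 layers x contacts) and per-contact geometry and labels in `colData`
#' (`patient`, `contact`, `x`, `y`, `z`, `soz`, `distance_mm`, `in_ez`).
#' Constructed by [buildContactExperiment()].
#'
#' @seealso [buildContactExperiment()], [uaeMatrix()]
#' @export
setClass("ContactExperiment", contains = "SummarizedExperiment")

setValidity("ContactExperiment", function(object) {
  msg <- character()
  if (!"uae" %in% names(assays(object)))
    msg <- c(msg, "assay 'uae' is required")
  else if (nrow(assay(object, "uae")) != 13L)
    msg <- c(msg, "assay 'uae' must have 13 rows (one per conv layer)")
  need <- c("patient", "contact", "soz", "distance_mm", "in_ez")
  if (!all(need %in% colnames(colData(object))))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Point-of-interest detection result
#'
#' Per-contact POI flags for one method (a per-layer extreme-value threshold
#' or the all-layer linear SVM) with each flagged contact's distance to the
#' resection margin and the distance summaries.
#'
#' @slot method `"layer-threshold(L)"` (L in 1..13) or `"svm"`.
#' @slot table data.frame with columns `patient`, `contact`, `flag`,
#'   `distance_mm`, `in_ez`.
#' @slot summary list with `median_mm`, `iqr_mm`, `pct_in_ez`,
#'   `pct_within_10mm`, `n_poi` (see [summarizePOI()]).
#'
#' @seealso [thresholdPOI()], [svmPOI()], [summarizePOI()]
#' @export
setClass("POIResult",
  representation(method = "character", table = "data.frame", summary = "list")
)

setValidity("POIResult", function(object) {
  msg <- character()
  need <- c("patient", "contact", "flag", "distance_mm", "in_ez")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, paste("table must contain:", paste(need, collapse = ", ")))
  if (length(object@method) != 1L) msg <- c(msg, "method must be length 1")
  if (length(msg)) msg else TRUE
})
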