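setMethod("show", "IEEGRecording", function(object) {
  cat("IEEGRecording '", object@patientId, "': ",
      nrow(object@signals), " channels x ",
      ncol(object@signals), " samples @ ", object@samplingRate, " Hz (",
      round(ncol(object@signals) / object@samplingRate, 1), " s), ",
      length(object@excludedChannels), " excluded\n", sep = "")
})

setMethod("show", "TFImage", function(object) {
  cat("TFImage: 224 x 224 amplitude grid, ",
      sprintf("%.1f-%.1f Hz, %.3f-%.3f s", min(object@freqs), max(object@freqs),
              min(object@times), max(object@times)),
      ", jet RGB 224 x 224 x 3\n", sep = "")
})

setMethod("show", "VGGBackbone", function(object) {
  np <- sum(vapply(object@weights, function(w) length(w$W) + length(w$b), 0))
  cat("VGGBackbone: 13 conv layers (", format(np, big.mark = ","),
      " parameters), weights: ", object@weightsSource, "\n", sep = "")
})

setMethod("show", "EVDFit", function(object) {
  cat(sprintf(
    "EVDFit (min-type Gumbel) patient %s, layer %d: location = %.4g, scale = %.4g (n = %d)\n",
    object@patientId, object@layer, object@location, object@scale, object@n))
})

setMethod("show", "GroupSplit", function(object) {
  sizes <- table(factor(object@fold, 1:3))
  cat("GroupSplit: ", length(object@fold), " patients in folds of size ",
      paste(sizes, collapse = "/"), "\n", sep = "")
  print(object@classCounts)
})

setMethod("show", "SyntheticCohort", function(object) {
  n <- length(object@patients)
  nc <- if (n) nrow(object@patients[[1]]$coords) else 0L
  cat("SyntheticCohort: ", n, " patients x ", nc, " contacts, ",
      "fs = ", object@config$sampling_rate, " Hz, ",
      object@config$duration, " s per patient\n", sep = "")
})

setMethod("show", "POIResult", function(object) {
  cat("POIResult [", object@method, "]: ", sum(object@table$flag), " / ",
      nrow(object@table), " contacts flagged; median distance ",
      sprintf("%.2f", object@summary$median_mm), " mm, ",
      sprintf("%.1f%%", object@summary$pct_in_ez), " inside EZ\n", sep = "")
})

#' Accessors for contact-level feature containers
#'
#' @param x a [ContactExperiment-class].
#' @return `uaeMatrix` returns the 13 x contacts activation-energy matrix;
#'   `contactInfo` returns the per-contact `colData` as a data.frame.
#' @examples
#' # see buildContactExperiment()
#' @export
uaeMatrix <- function(x) {
  stopifnot(is(x, "ContactExperiment"))
  assay(x, "uae")
}

#' @rdname uaeMatrix
#' @export
contactInfo <- function(x) {
  stopifnot(is(x, "ContactExperiment"))
  as.data.frame(colData(x))
}

#' Accessors for POI results
#'
#' @param x a [POIResult-class].
#' @return `poiTable` returns the per-contact flag table; `poiSummary` the
#'   distance summary list; `poiMethod` the method label.
#' @export
poiTable <- function(x) { stopifnot(is(x, "POIResult")); x@table }

#' @rdname poiTable
#' @export
poiSummary <- function(x) { stopifnot(is(x, "POIResult")); x@summary }

#' @rdname poiTable
#' @export
poiMethod <- function(x) { stopifnot(is(x, "POIResult")); x@method }
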