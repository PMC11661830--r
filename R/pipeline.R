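## End-to-end orchestration: signals -> TF images -> activation-energy
## features -> geometry labels -> POI detection -> statistical report.

#' Construct a contact-level feature container
#'
#' Low-level constructor for real data already reduced to features: a 13 x
#' contacts UAE matrix plus the per-contact geometry table.
#'
#' @param uae 13 x n numeric matrix (rows = conv layers 1..13).
#' @param info data.frame with columns `patient`, `contact`, `x`, `y`, `z`,
#'   `soz`, `distance_mm`, `in_ez` (one row per contact).
#' @param metadata optional list stored in the experiment metadata.
#' @return a [ContactExperiment-class].
#' @export
contactExperiment <- function(uae, info, metadata = list()) {
  stopifnot(nrow(uae) == 13L, ncol(uae) == nrow(info))
  rownames(uae) <- paste0("L", 1:13)
  se <- SummarizedExperiment(
    assays = list(uae = uae),
    rowData = DataFrame(layer = 1:13),
    colData = DataFrame(info, row.names = paste(info$patient, info$contact,
                                                sep = ".")))
  metadata(se) <- metadata
  new("ContactExperiment", se)
}

#' Run the imaging and complexity stages over a cohort
#'
#' For every contact of every patient: drop excluded channels, bandpass
#' filter to 1-70 Hz, cut non-overlapping 3 s epochs, render each epoch's
#' 224 x 224 jet-RGB Morlet image, extract the 13 per-layer activation
#' energies and average them across epochs. Contact geometry (distance to
#' the resection margin, EZ label) is computed from the coordinates and mask.
#'
#' @param cohort a [SyntheticCohort-class] (or any list of patients in the
#'   same shape: `recording`, `coords`, `sozFlag`, `mask`).
#' @param backbone a [VGGBackbone-class].
#' @param params a [MorletParams-class].
#' @param verbose print per-patient progress.
#' @return a [ContactExperiment-class].
#' @export
buildContactExperiment <- function(cohort, backbone,
                                   params = morletParams(),
                                   verbose = FALSE) {
  patients <- if (is(cohort, "SyntheticCohort")) cohort@patients else cohort
  uaeCols <- list(); infoRows <- list()
  for (p in patients) {
    rec <- selectChannels(p$recording)
    rec <- bandpassFilter(rec)
    keep <- match(rec@labels, p$recording@labels)
    geo <- contactGeometry(
      data.frame(name = rec@labels,
                 x = p$coords[keep, 1], y = p$coords[keep, 2],
                 z = p$coords[keep, 3],
                 soz_flag = p$sozFlag[keep]), p$mask)
    for (i in seq_along(rec@labels)) {
      ep <- epochSignal(rec@signals[i, ], rec@samplingRate)
      images <- lapply(seq_len(nrow(ep)), function(j)
        makeTFImage(ep[j, ], rec@samplingRate, params))
      v <- contactUAE(images, backbone)
      uaeCols[[length(uaeCols) + 1L]] <- v
      infoRows[[length(infoRows) + 1L]] <- data.frame(
        patient = rec@patientId, contact = rec@labels[i],
        x = geo$x[i], y = geo$y[i], z = geo$z[i],
        soz = geo$soz_flag[i], distance_mm = geo$distance_mm[i],
        in_ez = geo$in_ez[i], n_epochs = nrow(ep))
    }
    if (verbose) message("processed ", rec@patientId, " (",
                         length(rec@labels), " contacts)")
  }
  contactExperiment(
    do.call(cbind, uaeCols), do.call(rbind, infoRows),
    metadata = list(
      weightsSource = backbone@weightsSource,
      inputConvention = list(mean = backbone@inputMean, sd = backbone@inputStd),
      morlet = list(nCycles = params@nCycles, freqs = params@freqs,
                    timeStep = params@timeStep),
      layerMap = paste0("conv layer ", 1:13, " = L", 1:13)))
}

#' Identify points of interest from a feature container
#'
#' Runs both detection routes: (a) for each patient and each layer, a
#' minimum-type Gumbel fit to the patient's UAE values with contacts below
#' the location parameter flagged (one POI set per patient-layer, pooled
#' per layer across patients), and (b) the all-layer linear SVM with
#' patient-distinct three-fold cross-validation.
#'
#' @param x a [ContactExperiment-class].
#' @param seed integer seed (fold construction).
#' @param evdType `"min"` (default) or `"max"` Gumbel convention.
#' @return list with `svm` (a [POIResult-class]), `layers` (list of 13
#'   [POIResult-class]), `split` (the [GroupSplit-class]) and `evdFits`
#'   (list of per-patient-layer [EVDFit-class]).
#' @export
runPOIAnalysis <- function(x, seed = 1L, evdType = c("min", "max")) {
  stopifnot(is(x, "ContactExperiment"))
  evdType <- match.arg(evdType)
  feats <- t(uaeMatrix(x))
  info <- contactInfo(x)
  pats <- unique(info$patient)

  evdFits <- list()
  layerResults <- vector("list", 13L)
  for (l in 1:13) {
    flags <- logical(nrow(info))
    for (p in pats) {
      sel <- info$patient == p
      fit <- fitEVD(feats[sel, l], patientId = p, layer = l, type = evdType)
      evdFits[[paste(p, l, sep = ".")]] <- fit
      flags[sel] <- thresholdPOI(feats[sel, l], fit)
    }
    layerResults[[l]] <- new("POIResult",
      method = sprintf("layer-threshold(%d)", l),
      table = data.frame(patient = info$patient, contact = info$contact,
                         flag = flags, distance_mm = info$distance_mm,
                         in_ez = info$in_ez),
      summary = summarizePOI(flags, info))
  }

  split <- makeGroupSplits(info$patient, info$in_ez, seed = seed)
  svmFlags <- svmPOI(feats, info$in_ez, info$patient, split)
  svmResult <- new("POIResult", method = "svm",
    table = data.frame(patient = info$patient, contact = info$contact,
                       flag = svmFlags, distance_mm = info$distance_mm,
                       in_ez = info$in_ez),
    summary = summarizePOI(svmFlags, info))

  list(svm = svmResult, layers = layerResults, split = split,
       evdFits = evdFits)
}

# Per-patient POI distance lists of one POIResult (patients without POIs
# are omitted).
.poiDistancesByPatient <- function(res) {
  tab <- poiTable(res)
  tab <- tab[tab$flag, ]
  split(tab$distance_mm, tab$patient)
}

#' Full statistical report
#'
#' Combines the per-layer SOZ comparison ([layerComparisons()]), the
#' per-method POI distance summaries, and the SVM-versus-each-layer distance
#' comparison ([compareMethods()]) into one JSON-serializable list.
#'
#' @param x a [ContactExperiment-class].
#' @param poi result of [runPOIAnalysis()].
#' @return a nested list; write it with [writeReport()].
#' @export
complexityReport <- function(x, poi) {
  layerStats <- layerComparisons(x)
  methods <- compareMethods(.poiDistancesByPatient(poi$svm),
                            lapply(poi$layers, .poiDistancesByPatient))
  list(
    conventions = list(
      pairing_unit = "patient (mean UAE inside vs outside SOZ)",
      method_comparison_unit = "patient (median POI distance)",
      cohens_d_ci = "noncentral-t, 95%",
      ez_rule = "distance < 5 mm",
      evd = "minimum-type Gumbel, threshold at location parameter"),
    layer_comparisons = layerStats,
    svm_summary = poiSummary(poi$svm),
    layer_summaries = lapply(poi$layers, poiSummary),
    method_comparisons = methods,
    fold_composition = poi$split@classCounts)
}

#' @rdname complexityReport
#' @param report list returned by `complexityReport`.
#' @param path output JSON path.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
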