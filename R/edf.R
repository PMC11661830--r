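## Minimal European Data Format (EDF) input/output: 16-bit integer data
## records with per-channel physical scaling. Covers plain continuous EDF
## only (no EDF+ annotations, no discontinuous records).

.padAscii <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write an iEEG recording as EDF
#'
#' Encodes each channel as 16-bit integers with a per-channel physical range
#' of +/- max absolute amplitude. The record duration is 1 s, so the sampling
#' rate must be a whole number; a trailing sub-second remainder is truncated.
#'
#' @param recording an [IEEGRecording-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @seealso [readEDF()]
#' @export
writeEDF <- function(recording, path) {
  stopifnot(is(recording, "IEEGRecording"))
  fs <- recording@samplingRate
  if (fs != round(fs)) stop("EDF output requires an integer sampling rate")
  fs <- as.integer(fs)
  ns <- nrow(recording@signals)
  nRec <- ncol(recording@signals) %/% fs
  if (nRec < 1L) stop("recording shorter than one 1 s data record")
  sig <- recording@signals[, seq_len(nRec * fs), drop = FALSE]
  physMax <- pmax(apply(abs(sig), 1, max), 1e-6)
  digMax <- 32767; digMin <- -32768
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(paste0(.padAscii(x, width), collapse = ""),
                                     con, eos = NULL)
  headerBytes <- 256L + 256L * ns
  wr("0", 8)                                  # version
  wr(recording@patientId, 80)                 # patient id
  wr("synthetic iEEG", 80)                    # recording id
  wr("01.01.01", 8); wr("00.00.00", 8)        # start date/time
  wr(headerBytes, 8)
  wr("", 44)
  wr(nRec, 8)
  wr(1, 8)                                    # record duration, s
  wr(ns, 4)
  wr(recording@labels, 16)
  wr(rep("", ns), 80)                         # transducer
  wr(rep("uV", ns), 8)                        # physical dimension
  wr(formatC(-physMax, format = "g", digits = 6), 8)
  wr(formatC(physMax, format = "g", digits = 6), 8)
  wr(rep(digMin, ns), 8)
  wr(rep(digMax, ns), 8)
  wr(rep("", ns), 80)                         # prefiltering
  wr(rep(fs, ns), 8)                          # samples per record
  wr(rep("", ns), 32)
  # re-read the physical ranges as written so the scaling is exactly invertible
  pMin <- as.numeric(formatC(-physMax, format = "g", digits = 6))
  pMax <- as.numeric(formatC(physMax, format = "g", digits = 6))
  for (r in seq_len(nRec)) {
    cols <- seq.int((r - 1L) * fs + 1L, r * fs)
    for (ch in seq_len(ns)) {
      x <- sig[ch, cols]
      dig <- round((x - pMin[ch]) / (pMax[ch] - pMin[ch]) *
                     (digMax - digMin) + digMin)
      dig <- pmin(pmax(dig, digMin), digMax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into an iEEG recording
#'
#' Reads a plain continuous EDF file written by [writeEDF()] or by standard
#' acquisition software, provided every channel shares one sampling rate.
#'
#' @param path EDF file path.
#' @return an [IEEGRecording-class] (patientId taken from the EDF patient
#'   field; excludedChannels empty).
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                       # version
  pid <- rd(80)
  rd(80); rd(8); rd(8)        # recording id, date, time
  rd(8)                       # header bytes
  rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)             # transducer
  for (i in seq_len(ns)) rd(8)              # physical dimension
  pMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)             # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel sampling rates are not supported")
  fs <- spr[1L] / recDur
  sig <- matrix(0, ns, nRec * spr[1L])
  for (r in seq_len(nRec)) {
    cols <- seq.int((r - 1L) * spr[1L] + 1L, r * spr[1L])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      sig[ch, cols] <- (dig - dMin[ch]) / (dMax[ch] - dMin[ch]) *
        (pMax[ch] - pMin[ch]) + pMin[ch]
    }
  }
  new("IEEGRecording", patientId = if (nzchar(pid)) pid else "unknown",
      labels = labels, signals = sig, samplingRate = fs,
      excludedChannels = character())
}
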