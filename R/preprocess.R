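## Signal conditioning: channel exclusion, 1-70 Hz zero-phase FIR bandpass,
## and contiguous non-overlapping 3 s epoching.

# Kaiser-window FIR bandpass design, cached per sampling rate. Band edges
# 1-70 Hz with 0.5 Hz (low) and 10 Hz (high) transition widths, 60 dB
# stopband. Applied forward-backward, so the effective attenuation doubles
# and the phase response cancels.
.firCache <- new.env(parent = emptyenv())

.designBandpass <- function(samplingRate) {
  key <- as.character(samplingRate)
  if (!is.null(.firCache[[key]])) return(.firCache[[key]])
  fs <- samplingRate
  fstop1 <- 0.5; fpass1 <- 1; fpass2 <- 70; fstop2 <- 80
  if (fstop2 >= fs / 2) fstop2 <- (fpass2 + fs / 2) / 2
  dev <- 10^(-60 / 20)
  ord <- signal::kaiserord(c(fstop1, fpass1, fpass2, fstop2) / (fs / 2),
                           c(0, 1, 0), c(dev, dev, dev))
  n <- ord$n
  if (n %% 2L == 1L) n <- n + 1L # even order -> odd-length symmetric FIR
  h <- signal::fir1(n, c(fpass1, fpass2) / (fs / 2), type = "pass",
                    window = signal::kaiser(n + 1L, ord$beta))
  .firCache[[key]] <- as.numeric(h)
  .firCache[[key]]
}

# Zero-phase filtering: multiply the spectrum by |H(w)|^2 (forward-backward
# application of the FIR). |H|^2 has zero phase, so the filtered signal is
# already delay-free; zero padding to at least len + 2(nh - 1) keeps the
# wrapped negative-lag tail of the autocorrelation kernel off the signal.
.zeroPhaseFilter <- function(x, h) {
  nh <- length(h)
  n <- length(x) + 2L * (nh - 1L)
  nfft <- stats::nextn(n, 2)
  H <- fft(c(h, numeric(nfft - nh)))
  X <- fft(c(x, numeric(nfft - length(x))))
  y <- Re(fft(X * (Mod(H)^2), inverse = TRUE)) / nfft
  y[seq_along(x)]
}

#' Bandpass filter an iEEG signal to 1-70 Hz
#'
#' Kaiser-window FIR bandpass (1-70 Hz passband, 0.5 Hz low and 10 Hz high
#' transition widths, 60 dB stopband) applied forward-backward for zero net
#' group delay, so discharge timing is preserved in the time-frequency image.
#'
#' @param x numeric time series, or an [IEEGRecording-class] (all channels
#'   filtered).
#' @param samplingRate Hz; must exceed 140 Hz so the 70 Hz passband edge is
#'   below Nyquist. Ignored when `x` is a recording.
#' @return object of the same type as `x`, filtered.
#' @examples
#' y <- bandpassFilter(pinkNoise(5, 256, seed = 1), 256)
#' @export
bandpassFilter <- function(x, samplingRate) {
  if (is(x, "IEEGRecording")) {
    h <- .checkRateAndDesign(x@samplingRate)
    x@signals <- t(apply(x@signals, 1, .zeroPhaseFilter, h = h))
    return(x)
  }
  h <- .checkRateAndDesign(samplingRate)
  .zeroPhaseFilter(as.numeric(x), h)
}

.checkRateAndDesign <- function(samplingRate) {
  if (samplingRate <= 140)
    stop("unsupported sampling rate: need > 140 Hz for a 1-70 Hz passband")
  .designBandpass(samplingRate)
}

#' Segment a signal into non-overlapping 3 s epochs
#'
#' Contiguous 3 s windows from t = 0; an incomplete trailing remainder is
#' dropped.
#'
#' @param x numeric time series of at least 3 s.
#' @param samplingRate Hz.
#' @return matrix with one row per epoch (`3 * samplingRate` columns);
#'   attribute `"starts"` gives each epoch's start time in seconds and
#'   attribute `"samplingRate"` the rate.
#' @examples
#' e <- epochSignal(pinkNoise(7, 256, seed = 1), 256) # 2 epochs
#' @export
epochSignal <- function(x, samplingRate) {
  len <- round(3 * samplingRate)
  if (length(x) < len) stop("signal shorter than one 3 s epoch")
  nEp <- length(x) %/% len
  m <- matrix(x[seq_len(nEp * len)], nrow = nEp, byrow = TRUE)
  attr(m, "starts") <- (seq_len(nEp) - 1L) * 3
  attr(m, "samplingRate") <- samplingRate
  m
}

#' Drop excluded channels from a recording
#'
#' Removes the channels named in `excludedChannels` (continuous-artifact
#' channels from clinical review), preserving the order of the remainder.
#' Exclusion labels not present in the recording produce a warning, not an
#' error.
#'
#' @param recording an [IEEGRecording-class].
#' @return the recording with excluded channels removed and
#'   `excludedChannels` cleared.
#' @export
selectChannels <- function(recording) {
  stopifnot(is(recording, "IEEGRecording"))
  excl <- recording@excludedChannels
  if (!length(excl)) return(recording)
  unknown <- setdiff(excl, recording@labels)
  if (length(unknown))
    warning("exclusion list names absent channel(s): ",
            paste(unknown, collapse = ", "))
  keep <- !(recording@labels %in% excl)
  recording@signals <- recording@signals[keep, , drop = FALSE]
  recording@labels <- recording@labels[keep]
  recording@excludedChannels <- character()
  recording
}
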