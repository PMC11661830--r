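## Fixed-grid Morlet time-frequency imaging: 224 frequencies x 224 times,
## unit normalization, and jet-colormap RGB encoding.

#' Canonical Morlet grid parameters
#'
#' The fixed grid: 224 frequencies from 1.0 Hz in 0.30 Hz steps (1.0-67.9 Hz)
#' and 224 time points in 8.9 ms steps (1.9936 s), centered within the 3 s
#' epoch; wavelet width 7 cycles.
#'
#' @param nCycles wavelet width in cycles.
#' @return a [MorletParams-class].
#' @export
morletParams <- function(nCycles = 7) {
  new("MorletParams", nCycles = nCycles,
      freqs = 1 + 0.30 * (0:223), timeStep = 0.0089)
}

#' Continuous Morlet wavelet transform (amplitude)
#'
#' Convolves a signal with complex Morlet wavelets — Gaussian envelope times
#' a complex exponential, with envelope width sigma = nCycles/(2 pi f) — and
#' returns the amplitude |S_w(f, t)| at every input sample. The wavelet is
#' L1-normalized and truncated at +/- 4 sigma; convolution is FFT-based with
#' zero padding ("same" alignment).
#'
#' @param x numeric time series.
#' @param samplingRate Hz.
#' @param freqs analysis frequencies in Hz.
#' @param nCycles wavelet width in cycles.
#' @return matrix `length(freqs)` x `length(x)` of non-negative amplitudes.
#' @seealso [morletSpectrogram()] for the fixed 224 x 224 grid.
#' @export
morletTransform <- function(x, samplingRate, freqs, nCycles = 7) {
  stopifnot(length(x) > 0, samplingRate > 0, all(freqs > 0))
  n <- length(x)
  out <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    w <- .morletKernel(freqs[i], samplingRate, nCycles)
    L <- (length(w) - 1L) %/% 2L
    nfft <- stats::nextn(n + length(w) - 1L, 2)
    conv <- fft(fft(c(x, numeric(nfft - n))) *
                fft(c(w, complex(length.out = nfft - length(w)))),
                inverse = TRUE) / nfft
    out[i, ] <- Mod(conv[seq.int(L + 1L, L + n)])
  }
  out
}

# Complex Morlet kernel at frequency f: Gaussian envelope (sd = sigma) times
# exp(i 2 pi f t), truncated at 4 sigma, L1-normalized Gaussian divided by
# the sampling rate so amplitude is rate-independent.
.morletKernel <- function(f, samplingRate, nCycles) {
  sigma <- nCycles / (2 * pi * f)
  L <- ceiling(4 * sigma * samplingRate)
  t <- (-L:L) / samplingRate
  exp(-t^2 / (2 * sigma^2)) * exp(2i * pi * f * t) /
    (sigma * sqrt(2 * pi)) / samplingRate
}

#' Morlet spectrogram of a 3 s epoch on the fixed 224 x 224 grid
#'
#' Computes the Morlet amplitude at the 224 grid frequencies, then samples
#' the central 224 x 8.9 ms = 1.9936 s window of the epoch at 8.9 ms steps
#' (linear interpolation between samples), discarding about 0.5 s at each
#' edge where wavelet edge effects dominate.
#'
#' @param epoch numeric vector of exactly 3 s.
#' @param samplingRate Hz.
#' @param params a [MorletParams-class].
#' @return 224 x 224 non-negative matrix (rows = frequency ascending,
#'   columns = time ascending) with attributes `"freqs"` and `"times"`.
#' @export
morletSpectrogram <- function(epoch, samplingRate, params = morletParams()) {
  validObject(params)
  nExp <- round(3 * samplingRate)
  if (length(epoch) != nExp)
    stop("epoch must be exactly 3 s long (", nExp, " samples at ",
         samplingRate, " Hz)")
  amp <- morletTransform(epoch, samplingRate, params@freqs, params@nCycles)
  tSig <- (seq_len(nExp) - 1L) / samplingRate
  tGrid <- 1.5 + (seq_len(224L) - (224L + 1) / 2) * params@timeStep
  out <- matrix(0, 224L, 224L)
  for (i in seq_len(224L))
    out[i, ] <- approx(tSig, amp[i, ], xout = tGrid, rule = 2)$y
  attr(out, "freqs") <- params@freqs
  attr(out, "times") <- tGrid
  out
}

#' Normalize a grid to the unit interval
#'
#' Affine map (x - min)/(max - min) per image; a constant grid maps to all
#' zeros (the conservative "no structure" convention). Per-image
#' normalization removes power differences across contacts and subjects.
#'
#' @param x numeric matrix or array.
#' @return same shape, values in \[0, 1\].
#' @export
normalizeUnit <- function(x) {
  if (!length(x)) stop("empty grid")
  rng <- range(x)
  if (rng[1] == rng[2]) return(x * 0)
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Piecewise-linear jet colormap
#'
#' Maps values in \[0, 1\] to RGB via the continuous jet ramps
#' r = clamp(1.5 - |4x - 3|), g = clamp(1.5 - |4x - 2|),
#' b = clamp(1.5 - |4x - 1|), each clamped to \[0, 1\]. Endpoints:
#' jet(0) = (0, 0, 0.5) (dark blue), jet(1) = (0.5, 0, 0) (dark red).
#'
#' @param x numeric scalar, vector, matrix or array with values in \[0, 1\].
#' @return for a scalar/vector input, a `length(x)` x 3 matrix (columns r, g,
#'   b); for a matrix input, an array `dim(x)` x 3.
#' @examples
#' jetRGB(c(0, 0.375, 1))
#' @export
jetRGB <- function(x) {
  if (any(x < 0 | x > 1)) stop("jet input must lie in [0, 1]")
  clamp <- function(v) pmin(pmax(v, 0), 1)
  r <- clamp(1.5 - abs(4 * x - 3))
  g <- clamp(1.5 - abs(4 * x - 2))
  b <- clamp(1.5 - abs(4 * x - 1))
  if (is.matrix(x)) {
    out <- array(0, c(dim(x), 3L))
    out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
    out
  } else cbind(r = as.numeric(r), g = as.numeric(g), b = as.numeric(b))
}

#' Build the time-frequency image of one epoch
#'
#' Composition of [morletSpectrogram()], [normalizeUnit()] and [jetRGB()]:
#' the raw amplitude grid is kept alongside its 224 x 224 x 3 jet RGB
#' encoding of the unit-normalized grid. Scaling the epoch by any positive
#' constant leaves the RGB image unchanged.
#'
#' @param epoch numeric vector of exactly 3 s.
#' @param samplingRate Hz.
#' @param params a [MorletParams-class].
#' @return a [TFImage-class].
#' @export
makeTFImage <- function(epoch, samplingRate, params = morletParams()) {
  amp <- morletSpectrogram(epoch, samplingRate, params)
  freqs <- attr(amp, "freqs"); times <- attr(amp, "times")
  attributes(amp) <- list(dim = dim(amp))
  rgb <- jetRGB(normalizeUnit(amp))
  new("TFImage", amplitude = amp, rgb = rgb, freqs = freqs, times = times)
}

#' Write a time-frequency image as an 8-bit PNG
#'
#' @param image a [TFImage-class].
#' @param path output path; a JSON sidecar `<path>.json` records the axes.
#' @return invisibly, `path`.
#' @export
writeTFImagePNG <- function(image, path) {
  stopifnot(is(image, "TFImage"))
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write PNG output")
  # flip rows so frequency increases upward in the rendered image
  png::writePNG(image@rgb[rev(seq_len(224L)), , ], path)
  jsonlite::write_json(
    list(freqs_hz = image@freqs, times_s = image@times,
         encoding = "round(255 * jet(normalized amplitude))"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
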