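# Independent oracles used across tests. Each is a deliberately naive
# implementation kept separate from the package's code paths.

# Welch-style PSD: mean periodogram over half-overlapping Hann segments.
welchPSD <- function(x, fs, segSeconds = 8) {
  nseg <- round(segSeconds * fs)
  hop <- nseg %/% 2L
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  starts <- seq(1L, length(x) - nseg + 1L, by = hop)
  P <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * win
    P <- P + Mod(fft(seg))^2
  }
  P <- P / length(starts)
  f <- (seq_len(nseg) - 1L) * fs / nseg
  keep <- seq_len(nseg %/% 2L)
  list(freq = f[keep], power = P[keep])
}

# Naive direct Morlet convolution: same kernel definition as the package
# (L1-normalized Gaussian envelope, 4-sigma truncation), computed by an
# explicit O(n * k) loop per frequency.
directMorlet <- function(x, fs, freqs, nCycles = 7) {
  n <- length(x)
  out <- matrix(0, length(freqs), n)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sigma <- nCycles / (2 * pi * f)
    L <- ceiling(4 * sigma * fs)
    tt <- (-L:L) / fs
    w <- exp(-tt^2 / (2 * sigma^2)) * exp(2i * pi * f * tt) /
      (sigma * sqrt(2 * pi)) / fs
    for (ni in seq_len(n)) {
      acc <- 0 + 0i
      for (k in -L:L) {
        m <- ni - k
        if (m >= 1 && m <= n) acc <- acc + x[m] * w[k + L + 1L]
      }
      out[fi, ni] <- Mod(acc)
    }
  }
  out
}

# Exhaustive sign-permutation two-sided p-value for the signed-rank statistic.
signPermWilcoxon <- function(a, b) {
  d <- (a - b)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  vObs <- sum(r[d > 0])
  total <- 2^n
  stats <- vapply(seq_len(total) - 1L, function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0
    sum(r[signs])
  }, 0)
  pLow <- mean(stats <= vObs)
  pHigh <- mean(stats >= vObs)
  min(1, 2 * min(pLow, pHigh))
}

# Band energy fraction of a transient from its FFT.
bandEnergyFraction <- function(w, fs, loBand, hiBand) {
  n <- 8192L
  W <- Mod(fft(c(w, numeric(n - length(w)))))^2
  f <- (seq_len(n) - 1L) * fs / n
  sum(W[f >= loBand[1] & f <= loBand[2]]) / sum(W[f >= hiBand[1] & f <= hiBand[2]])
}
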