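## Synthetic interictal cohorts: pink-noise background channels plus a
## spatially clustered subset carrying transient broadband (>10 Hz)
## discharges, with contact geometry and a spherical resection volume.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Synthetic cohort configuration
#'
#' Default values emulate the cohort structure the analysis is designed for:
#' 20 patients with 96 contacts each, 2 min of signal, roughly 40% of contacts
#' epileptogenic, pink (1/f) background, and prominent interictal discharges
#' (peak 5x the background RMS, 20 events/min) clustered inside a 15 mm
#' spherical resection volume.
#'
#' @param n_patients number of patients (>= 1).
#' @param contacts_per_patient contacts per patient (>= 1).
#' @param fraction_epileptogenic fraction of contacts carrying discharges,
#'   strictly between 0 and 1.
#' @param sampling_rate sampling rate in Hz.
#' @param duration seconds of signal per patient (>= 3).
#' @param noise_exponent spectral slope of the background (power ~ 1/f^exponent).
#' @param discharge_rate discharge events per minute on epileptogenic channels.
#' @param discharge_amplitude discharge peak as a multiple of background RMS.
#' @param resection_radius radius (mm) of the spherical resection volume.
#' @param seed integer seed; fully determines the generated cohort.
#' @return a validated named list of class `"syntheticConfig"`.
#' @examples
#' cfg <- syntheticConfig(n_patients = 2, contacts_per_patient = 8,
#'                        duration = 6, sampling_rate = 256, seed = 1)
#' @export
syntheticConfig <- function(n_patients = 20L,
                            contacts_per_patient = 96L,
                            fraction_epileptogenic = 0.4,
                            sampling_rate = 512,
                            duration = 120,
                            noise_exponent = 1,
                            discharge_rate = 20,
                            discharge_amplitude = 5,
                            resection_radius = 15,
                            seed = 1L) {
  if (n_patients < 1 || contacts_per_patient < 1)
    stop("n_patients and contacts_per_patient must be >= 1")
  if (fraction_epileptogenic <= 0 || fraction_epileptogenic >= 1)
    stop("fraction_epileptogenic must lie strictly between 0 and 1")
  if (duration < 3) stop("duration must be at least 3 s")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (round(fraction_epileptogenic * contacts_per_patient) < 1)
    stop("fraction_epileptogenic x contacts_per_patient must be at least 1")
  structure(list(
    n_patients = as.integer(n_patients),
    contacts_per_patient = as.integer(contacts_per_patient),
    fraction_epileptogenic = fraction_epileptogenic,
    sampling_rate = sampling_rate,
    duration = duration,
    noise_exponent = noise_exponent,
    discharge_rate = discharge_rate,
    discharge_amplitude = discharge_amplitude,
    resection_radius = resection_radius,
    seed = as.integer(seed)
  ), class = "syntheticConfig")
}

#' Pink (1/f) noise by spectral synthesis
#'
#' Generates a zero-mean Gaussian time series whose power spectrum follows
#' 1/f^exponent, the stand-in for chaotic interictal background activity.
#' Amplitudes are shaped in the frequency domain (white complex Gaussian
#' spectrum scaled by f^(-exponent/2)) and inverse-transformed; the result is
#' standardized to unit variance.
#'
#' @param duration seconds (> 0).
#' @param samplingRate Hz (> 0).
#' @param noiseExponent spectral slope (1 = pink, 0 = white, 2 = brown).
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return numeric vector of length `duration * samplingRate`, zero mean,
#'   unit variance.
#' @examples
#' x <- pinkNoise(10, 256, seed = 7)
#' @export
pinkNoise <- function(duration, samplingRate, noiseExponent = 1, seed = NULL) {
  if (duration <= 0) stop("duration must be positive")
  if (samplingRate <= 0) stop("samplingRate must be positive")
  n <- round(duration * samplingRate)
  .withSeed(seed, {
    nf <- n %/% 2L
    f <- seq_len(nf) * samplingRate / n
    amp <- f^(-noiseExponent / 2)
    z <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * amp / sqrt(2)
    spec <- complex(length.out = n)
    spec[2:(nf + 1L)] <- z
    if (n %% 2L == 0L) {
      spec[nf + 1L] <- complex(real = rnorm(1) * amp[nf]) # Nyquist bin is real
      k <- 2:nf
    } else {
      k <- 2:(nf + 1L)
    }
    spec[n - k + 2L] <- Conj(spec[k])
    x <- Re(fft(spec, inverse = TRUE)) / sqrt(n)
    x <- x - mean(x)
    x / sd(x)
  })
}

#' Canonical interictal discharge waveform
#'
#' A biphasic sharp transient: a Gaussian-windowed 20 Hz sine (envelope sd
#' 15 ms, ~70 ms visible width) followed by a slower opposite-polarity
#' after-wave (envelope sd 60 ms, centered 150 ms later, 25% amplitude). The
#' fast component concentrates spectral energy above 10 Hz, giving the
#' broadband (>10 Hz) signature of an epileptiform sharp discharge; the
#' after-wave adds the low-frequency tail seen in real spikes.
#'
#' @param samplingRate Hz.
#' @return numeric vector (unit peak amplitude) covering -0.1 to 0.4 s around
#'   the sharp peak, with attribute `"peakIndex"` marking t = 0.
#' @examples
#' w <- dischargeWaveform(512)
#' @export
dischargeWaveform <- function(samplingRate) {
  t <- seq(-0.1, 0.4, by = 1 / samplingRate)
  fast <- exp(-t^2 / (2 * 0.015^2)) * sin(2 * pi * 20 * t)
  slow <- -0.25 * exp(-(t - 0.15)^2 / (2 * 0.06^2))
  w <- fast + slow
  w <- w / max(abs(w))
  attr(w, "peakIndex") <- which.min(abs(t)) # t = 0 sample
  w
}

#' Superimpose interictal discharges on a signal
#'
#' Adds biphasic sharp transients ([dischargeWaveform()]) at homogeneous
#' Poisson event times (events closer than 300 ms to the previous event are
#' dropped to avoid overlap). Each transient is scaled so its peak equals
#' `amplitude` times the RMS of the input signal.
#'
#' @param signal numeric time series (non-empty).
#' @param samplingRate Hz.
#' @param rate events per minute (>= 0); 0 returns the input untouched.
#' @param amplitude peak amplitude as a multiple of the input RMS.
#' @param seed integer seed, or NULL.
#' @return `list(signal, eventTimes)` with event times in seconds.
#' @examples
#' x <- pinkNoise(10, 256, seed = 1)
#' out <- addDischarges(x, 256, rate = 12, amplitude = 5, seed = 2)
#' @export
addDischarges <- function(signal, samplingRate, rate, amplitude = 5,
                          seed = NULL) {
  if (!length(signal)) stop("signal must be non-empty")
  if (rate < 0) stop("rate must be non-negative")
  if (rate == 0) return(list(signal = signal, eventTimes = numeric()))
  dur <- length(signal) / samplingRate
  .withSeed(seed, {
    nEvents <- rpois(1L, rate * dur / 60)
    times <- sort(runif(nEvents, 0, dur))
    if (length(times) > 1L) { # greedy: drop events within 300 ms of the last kept
      keptT <- numeric(); last <- -Inf
      for (tt in times) if (tt - last >= 0.3) { keptT <- c(keptT, tt); last <- tt }
      times <- keptT
    }
    w <- dischargeWaveform(samplingRate)
    peak <- attr(w, "peakIndex")
    scale <- amplitude * sqrt(mean(signal^2))
    out <- signal
    kept <- numeric()
    for (tt in times) {
      i0 <- round(tt * samplingRate) + 1L - (peak - 1L)
      idx <- seq.int(i0, i0 + length(w) - 1L)
      ok <- idx >= 1L & idx <= length(out)
      if (!any(ok)) next
      out[idx[ok]] <- out[idx[ok]] + scale * w[ok]
      kept <- c(kept, tt)
    }
    list(signal = out, eventTimes = kept)
  })
}

#' Generate a synthetic cohort
#'
#' For each patient: contact coordinates are sampled in a 100 x 100 x 100 mm
#' box; a consecutive block of `fraction_epileptogenic` contacts is placed
#' uniformly inside a sphere of `resection_radius` around a random centroid
#' and given discharge-bearing signals; the remaining contacts receive pure
#' 1/f background and are kept at least 5 mm outside the sphere so that
#' ground-truth flags and the distance-based EZ labels coincide. The resection
#' mask is the sphere voxelized at 1 mm isotropic resolution (voxel centers at
#' half-integer mm; identity-scaled affine).
#'
#' @param config a [syntheticConfig()].
#' @return a [SyntheticCohort-class].
#' @examples
#' cohort <- generateCohort(syntheticConfig(n_patients = 2,
#'   contacts_per_patient = 8, duration = 6, sampling_rate = 256, seed = 1))
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  box <- 100
  r <- config$resection_radius
  nEp <- round(config$fraction_epileptogenic * config$contacts_per_patient)
  if (nEp < 1) stop("fraction_epileptogenic x contacts_per_patient must be >= 1")
  .withSeed(config$seed, {
    patients <- vector("list", config$n_patients)
    for (p in seq_len(config$n_patients)) {
      pid <- sprintf("P%02d", p)
      centroid <- runif(3, r, box - r)
      nC <- config$contacts_per_patient
      coords <- matrix(NA_real_, nC, 3)
      # epileptogenic block: uniform inside the sphere
      u <- matrix(rnorm(3 * nEp), nEp, 3)
      u <- u / sqrt(rowSums(u^2))
      rad <- r * runif(nEp)^(1 / 3)
      coords[seq_len(nEp), ] <- sweep(u * rad, 2, centroid, "+")
      # background contacts: uniform in the box, outside sphere + 5 mm
      for (i in seq.int(nEp + 1L, nC)) {
        repeat {
          xyz <- runif(3, 0, box)
          if (sqrt(sum((xyz - centroid)^2)) > r + 5) break
        }
        coords[i, ] <- xyz
      }
      flags <- c(rep(TRUE, nEp), rep(FALSE, nC - nEp))
      labels <- sprintf("C%03d", seq_len(nC))
      sig <- matrix(0, nC, round(config$duration * config$sampling_rate))
      events <- vector("list", nC)
      seeds <- sample.int(.Machine$integer.max - 1L, 2L * nC)
      for (i in seq_len(nC)) {
        x <- 50 * pinkNoise(config$duration, config$sampling_rate,
                            config$noise_exponent, seed = seeds[2L * i - 1L])
        if (flags[i]) {
          d <- addDischarges(x, config$sampling_rate, config$discharge_rate,
                             config$discharge_amplitude, seed = seeds[2L * i])
          x <- d$signal
          events[[i]] <- d$eventTimes
        } else events[[i]] <- numeric()
        sig[i, ] <- x
      }
      rec <- new("IEEGRecording", patientId = pid, labels = labels,
                 signals = sig, samplingRate = config$sampling_rate,
                 excludedChannels = character())
      mask <- .sphereMask(centroid, r, box)
      patients[[p]] <- list(patientId = pid, recording = rec, coords = coords,
                            sozFlag = flags, eventTimes = events, mask = mask,
                            centroid = centroid)
    }
    new("SyntheticCohort", patients = patients, config = unclass(config))
  })
}

# Voxelize a sphere on a 1 mm grid over [0, box]^3; voxel centers at
# half-integer mm, so the affine maps 0-based index i to world i + 0.5.
.sphereMask <- function(centroid, radius, box = 100) {
  n <- as.integer(box)
  cc <- seq_len(n) - 0.5
  dx2 <- (cc - centroid[1])^2
  dy2 <- (cc - centroid[2])^2
  dz2 <- (cc - centroid[3])^2
  vol <- array(FALSE, c(n, n, n))
  r2 <- radius^2
  for (k in seq_len(n)) {
    s <- outer(dx2, dy2, "+") + dz2[k]
    vol[, , k] <- s <= r2
  }
  affine <- diag(4)
  affine[1:3, 4] <- 0.5
  list(volume = vol, affine = affine)
}

#' Write a synthetic cohort to disk
#'
#' Writes, per patient, an EDF file with the channel signals, a tab-separated
#' electrode table (`name`, `x`, `y`, `z`, `soz_flag`) and a NIfTI binary
#' resection mask (1 mm isotropic).
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if missing).
#' @return invisibly, a data.frame manifest of the written files.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort@patients, function(p) {
    edf <- file.path(dir, paste0(p$patientId, ".edf"))
    tsv <- file.path(dir, paste0(p$patientId, "_electrodes.tsv"))
    nii <- file.path(dir, paste0(p$patientId, "_resection.nii.gz"))
    writeEDF(p$recording, edf)
    writeElectrodeTable(data.frame(name = p$recording@labels,
                                   x = p$coords[, 1], y = p$coords[, 2],
                                   z = p$coords[, 3],
                                   soz_flag = as.integer(p$sozFlag)), tsv)
    img <- RNifti::asNifti(array(as.integer(p$mask$volume), dim(p$mask$volume)))
    RNifti::qform(img) <- structure(p$mask$affine, code = 2L)
    RNifti::writeNifti(img, nii)
    data.frame(patient = p$patientId, edf = edf, electrodes = tsv, mask = nii)
  })
  invisible(do.call(rbind, rows))
}
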