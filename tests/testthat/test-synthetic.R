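test_that("pink noise is seeded, zero mean, and rejects bad arguments", {
  x1 <- pinkNoise(5, 256, seed = 42)
  x2 <- pinkNoise(5, 256, seed = 42)
  expect_identical(x1, x2)
  expect_false(identical(x1, pinkNoise(5, 256, seed = 43)))
  expect_length(x1, 5 * 256)
  expect_equal(mean(x1), 0, tolerance = 1e-12)
  expect_error(pinkNoise(0, 256), "duration")
  expect_error(pinkNoise(5, -1), "samplingRate")
})

test_that("pink noise spectral slope matches the requested exponent", {
  x <- pinkNoise(120, 512, noiseExponent = 1, seed = 7)
  psd <- welchPSD(x, 512)
  keep <- psd$freq >= 2 & psd$freq <= 60
  slope <- coef(lm(log(psd$power[keep]) ~ log(psd$freq[keep])))[2]
  expect_lt(abs(slope - (-1)), 0.2)
  # steeper exponent gives steeper slope
  xb <- pinkNoise(120, 512, noiseExponent = 2, seed = 7)
  psdb <- welchPSD(xb, 512)
  slopeb <- coef(lm(log(psdb$power[keep]) ~ log(psdb$freq[keep])))[2]
  expect_lt(slopeb, slope - 0.5)
})

test_that("discharge injection is a no-op at rate zero and errors below", {
  x <- pinkNoise(10, 256, seed = 1)
  out <- addDischarges(x, 256, rate = 0)
  expect_identical(out$signal, x)
  expect_length(out$eventTimes, 0)
  expect_error(addDischarges(x, 256, rate = -1), "non-negative")
  expect_error(addDischarges(numeric(), 256, rate = 1), "non-empty")
})

test_that("discharge event counts follow the Poisson model", {
  x <- pinkNoise(120, 256, seed = 2)
  counts <- vapply(1:20, function(s)
    length(addDischarges(x, 256, rate = 10, seed = s)$eventTimes), 0)
  ci <- qpois(c(0.005, 0.995), 20) # 99% interval around 10/min x 2 min
  expect_true(all(counts >= ci[1] & counts <= ci[2]))
  # events are at least 300 ms apart
  ev <- addDischarges(x, 256, rate = 60, seed = 3)$eventTimes
  expect_true(all(diff(ev) >= 0.3))
})

test_that("the discharge waveform is broadband above 10 Hz", {
  for (fs in c(256, 512)) {
    w <- dischargeWaveform(fs)
    frac <- bandEnergyFraction(as.numeric(w), fs, c(10, 70), c(1, 70))
    expect_gt(frac, 0.5)
  }
})

test_that("injected transients dominate the signal where placed", {
  x <- pinkNoise(10, 256, seed = 4)
  out <- addDischarges(x, 256, rate = 12, amplitude = 5, seed = 5)
  expect_gt(length(out$eventTimes), 0)
  # the biphasic peak sits a few ms after the event time; search +/- 50 ms
  i <- round(out$eventTimes[1] * 256) + 1 + seq(-13, 13)
  expect_gt(max(abs(out$signal[i] - x[i])), 2 * sd(x))
})

test_that("cohort generation is seeded and satisfies its geometry contract", {
  cfg <- syntheticConfig(n_patients = 2, contacts_per_patient = 10,
                         fraction_epileptogenic = 0.3, sampling_rate = 256,
                         duration = 3, discharge_rate = 40, seed = 9)
  co1 <- generateCohort(cfg)
  co2 <- generateCohort(cfg)
  expect_identical(co1@patients[[1]]$recording@signals,
                   co2@patients[[1]]$recording@signals)
  expect_identical(co1@patients[[2]]$coords, co2@patients[[2]]$coords)
  expect_length(co1@patients, 2)
  total <- sum(vapply(co1@patients, function(p) length(p$recording@labels), 0L))
  expect_identical(total, 20L)
  for (p in co1@patients) {
    d <- distanceToResection(p$coords[p$sozFlag, , drop = FALSE], p$mask)
    expect_true(all(d == 0)) # flagged contacts sit inside the mask
    dOut <- distanceToResection(p$coords[!p$sozFlag, , drop = FALSE], p$mask)
    expect_true(all(dOut > 0))
  }
})

test_that("epileptogenic channels carry more 10-70 Hz band power", {
  cfg <- syntheticConfig(n_patients = 1, contacts_per_patient = 12,
                         fraction_epileptogenic = 0.34, sampling_rate = 256,
                         duration = 12, discharge_rate = 40, seed = 21)
  co <- generateCohort(cfg)
  p <- co@patients[[1]]
  bandPower <- function(x) {
    P <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * 256 / length(x)
    mean(P[f >= 10 & f <= 70])
  }
  bp <- apply(p$recording@signals, 1, bandPower)
  expect_gt(mean(bp[p$sozFlag]), mean(bp[!p$sozFlag]))
})

test_that("configuration invariants are enforced", {
  expect_error(syntheticConfig(fraction_epileptogenic = 0), "strictly between")
  expect_error(syntheticConfig(fraction_epileptogenic = 1), "strictly between")
  expect_error(syntheticConfig(duration = 2), "at least 3")
  expect_error(syntheticConfig(n_patients = 0), ">= 1")
  expect_error(syntheticConfig(contacts_per_patient = 20,
                               fraction_epileptogenic = 0.01), "at least 1")
})

test_that("cohorts round-trip through EDF, TSV and NIfTI files", {
  cfg <- syntheticConfig(n_patients = 1, contacts_per_patient = 6,
                         fraction_epileptogenic = 0.34, sampling_rate = 256,
                         duration = 3, seed = 5)
  co <- generateCohort(cfg)
  dir <- withr::local_tempdir()
  manifest <- writeCohort(co, dir)
  p <- co@patients[[1]]
  rec <- readEDF(manifest$edf[1])
  expect_identical(rec@labels, p$recording@labels)
  expect_equal(rec@samplingRate, 256)
  tol <- 2 * max(abs(p$recording@signals)) / 65535 # 16-bit quantization
  expect_lt(max(abs(rec@signals - p$recording@signals)), 2 * tol)
  tab <- readElectrodeTable(manifest$electrodes[1])
  expect_identical(tab$soz_flag, p$sozFlag)
  expect_equal(as.matrix(tab[, c("x", "y", "z")]), p$coords,
               ignore_attr = TRUE, tolerance = 1e-6)
  mask <- readResectionMask(manifest$mask[1])
  expect_identical(mask$volume, p$mask$volume)
  expect_equal(mask$affine, p$mask$affine, tolerance = 1e-6)
})
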