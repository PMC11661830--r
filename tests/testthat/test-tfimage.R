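test_that("the Morlet transform matches a naive direct convolution", {
  fs <- 256
  set.seed(11)
  x <- rnorm(round(0.5 * fs)) # 0.5 s probe
  freqs <- c(4, 12.7, 40)
  fast <- morletTransform(x, fs, freqs)
  slow <- directMorlet(x, fs, freqs)
  expect_lt(max(abs(fast - slow)) / max(slow), 1e-6)
})

test_that("the fixed spectrogram grid peaks at the probe frequency", {
  fs <- 512
  t <- seq(1 / fs, 3, by = 1 / fs)
  params <- morletParams()
  for (probe in c(10, 25, 47)) {
    grid <- morletSpectrogram(sin(2 * pi * probe * t), fs, params)
    rowMean <- rowMeans(grid)
    expect_identical(which.max(rowMean), which.min(abs(params@freqs - probe)))
  }
})

test_that("the spectrogram grid shape, axes and degenerate input behave", {
  fs <- 256
  grid <- morletSpectrogram(numeric(3 * fs), fs)
  expect_identical(dim(grid), c(224L, 224L))
  expect_true(all(grid == 0))
  tGrid <- attr(grid, "times")
  expect_equal(diff(range(tGrid)), 223 * 0.0089) # 1.9847 s span, 1.9936 s window
  expect_equal(mean(tGrid), 1.5)                 # centered in the epoch
  f <- attr(grid, "freqs")
  expect_equal(f[1], 1.0)
  expect_equal(f[224], 67.9)
  expect_equal(unique(round(diff(f), 10)), 0.30)
  expect_error(morletSpectrogram(numeric(2 * fs), fs), "exactly 3 s")
})

test_that("unit normalization maps to [0, 1] with the degenerate convention", {
  expect_equal(normalizeUnit(matrix(c(2, 4, 6), 1)), matrix(c(0, 0.5, 1), 1))
  expect_equal(normalizeUnit(matrix(5, 3, 3)), matrix(0, 3, 3))
  set.seed(1)
  g <- normalizeUnit(matrix(rnorm(100), 10))
  expect_equal(min(g), 0)
  expect_equal(max(g), 1)
  expect_error(normalizeUnit(numeric()), "empty")
})

test_that("the jet map hits its endpoints and stays inside [0, 1]", {
  expect_equal(jetRGB(0)[1, ], c(r = 0, g = 0, b = 0.5))
  expect_equal(jetRGB(1)[1, ], c(r = 0.5, g = 0, b = 0))
  expect_equal(jetRGB(0.375)[1, ], c(r = 0, g = 1, b = 1))
  expect_error(jetRGB(-0.01), "\\[0, 1\\]")
  expect_error(jetRGB(1.01), "\\[0, 1\\]")
  xs <- seq(0, 1, by = 1e-4)
  rgb <- jetRGB(xs)
  expect_true(all(rgb >= 0 & rgb <= 1))
  # continuity: piecewise-linear with |slope| <= 4
  expect_lt(max(abs(diff(rgb[, 1]))), 4.1e-4)
  expect_lt(max(abs(diff(rgb[, 2]))), 4.1e-4)
  expect_lt(max(abs(diff(rgb[, 3]))), 4.1e-4)
})

test_that("TF images compose the stages and are amplitude invariant", {
  fs <- 256
  x <- pinkNoise(3, fs, seed = 5)
  img <- makeTFImage(x, fs)
  expect_s4_class(img, "TFImage")
  expect_identical(dim(img@rgb), c(224L, 224L, 3L))
  expect_identical(dim(img@amplitude), c(224L, 224L))
  expect_true(all(img@amplitude >= 0))
  # determinism
  expect_identical(makeTFImage(x, fs)@rgb, img@rgb)
  # positive rescaling of the epoch leaves the normalized image unchanged
  img10 <- makeTFImage(10 * x, fs)
  expect_equal(img10@rgb, img@rgb, tolerance = 1e-12)
  # zero epoch: uniform jet(0) = dark blue
  imgZ <- makeTFImage(numeric(3 * fs), fs)
  expect_true(all(imgZ@rgb[, , 1] == 0))
  expect_true(all(imgZ@rgb[, , 2] == 0))
  expect_true(all(imgZ@rgb[, , 3] == 0.5))
})
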