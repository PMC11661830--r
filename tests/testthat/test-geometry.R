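# A 15 mm sphere voxelized at 1 mm in a 100 mm box, via the same helper the
# cohort generator uses (construction checked against analytic geometry here).
sphereMask <- iEEGComplexity:::.sphereMask(c(50, 50, 50), 15)

test_that("distances to a voxelized sphere match analytic geometry", {
  expect_identical(distanceToResection(c(50, 50, 50), sphereMask), 0)
  # 10 mm outside the surface along an axis: 50 + 15 + 10
  d <- distanceToResection(c(75, 50, 50), sphereMask)
  expect_lt(abs(d - 10), 0.9)
  # along an oblique direction
  p <- c(50, 50, 50) + (15 + 7) * c(1, 1, 1) / sqrt(3)
  expect_lt(abs(distanceToResection(p, sphereMask) - 7), 0.9)
  # any interior point is at distance zero
  expect_identical(distanceToResection(c(58, 50, 50), sphereMask), 0)
  expect_error(
    distanceToResection(c(0, 0, 0),
                        list(volume = array(FALSE, c(5, 5, 5)),
                             affine = diag(4))), "empty")
})

test_that("EZ labeling applies the strict 5 mm rule", {
  expect_true(labelEZ(0))
  expect_true(labelEZ(4.9))
  expect_false(labelEZ(5.0))
  expect_false(labelEZ(12))
  expect_identical(labelEZ(c(0, 4.99, 5, 7)), c(TRUE, TRUE, FALSE, FALSE))
  expect_error(labelEZ(-1), "non-negative")
})

test_that("distance is invariant under joint translation via the affine", {
  shift <- c(-12.5, 8, 3.25)
  shifted <- sphereMask
  shifted$affine[1:3, 4] <- shifted$affine[1:3, 4] + shift
  pts <- rbind(c(75, 50, 50), c(50, 20, 50), c(40, 60, 70))
  d0 <- distanceToResection(pts, sphereMask)
  d1 <- distanceToResection(sweep(pts, 2, -shift), shifted)
  expect_equal(d0, d1, tolerance = 1e-9)
})

test_that("dilating the mask never increases a contact's distance", {
  dilate6 <- function(vol) {
    d <- dim(vol)
    out <- vol
    out[-1, , ] <- out[-1, , ] | vol[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | vol[-1, , ]
    out[, -1, ] <- out[, -1, ] | vol[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | vol[, -1, ]
    out[, , -1] <- out[, , -1] | vol[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | vol[, , -1]
    out
  }
  grown <- list(volume = dilate6(sphereMask$volume), affine = sphereMask$affine)
  set.seed(6)
  pts <- matrix(runif(30, 0, 100), 10)
  expect_true(all(distanceToResection(pts, grown) <=
                  distanceToResection(pts, sphereMask) + 1e-9))
})

test_that("the geometry table combines distances, labels and SOZ flags", {
  tab <- data.frame(name = c("A1", "A2", "A3"),
                    x = c(50, 75, 90), y = c(50, 50, 50), z = c(50, 50, 50),
                    soz_flag = c(TRUE, FALSE, FALSE))
  geo <- contactGeometry(tab, sphereMask)
  expect_identical(geo$in_ez, c(TRUE, FALSE, FALSE))
  expect_identical(geo$distance_mm[1], 0)
  expect_gt(geo$distance_mm[3], geo$distance_mm[2])
  f <- withr::local_tempfile(fileext = ".tsv")
  writeElectrodeTable(tab, f)
  back <- readElectrodeTable(f)
  expect_identical(back$name, tab$name)
  expect_identical(back$soz_flag, tab$soz_flag)
  expect_error(readElectrodeTable(writeElectrodeTable(data.frame(a = 1), f)),
               "must contain")
})
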