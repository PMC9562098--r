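test_that("volumes round-trip through TIFF + sidecar exactly", {
  ramp <- array(seq(0, 1, length.out = 4 * 8 * 4), c(4, 8, 4))
  ramp <- round(ramp * 65535) / 65535 # on the 16-bit storage grid
  vol <- OCTVolume(ramp, axialPixelUm = 4.4, lateralPixelUm = 12,
    metadata = list(patient_id = "P001", eye = "OD", session_id = 3L))
  path <- withr::local_tempfile(fileext = ".tiff")
  writeVolume(vol, path)
  back <- readVolume(path)
  expect_identical(intensities(back), ramp)
  expect_equal(axialPixelUm(back), 4.4)
  expect_equal(lateralPixelUm(back), 12)
  expect_equal(volMetadata(back)$patient_id, "P001")
  expect_equal(volMetadata(back)$session_id, 3L)
})

test_that("volume reading validates the sidecar against the stack", {
  vol <- OCTVolume(array(0.5, c(5, 6, 4)))
  path <- withr::local_tempfile(fileext = ".tiff")
  writeVolume(vol, path)

  expect_error(readVolume(withr::local_tempfile(fileext = ".tiff")),
    "not found")

  sidecar <- sub("\\.tiff$", ".json", path)
  meta <- jsonlite::read_json(sidecar)
  meta$n_slow <- 6
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE)
  expect_error(readVolume(path), "5 pages but sidecar declares n_slow = 6")

  meta$n_slow <- 5
  meta$axial_pixel_um <- -1
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE)
  expect_error(readVolume(path), "non-positive pixel spacing")

  file.remove(sidecar)
  expect_error(readVolume(path), "missing JSON sidecar")
})

test_that("en face projections collapse the axial axis correctly", {
  const <- OCTVolume(array(0.3, c(3, 5, 2)))
  expect_true(all(pixels(enfaceProjection(const, "mean")) == 0.3))
  expect_true(all(pixels(enfaceProjection(const, "max")) == 0.3))

  v <- array(0.2, c(1, 3, 1))
  v[1, , 1] <- c(1, 2, 9) / 10
  vol <- OCTVolume(v)
  expect_equal(pixels(enfaceProjection(vol, "max"))[1, 1], 0.9)
  expect_equal(pixels(enfaceProjection(vol, "mean"))[1, 1], 0.4)
  expect_error(enfaceProjection(vol, "median"))

  # bounds + dominance over a random volume
  rv <- OCTVolume(array(runif(4 * 10 * 5), c(4, 10, 5)))
  mx <- pixels(enfaceProjection(rv, "max"))
  mn <- pixels(enfaceProjection(rv, "mean"))
  expect_true(all(mx >= mn))
  expect_true(all(mn >= min(intensities(rv)) - 1e-12))
  expect_true(all(mx <= max(intensities(rv)) + 1e-12))
})

test_that("the ridge arc is the bright band of the mean projection", {
  ph <- smallPhantom(ridgeHeightUm = 400)
  img <- pixels(enfaceProjection(ph$volume, "mean"))
  crest <- tracePoints(ph$truth@trueRidgeline)
  onArc <- img[cbind(round(crest[, 1]) + 1L, round(crest[, 2]) + 1L)]
  # control samples: same directions, well inside the vascularized zone
  cx <- (48 - 1) / 2
  inward <- crest + 0.55 * (matrix(c(cx, cx), nrow(crest), 2, byrow = TRUE) - crest)
  offArc <- img[cbind(round(inward[, 1]) + 1L, round(inward[, 2]) + 1L)]
  expect_gt(mean(onArc), mean(offArc))
})

test_that("adjacent B-scan averaging is a truncated sliding mean", {
  v <- array(0, c(3, 4, 2))
  v[1, , ] <- 0
  v[2, , ] <- 0.3
  v[3, , ] <- 0.6
  vol <- OCTVolume(v)
  expect_identical(averageAdjacentBscans(vol, 1L), vol)
  sm <- intensities(averageAdjacentBscans(vol, 3L))
  expect_equal(sm[2, 1, 1], 0.3)             # full window
  expect_equal(sm[1, 1, 1], 0.15)            # truncated at the edge
  expect_error(averageAdjacentBscans(vol, 2L), "odd")
  expect_error(averageAdjacentBscans(vol, 5L), "\\[1, 3\\]")

  # linearity: averaging commutes with intensity scaling
  rv <- OCTVolume(array(runif(6 * 5 * 4), c(6, 5, 4)))
  doubled <- rv
  doubled@intensities <- rv@intensities * 2
  expect_equal(intensities(averageAdjacentBscans(doubled, 3L)),
    2 * intensities(averageAdjacentBscans(rv, 3L)))

  # speckle suppression: middle-scan variance strictly drops with k = 5
  ph <- smallPhantom(speckleSnr = 2, nSlow = 16L, nFast = 24L,
    nAxial = 220L, seed = 8)
  raw <- intensities(ph$volume)
  ave <- intensities(averageAdjacentBscans(ph$volume, 5L))
  mid <- 8L
  tissueRows <- 100:125 # inside the retina, away from boundaries
  expect_lt(var(as.vector(ave[mid, tissueRows, ])),
    var(as.vector(raw[mid, tissueRows, ])))
})

test_that("axial scale conversions match the device constants", {
  expect_equal(round(airToTissueDepth(6.0, 1.333), 2), 4.50)
  expect_equal(airToTissueDepth(2.7, 1.0), 2.7)
  expect_equal(airToTissueDepth(4.5, 1.5), 3.0)
  expect_error(airToTissueDepth(-6, 1.33), "positive")

  expect_equal(round(axialPixelSizeUm(airToTissueDepth(6, 1.333), 1024), 1),
    4.4)
  expect_equal(axialPixelSizeUm(1.0, 1000), 1.0)
  expect_equal(axialPixelSizeUm(4.5, 1), 4500)
  expect_error(axialPixelSizeUm(4.5, 0), "positive integer")

  # monotone in both arguments
  px <- vapply(c(256, 512, 1024, 2048), axialPixelSizeUm,
    numeric(1), rangeTissueMm = 4.5)
  expect_true(all(diff(px) < 0))
  rr <- vapply(c(2, 4.5, 6), axialPixelSizeUm, numeric(1), nAxial = 1024)
  expect_true(all(diff(rr) > 0))
})

test_that("en face images export as PNG and TIFF", {
  ph <- smallPhantom(ridgeHeightUm = 100, nAxial = 160L, nFast = 32L,
    nSlow = 32L, speckleSnr = 3, seed = 5)
  img <- enfaceProjection(ph$volume, "mean")
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".tiff")
  writeEnFace(img, p1)
  writeEnFace(img, p2)
  expect_gt(file.size(p1), 0)
  back <- tiff::readTIFF(p2)
  expect_equal(dim(back), dim(pixels(img)))
  expect_error(writeEnFace(img, "x.gif"), "unsupported")
})

test_that("contrast rescale maps the percentile band onto [0, 1]", {
  m <- matrix(seq(0, 10, length.out = 200), 10, 20)
  r <- rescaleContrast(m, 0.1, 0.9)
  expect_equal(range(r), c(0, 1))
  expect_equal(sum(r == 0) / length(r), 0.1, tolerance = 0.02)
  expect_error(rescaleContrast(m, 0.9, 0.1), "lower < upper")
})
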