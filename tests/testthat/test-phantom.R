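test_that("phantom spec enforces its invariants", {
  expect_error(phantomSpec(nVertebrae = 30, vertebraHeight = 44,
                           imageHeight = 512), "packing")
  expect_error(phantomSpec(foregroundIntensity = 40,
                           backgroundIntensity = 200), "exceed")
  expect_error(phantomSpec(targetCobb = 95), "90")
  expect_error(phantomSpec(lateralFalloff = 1.2), "lateralFalloff")
})

test_that("straight phantom with zero target has parallel endplates", {
  ph <- straightPhantom()
  expect_equal(phantomCobb(ph), 0)
  expect_true(all(phantomTruth(ph)$orientationDeg == 0))
})

test_that("mask has exactly one component per vertebra", {
  ph <- curvedPhantom()
  vb <- extractVertebraBoxes(phantomMask(ph))
  expect_identical(nrow(boxTable(vb)), 17L)
  expect_identical(sort(unique(as.vector(phantomMask(ph)))), 0:17)
})

test_that("ground-truth Cobb angle matches the direction-vector oracle", {
  ph <- curvedPhantom()
  tr <- phantomTruth(ph)
  n <- nrow(tr)
  best <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- slopeAngleOracle(tr$upperSlope[i], tr$lowerSlope[j])
    if (a > best) best <- a
  }
  expect_equal(phantomCobb(ph), best, tolerance = 1e-9)
  expect_equal(phantomCobb(ph), 25, tolerance = 0.5)
})

test_that("generation is deterministic for a fixed spec and seed", {
  s <- phantomSpec(targetCobb = 18, seed = 42, noiseSigma = 6)
  a <- generatePhantom(s); b <- generatePhantom(s)
  expect_identical(phantomImage(a), phantomImage(b))
  expect_identical(phantomMask(a), phantomMask(b))
  expect_identical(phantomTruth(a), phantomTruth(b))
})

test_that("box extractor recovers per-vertebra orientation within 1 degree", {
  ph <- curvedPhantom()
  vb <- extractVertebraBoxes(phantomMask(ph))
  meas <- atan(boxTable(vb)$upperSlope) * 180 / pi
  expect_lt(max(abs(meas - phantomTruth(ph)$orientationDeg)), 1)
})

test_that("degrade is the identity at zero sigmas and clips to range", {
  ph <- straightPhantom()
  img <- phantomImage(ph)
  expect_identical(degradeImage(img, 0, 0), img)
  out <- degradeImage(img, 20, 1, seed = 7)
  expect_true(all(out >= 0 & out <= 255))
  expect_identical(out, degradeImage(img, 20, 1, seed = 7))
})

test_that("degradation noise and blur behave quantitatively", {
  flat <- matrix(120, 256, 256)
  noisy <- degradeImage(flat, 10, 0, seed = 5)
  expect_equal(sd(noisy - flat), 10, tolerance = 0.1 * 10)
  ph <- straightPhantom()
  blurred <- degradeImage(phantomImage(ph), 0, 2, seed = 1)
  expect_equal(mean(blurred), mean(phantomImage(ph)), tolerance = 0.01)
})

test_that("image degradation difficulty is monotone in the noise level", {
  clean <- generatePhantom(phantomSpec(noiseSigma = 0, blurSigma = 0,
                                       seed = 9))
  img <- phantomImage(clean)
  mse <- vapply(c(0, 4, 8, 16), function(s)
    pixelMSE(img, degradeImage(img, s, 0, seed = 21)), numeric(1))
  expect_true(all(diff(mse) >= 0))
})

test_that("the training set generator yields the requested phantoms", {
  phs <- phantomTrainingSet(5, seed = 77)
  expect_length(phs, 5)
  for (p in phs) {
    expect_identical(dim(phantomImage(p)), c(64L, 64L))
    expect_identical(max(phantomMask(p)), 4L)
  }
})
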