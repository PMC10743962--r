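test_that("axis-aligned rectangles give exact bounds and flat endplates", {
  m <- matrix(0L, 40, 40); m[10:20, 5:30] <- 1L
  vb <- extractVertebraBoxes(m, minPixels = 1)
  tb <- boxTable(vb)
  expect_identical(nrow(tb), 1L)
  expect_equal(tb$minRow, 10); expect_equal(tb$maxRow, 20)
  expect_equal(tb$minCol, 5); expect_equal(tb$maxCol, 30)
  expect_equal(tb$orientationDeg, 0, tolerance = 1e-9)
  expect_equal(tb$upperSlope, 0, tolerance = 1e-12)
  expect_equal(tb$lowerSlope, 0, tolerance = 1e-12)
  expect_equal(unname(endplateSlopes(vb, 1)), c(0, 0), tolerance = 1e-12)
})

test_that("a rotated rectangle is recovered by box and slope estimators", {
  m <- rasterRotRect(100, 100, 50, 50, 35, 12, 12)
  vb <- extractVertebraBoxes(m, minPixels = 1)
  expect_equal(boxTable(vb)$orientationDeg, 12, tolerance = 1)
  # moment-based slopes (default)
  expect_equal(boxTable(vb)$upperSlope, tan(12 * pi / 180), tolerance = 0.01)
  # edge-fit slopes at a 10-degree tilt
  m10 <- rasterRotRect(100, 100, 50, 50, 40, 14, 10)
  vbE <- extractVertebraBoxes(m10, minPixels = 1, slopeMethod = "edges")
  expect_equal(boxTable(vbE)$upperSlope, tan(10 * pi / 180), tolerance = 0.02)
  expect_equal(boxTable(vbE)$lowerSlope, tan(10 * pi / 180), tolerance = 0.02)
})

test_that("a wedge-shaped body has distinct endplate slopes (edge fit)", {
  m <- matrix(0L, 60, 80)
  for (cc in 15:65) {
    top <- round(20 + (cc - 15) * 0.18)   # sloped upper endplate
    m[top:45, cc] <- 1L                   # flat lower endplate at row 45
  }
  vb <- extractVertebraBoxes(m, minPixels = 1, slopeMethod = "edges")
  expect_equal(boxTable(vb)$upperSlope, 0.18, tolerance = 0.03)
  expect_equal(boxTable(vb)$lowerSlope, 0, tolerance = 0.01)
})

test_that("components are ordered top to bottom and specks dropped", {
  m <- matrix(0L, 60, 30)
  m[40:50, 5:25] <- 1L        # lower, painted first
  m[5:15, 5:25] <- 1L         # upper
  m[30, 29] <- 1L             # one-pixel speck
  vb <- extractVertebraBoxes(m, minPixels = 5)
  tb <- boxTable(vb)
  expect_identical(nrow(tb), 2L)
  expect_lt(tb$centerRow[1], tb$centerRow[2])
  expect_error(extractVertebraBoxes(matrix(0L, 5, 5)), "empty")
})

test_that("the pairwise endplate angle matches its reference cases", {
  flat <- data.frame(upperSlope = c(0.2, 0.2, 0.2),
                     lowerSlope = c(0.2, 0.2, 0.2))
  expect_equal(cobbAngleDeg(cobbAngle(flat)), 0)
  two <- data.frame(upperSlope = c(tan(10 * pi / 180), 0),
                    lowerSlope = c(0, tan(-15 * pi / 180)))
  expect_equal(cobbAngleDeg(cobbAngle(two)), 25, tolerance = 1e-9)
  perp <- data.frame(upperSlope = c(2, 0), lowerSlope = c(0, -0.5))
  expect_equal(cobbAngleDeg(cobbAngle(perp)), 90)
  expect_error(cobbAngle(flat[1, , drop = FALSE]), "at least 2")
})

test_that("angle formula is symmetric and rotation invariant", {
  set.seed(55)
  z <- runif(20, -1.5, 1.5)
  for (k in 1:30) {
    zi <- sample(z, 1); zj <- sample(z, 1)
    expect_equal(cobbQuant:::.slopeAngleDeg(zi, zj),
                 cobbQuant:::.slopeAngleDeg(zj, zi))
    delta <- runif(1, -0.4, 0.4)
    zi2 <- tan(atan(zi) + delta); zj2 <- tan(atan(zj) + delta)
    expect_equal(cobbQuant:::.slopeAngleDeg(zi, zj),
                 cobbQuant:::.slopeAngleDeg(zi2, zj2), tolerance = 1e-9)
  }
})

test_that("severity classes follow the Cobb-method boundaries", {
  expect_identical(classifySeverity(5), "Normal")
  expect_identical(classifySeverity(23.80), "Moderate")
  expect_identical(classifySeverity(43.70), "Severe")
  expect_identical(classifySeverity(c(0, 10, 20, 40, 40.01)),
                   c("Normal", "Mild", "Moderate", "Moderate", "Severe"))
  expect_error(classifySeverity(-1), "nonnegative")
})

test_that("reference vertebrae and pair table are reported coherently", {
  ph <- curvedPhantom()
  res <- cobbAngle(extractVertebraBoxes(phantomMask(ph)))
  expect_lt(res@upperIndex, res@lowerIndex)
  expect_identical(severityClass(res), classifySeverity(cobbAngleDeg(res)))
  pt <- anglePairs(res)
  expect_identical(nrow(pt), 136L)   # choose(17, 2) pairs
  expect_equal(max(pt$angle), cobbAngleDeg(res))
  resAdj <- cobbAngle(extractVertebraBoxes(phantomMask(ph)),
                      adjacentOnly = TRUE)
  expect_identical(resAdj@lowerIndex, resAdj@upperIndex + 1L)
})
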