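test_that("explicit-box crop is an exact passthrough with its offset", {
  img <- matrix(1:100, 10, 10)
  cr <- cropSpineROI(img, box = c(3, 7, 2, 9))
  expect_identical(cr$image, img[3:7, 2:9])
  expect_identical(unname(cr$offset), c(3L, 2L))
  expect_error(cropSpineROI(matrix(5, 4, 4)), "blank")
})

test_that("automatic crop keeps all foreground and shrinks the frame", {
  ph <- fixture("wideStraight", function()
    generatePhantom(phantomSpec(imageWidth = 512L, amplitude = 20,
                                centerlineModel = "single-arc",
                                targetCobb = 10, seed = 6)))
  cr <- cropSpineROI(phantomImage(ph))
  mask <- phantomMask(ph)
  fg <- which(mask > 0, arr.ind = TRUE)
  expect_true(all(fg[, 1] >= cr$offset["row"] &
                  fg[, 1] <= cr$offset["row"] + nrow(cr$image) - 1))
  expect_true(all(fg[, 2] >= cr$offset["col"] &
                  fg[, 2] <= cr$offset["col"] + ncol(cr$image) - 1))
  expect_lt(length(cr$image) / length(phantomImage(ph)), 0.6)
})

test_that("center line tracks a straight spine within 2 px", {
  ph <- straightPhantom()
  cl <- detectCenterLine(wienerFilter(phantomImage(ph)))
  rows <- cl@rowRange[1]:cl@rowRange[2]
  expect_lt(max(abs(curveColumns(cl, rows) - ncol(phantomImage(ph)) / 2)), 2)
  # non-constant coefficients are negligible on a straight spine
  expect_true(all(abs(cl@coefficients[-1]) < 0.01))
  expect_error(detectCenterLine(matrix(1, 64, 64)), "constant")
})

test_that("center line follows a curved spine within 3 px", {
  ph <- fixture("arc10", function()
    generatePhantom(phantomSpec(centerlineModel = "single-arc",
                                amplitude = 10, targetCobb = 10, seed = 8)))
  cl <- detectCenterLine(wienerFilter(phantomImage(ph)))
  tr <- phantomTruth(ph)
  fit <- curveColumns(cl, tr$centerRow)
  expect_lt(max(abs(fit - tr$centerCol)), 3)
})

test_that("lateral boundaries bracket the spine at its true half-width", {
  ph <- straightPhantom()
  img <- wienerFilter(phantomImage(ph))
  cl <- detectCenterLine(img)
  bp <- detectLateralBoundaries(img, cl)
  tr <- phantomTruth(ph)
  # evaluate at vertebra centers: between vertebrae the edge-search strip
  # spans the disc gap and the lateral edge is genuinely undefined
  rows <- round(tr$centerRow[3:15])
  bc <- curveColumns(bp, rows)
  ctr <- ncol(img) / 2
  halfW <- ph@spec$vertebraWidth / 2
  expect_lt(max(abs(bc[, "left"] - (ctr - halfW))), 2)
  expect_lt(max(abs(bc[, "right"] - (ctr + halfW))), 2)
  allRows <- bp@rowRange[1]:bp@rowRange[2]
  bcAll <- curveColumns(bp, allRows)
  expect_true(all(bcAll[, "left"] < bcAll[, "right"]))
})

test_that("a widening spine yields monotonically increasing fitted width", {
  # trapezoid: bright region widening linearly down the image
  img <- matrix(30, 400, 200)
  for (r in 50:350) {
    hw <- 30 + (r - 50) * 0.1
    img[r, round(100 - hw):round(100 + hw)] <- 190
  }
  img <- degradeImage(img, 4, 1, seed = 2)
  cl <- detectCenterLine(img)
  bp <- detectLateralBoundaries(img, cl)
  rows <- seq(80, 320, by = 20)
  bc <- curveColumns(bp, rows)
  width <- bc[, "right"] - bc[, "left"]
  expect_true(all(diff(width) > -2))
  expect_gt(width[length(width)], width[1] + 20)
})

test_that("summed histogram counts zero-indicator features per bin", {
  proj <- rbind(c(0, 1, 0, 2), c(0, 0, 3, 4), c(0, 5, 0, 6), c(7, 0, 0, 8))
  sh <- summedHistogram(proj)
  expect_identical(sh$summed, c(3, 2, 3, 0))
  expect_true(all(sh$indicator %in% c(0, 1)))
  allPos <- matrix(1, 3, 5)
  expect_identical(summedHistogram(allPos)$summed, rep(0, 5))
  expect_error(summedHistogram(list(1:3, 1:4)), "equal length")
})

test_that("vertebra identification recovers counts and labels", {
  ph12 <- fixture("twelve", function()
    generatePhantom(phantomSpec(nVertebrae = 12L, targetCobb = 15,
                                seed = 13)))
  img <- wienerFilter(phantomImage(ph12))
  cl <- detectCenterLine(img)
  bp <- detectLateralBoundaries(img, cl)
  rois <- identifyVertebrae(img, bp, minVertebraHeight = 22)
  expect_identical(nrow(rois), 12L)
  expect_true(!is.unsorted(rois$topRow))
  expect_true(all(rois$bottomRow > rois$topRow))

  ph17 <- curvedPhantom()
  img <- wienerFilter(phantomImage(ph17))
  cl <- detectCenterLine(img)
  bp <- detectLateralBoundaries(img, cl)
  rois <- identifyVertebrae(img, bp, minVertebraHeight = 22)
  expect_identical(nrow(rois), 17L)
  expect_identical(rois$label,
                   c(sprintf("TH%02d", 1:12), sprintf("LU%02d", 1:5)))
})

test_that("an uninterrupted bright column has no detectable disc gaps", {
  img <- matrix(30, 300, 120)
  img[20:280, 40:80] <- 200
  cl <- detectCenterLine(img)
  bp <- detectLateralBoundaries(img, cl)
  expect_error(identifyVertebrae(img, bp), "no disc gaps")
})

test_that("ROIs map back into the original frame through the crop offset", {
  ph <- curvedPhantom()
  cr <- cropSpineROI(phantomImage(ph))
  img <- wienerFilter(cr$image)
  cl <- detectCenterLine(img)
  bp <- detectLateralBoundaries(img, cl)
  rois <- identifyVertebrae(img, bp, minVertebraHeight = 22)
  origRows <- rois$topRow + cr$offset["row"] - 1L
  origCols <- rois$leftCol + cr$offset["col"] - 1L
  expect_true(all(origRows >= 1 & origRows <= nrow(phantomImage(ph))))
  expect_true(all(origCols >= 1 & origCols <= ncol(phantomImage(ph))))
})
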