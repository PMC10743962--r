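test_that("weighted grayscale conversion uses the published channel weights", {
  rgb <- array(0, c(2, 2, 3))
  rgb[1, 1, ] <- c(100, 100, 100)
  rgb[1, 2, ] <- c(255, 0, 0)
  g <- toWeightedGray(rgb)
  expect_equal(g[1, 1], 100)
  expect_equal(g[1, 2], 0.21 * 255)
  expect_equal(g[2, 2], 0)
  expect_identical(toWeightedGray(g), g)              # pass-through
  expect_error(toWeightedGray(array(0, c(2, 2, 2))), "channels")
})

test_that("noise variance estimation matches a known noise level", {
  expect_equal(estimateNoiseVariance(matrix(7, 32, 32)), 0)
  set.seed(123)
  flat <- matrix(100 + rnorm(256 * 256, 0, 5), 256, 256)
  est1 <- estimateNoiseVariance(flat)
  expect_equal(est1, 25, tolerance = 0.1 * 25)
  set.seed(124)
  flat2 <- matrix(100 + rnorm(256 * 256, 0, 10), 256, 256)
  expect_gt(estimateNoiseVariance(flat2) / est1, 3.5)
  expect_lt(estimateNoiseVariance(flat2) / est1, 4.5)
})

test_that("Wiener filter honours its closed-form identities", {
  const <- matrix(7, 16, 16)
  expect_equal(wienerFilter(const), const)
  ph <- straightPhantom()
  img <- phantomImage(ph)[1:64, 1:64]
  expect_equal(wienerFilter(img, noiseVariance = 0), img)
  expect_error(wienerFilter(matrix(1, 2, 2), window = c(5, 5)), "window")
})

test_that("Wiener center pixel matches a hand-evaluated oracle", {
  img <- matrix(0, 5, 5); img[3, 3] <- 90
  # independent evaluation at the center: 3x3 local stats (no padding
  # needed at the center), noise variance = mean local variance with
  # reflect padding, then the shrinkage formula
  meanC <- mean(img[2:4, 2:4])
  varC <- mean((img[2:4, 2:4] - meanC)^2)
  pad <- rbind(img[2, ], img, img[4, ])
  pad <- cbind(pad[, 2], pad, pad[, 4])
  vars <- matrix(0, 5, 5)
  for (r in 1:5) for (cc in 1:5) {
    w <- pad[r:(r + 2), cc:(cc + 2)]
    vars[r, cc] <- mean((w - mean(w))^2)
  }
  nv <- mean(vars)
  s2 <- max(varC - nv, 0)
  expected <- meanC + s2 / (s2 + nv) * (90 - meanC)
  out <- wienerFilter(img)
  expect_equal(out[3, 3], expected, tolerance = 1e-12)
})

test_that("Wiener output is a shrinkage toward the local mean everywhere", {
  set.seed(31)
  for (k in 1:5) {
    img <- matrix(runif(48 * 40, 0, 255), 48, 40)
    ls <- cobbQuant:::.localStats(img, c(3L, 3L))
    out <- wienerFilter(img)
    expect_true(all(abs(out - ls$mean) <= abs(img - ls$mean) + 1e-9))
  }
})

test_that("piecewise-constant plateaus are fixed points away from borders", {
  img <- matrix(40, 32, 32); img[10:22, 10:22] <- 200
  out <- wienerFilter(img)
  interior <- out[13:19, 13:19]
  expect_equal(interior, matrix(200, 7, 7), tolerance = 1e-9)
  expect_equal(out[1:5, 1:5], matrix(40, 5, 5), tolerance = 1e-9)
})

test_that("filtering reduces MSE to the clean image for sigma >= 5", {
  clean <- phantomImage(generatePhantom(phantomSpec(noiseSigma = 0,
                                                    seed = 4)))[1:256, ]
  for (s in c(5, 10, 20)) {
    noisy <- degradeImage(clean, s, 0, seed = 40 + s)
    filt <- wienerFilter(noisy)
    expect_lt(pixelMSE(filt, clean), pixelMSE(noisy, clean))
  }
})

test_that("VIF scores the identity as 1 and degrades with noise", {
  ph <- straightPhantom()
  ref <- phantomImage(ph)[257:512, ]
  expect_equal(vifScore(ref, ref), 1, tolerance = 1e-6)
  n5 <- degradeImage(ref, 5, 0, seed = 1)
  n25 <- degradeImage(ref, 25, 0, seed = 1)
  expect_lt(vifScore(ref, n25), 0.5)
  expect_gt(vifScore(ref, n5), vifScore(ref, n25))
  expect_error(vifScore(ref, ref[1:10, 1:10]), "shape")
  expect_error(vifScore(matrix(1, 8, 8), matrix(1, 8, 8)), "constant")
})

test_that("Pearson and Spearman correlations behave on reference cases", {
  expect_equal(unname(ccSrocc(1:10, 1:10)), c(1, 1))
  expect_equal(unname(ccSrocc(1:10, 10:1)), c(-1, -1))
  r <- ccSrocc(c(1, 2, 3, 4), c(1, 4, 9, 16))
  expect_equal(unname(r["srocc"]), 1)
  # textbook Pearson on the same pairs
  a <- c(1, 2, 3, 4); b <- c(1, 4, 9, 16)
  cc <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(unname(r["cc"]), cc)
  expect_error(ccSrocc(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(ccSrocc(1:2, 1:2), "at least 3")
})
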