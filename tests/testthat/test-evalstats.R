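test_that("overlap metrics reproduce hand-counted cases", {
  gt <- matrix(0, 4, 4); pr <- matrix(0, 4, 4)
  gt[1, 1:4] <- 1                 # 4 px
  pr[1, 3:4] <- 1; pr[2, 1:2] <- 1  # 4 px, overlap 2
  expect_equal(maskIoU(gt, pr), 2 / 6)
  expect_equal(maskDice(gt, pr), 4 / 8)
  expect_equal(maskIoU(gt, gt), 1)
  expect_equal(maskDice(gt, gt), 1)
  z <- matrix(0, 4, 4)
  expect_equal(maskIoU(z, z), 1)   # agreement on absence
  expect_equal(maskDice(z, z), 1)
  expect_equal(maskIoU(gt, z), 0)
  expect_equal(maskDice(gt, z), 0)
  expect_error(maskIoU(gt, matrix(0, 3, 3)), "shape")
})

test_that("Dice and IoU obey their algebraic identity on random masks", {
  set.seed(8)
  for (k in 1:1000) {
    a <- matrix(rbinom(64, 1, runif(1, 0.05, 0.9)), 8, 8)
    b <- matrix(rbinom(64, 1, runif(1, 0.05, 0.9)), 8, 8)
    iou <- maskIoU(a, b)
    expect_equal(maskDice(a, b), 2 * iou / (1 + iou), tolerance = 1e-12)
  }
})

test_that("pixelwise MSE matches hand arithmetic", {
  expect_equal(pixelMSE(matrix(1, 3, 3), matrix(1, 3, 3)), 0)
  expect_equal(pixelMSE(matrix(c(0, 1, 2), 1), matrix(c(1, 1, 4), 1)),
               5 / 3)
  gt <- matrix(rbinom(100, 1, 0.4), 10, 10)
  pr <- gt; pr[1:7] <- 1 - pr[1:7]
  expect_equal(pixelMSE(gt, pr), 7 / 100)
})

test_that("pooled t-test matches hand formula and the stats oracle", {
  r <- twoSampleT(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3 / sqrt(2 / 3))   # pooled SD is exactly 1
  expect_identical(r$df, 4)
  expect_equal(twoSampleT(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_error(twoSampleT(c(1, 1), c(1, 1)), "pooled")
  expect_error(twoSampleT(1, c(1, 2)), "at least 2")
  set.seed(99)
  for (k in 1:100) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), 0.3)
    mine <- twoSampleT(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("MAPE matches hand arithmetic and is scale invariant", {
  expect_equal(mapeScore(c(10, 20), c(11, 18))$mape, 10)
  expect_equal(mapeScore(1:5, 1:5)$mape, 0)
  expect_error(mapeScore(c(0, 1), c(1, 1)), "zero")
  set.seed(12)
  a <- runif(10, 5, 50); x <- a + rnorm(10)
  m0 <- mapeScore(a, x)$mape
  for (cc in c(-3, 0.1, 7))
    expect_equal(mapeScore(cc * a, cc * x)$mape, m0, tolerance = 1e-12)
})

test_that("cross-validation partitions, scores and aggregates correctly", {
  set.seed(5)
  cases <- lapply(1:12, function(i) {
    img <- matrix(runif(64, 0, 255), 8, 8)
    list(image = img, mask = (img > 128) * 1)
  })
  trainer <- function(train, seed) {
    thr <- mean(vapply(train, function(cs) mean(cs$image), numeric(1)))
    function(img) (img > thr) * 1
  }
  rep <- crossValidate(cases, k = 4, trainer = trainer, seed = 3)
  expect_identical(nrow(rep), 5L)
  foldId <- attr(rep, "foldId")
  expect_identical(sort(unique(foldId)), 1:4)
  expect_identical(length(foldId), 12L)
  expect_equal(rep$sdc[5], mean(rep$sdc[1:4]), tolerance = 1e-12)
  expect_equal(rep$iou[5], mean(rep$iou[1:4]), tolerance = 1e-12)
  expect_error(crossValidate(cases, k = 1, trainer = trainer), "at least 2")
  expect_error(crossValidate(cases[1:3], k = 4, trainer = trainer),
               "smaller")
})

test_that("the bundled agreement study carries the expected layout", {
  tab <- cobbAgreementStudy()
  expect_identical(nrow(tab), 10L)
  expect_true(all(c("autoAngle", "expertAngle") %in% names(tab)))
  expect_equal(tab$autoAngle[tab$id == "0021"], 23.80)
  expect_equal(tab$expertAngle[tab$id == "0021"], 23.50)
})
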