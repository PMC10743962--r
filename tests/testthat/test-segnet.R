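# Desk-scale architecture and engine tests use a narrow channel plan so the
# mechanics (shapes, gradients, determinism) are checked in seconds; the
# full published plan is exercised by the model-description test and by the
# training runs in the acceptance suite.

tinyConfig <- function(size = c(32L, 32L), dropout = 0, useFPN = FALSE)
  netConfig(inputSize = size,
            channelsPlan = list(c(2L, 2L), c(2L, 2L), c(4L, 4L), c(4L, 4L)),
            bottleneckChannels = 4L, dropout = dropout, useFPN = useFPN)

test_that("the default architecture follows the published layout", {
  m <- buildModel(netConfig(), seed = 1)
  d <- modelDescription(m)
  convs <- d$channels[d$op == "conv"]
  expect_identical(convs[1:3], c(32L, 32L, 64L))     # first encoder block
  expect_identical(convs[4:6], c(64L, 64L, 128L))    # second encoder block
  rates <- sort(unique(d$dilation[d$op == "conv" & d$dilation > 1]))
  expect_identical(rates, c(2L, 4L, 6L))             # ASPP atrous rates
  expect_true(any(d$op == "gap"))                    # image-pooling branch
  expect_identical(d$op[nrow(d)], "sigmoid")
  expect_error(netConfig(inputSize = c(60, 60)), "divisible")
  expect_error(netConfig(atrousRates = c(4, 2)), "increasing")
})

test_that("a forward pass maps any input into (0,1) at the input shape", {
  m <- buildModel(tinyConfig(), seed = 3)
  p0 <- netForward(m, matrix(0, 32, 32))
  expect_identical(dim(p0), c(32L, 32L, 1L))
  expect_true(all(p0 > 0 & p0 < 1))
  p1 <- netForward(m, matrix(runif(32 * 32, 0, 255), 32, 32))
  expect_true(all(is.finite(p1) & p1 > 0 & p1 < 1))
})

test_that("analytic gradients agree with central differences", {
  m <- buildModel(tinyConfig(), seed = 2)
  set.seed(9)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  y <- array(rbinom(2048, 1, 0.3), c(32, 32, 1, 2))
  fw <- cobbQuant:::.graphForward(m, x, training = TRUE)
  out <- fw$acts[[length(m@graph)]]
  dOut <- 2 * (out - y) / length(out)
  bw <- cobbQuant:::.graphBackward(m, fw,
                                   setNames(list(dOut), length(m@graph)))
  loss <- function(mm) {
    ff <- cobbQuant:::.graphForward(mm, x, training = TRUE)
    mean((ff$acts[[length(mm@graph)]] - y)^2)
  }
  set.seed(17)
  picks <- list(c("conv001", "W"), c("conv005", "W"), c("bn003", "gamma"),
                c("bn010", "beta"), c("conv014", "W"))
  for (p in picks) {
    nm <- p[1]; f <- p[2]
    k <- sample(length(m@params[[nm]][[f]]), 1)
    eps <- 1e-5
    mp <- m; mp@params[[nm]][[f]][k] <- mp@params[[nm]][[f]][k] + eps
    mn <- m; mn@params[[nm]][[f]][k] <- mn@params[[nm]][[f]][k] - eps
    num <- (loss(mp) - loss(mn)) / (2 * eps)
    ana <- bw$pgrads[[nm]][[f]][k]
    # float32 convolution GEMMs limit both gradients to ~1e-3 relative
    expect_equal(ana, num, tolerance = 5e-2)
  }
})

test_that("training is deterministic and improves the loss", {
  phs <- phantomTrainingSet(6, size = 64, seed = 300)
  cfg <- trainConfig(batchSize = 3L, epochs = 3L, valFraction = 0,
                     seed = 4L)
  m1 <- trainModel(buildModel(tinyConfig(c(64L, 64L), dropout = 0.2),
                              seed = 5), phs, cfg)
  m2 <- trainModel(buildModel(tinyConfig(c(64L, 64L), dropout = 0.2),
                              seed = 5), phs, cfg)
  expect_identical(trainingHistory(m1)$trainLoss,
                   trainingHistory(m2)$trainLoss)
  h <- trainingHistory(m1)
  expect_lt(h$trainLoss[nrow(h)], h$trainLoss[1])
  expect_true(all(is.finite(h$trainLoss)))
  bad <- phs; bad[[1]] <- list(image = matrix(0, 64, 64),
                               mask = matrix(0L, 32, 32))
  expect_error(trainModel(buildModel(tinyConfig(c(64L, 64L)), seed = 1),
                          bad, cfg), "mismatch")
})

test_that("segmentation thresholding and trained-model guard behave", {
  m <- buildModel(tinyConfig(c(64L, 64L)), seed = 7)
  expect_error(segmentImage(m, matrix(0, 64, 64)), "trained")
  seg <- segmentImage(m, matrix(runif(64 * 64, 0, 255), 64, 64),
                      requireTrained = FALSE)
  expect_true(all(seg$prob > 0 & seg$prob < 1))
  hi <- segmentImage(m, matrix(runif(64 * 64, 0, 255), 64, 64),
                     threshold = max(seg$prob) + 1e-6,
                     requireTrained = FALSE)
  expect_identical(max(hi$mask), 0L)                 # nothing passes
  lo <- segmentImage(m, matrix(runif(64 * 64, 0, 255), 64, 64),
                     threshold = 0, requireTrained = FALSE)
  expect_true(all(lo$mask > 0))                      # everything passes
})

test_that("the feature pyramid fuses four levels at matching shapes", {
  fpn <- buildAtrousFPN(inChannels = c(4L, 4L, 8L, 8L), mapSize = c(32L, 32L),
                        fpnChannels = 6L, seed = 2)
  feats <- list(array(0, c(32, 32, 4, 1)), array(0, c(16, 16, 4, 1)),
                array(0, c(8, 8, 8, 1)), array(0, c(4, 4, 8, 1)))
  outs <- fpnForward(fpn, feats)
  expect_length(outs, 4)
  sizes <- t(vapply(outs, function(o) dim(o)[1:3], integer(3)))
  expect_equal(sizes[, 1], c(32, 16, 8, 4))
  expect_true(all(sizes[, 3] == 6))
  expect_true(all(vapply(outs, function(o) all(is.finite(o)), logical(1))))
  # weight sharing: the parameter count does not depend on spatial size
  fpn2 <- buildAtrousFPN(inChannels = c(4L, 4L, 8L, 8L),
                         mapSize = c(64L, 64L), fpnChannels = 6L, seed = 2)
  expect_identical(modelParameterCount(fpn), modelParameterCount(fpn2))
  expect_error(fpnForward(fpn, feats[1:3]), "four")
})

test_that("disabling the pyramid flag reproduces the plain model exactly", {
  a <- buildModel(tinyConfig(useFPN = FALSE), seed = 6)
  b <- buildModel(netConfig(inputSize = c(32L, 32L),
                            channelsPlan = list(c(2L, 2L), c(2L, 2L),
                                                c(4L, 4L), c(4L, 4L)),
                            bottleneckChannels = 4L, dropout = 0), seed = 6)
  expect_identical(a@params, b@params)
  expect_identical(length(a@graph), length(b@graph))
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(netForward(a, x), netForward(b, x))
  withFPN <- buildModel(tinyConfig(useFPN = TRUE), seed = 6)
  expect_gt(modelParameterCount(withFPN), modelParameterCount(a))
  pf <- netForward(withFPN, x)
  expect_true(all(is.finite(pf) & pf > 0 & pf < 1))
})

test_that("the ASPP bottleneck widens the receptive field", {
  base <- list(c(2L, 2L), c(2L, 2L), c(2L, 2L), c(2L, 2L))
  withA <- buildModel(netConfig(inputSize = c(512L, 512L),
                                channelsPlan = base, bottleneckChannels = 2L,
                                dropout = 0, useASPP = TRUE), seed = 3)
  plain <- buildModel(netConfig(inputSize = c(512L, 512L),
                                channelsPlan = base, bottleneckChannels = 2L,
                                dropout = 0, useASPP = FALSE), seed = 3)
  expect_gt(receptiveFieldProbe(withA, seed = 4),
            receptiveFieldProbe(plain, seed = 4))
})
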