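# Encoder-decoder segmentation network with a bottleneck atrous spatial
# pyramid pooling (ASPP) block, written from first principles: a static
# layer graph evaluated by a forward/backward engine over Rcpp kernels
# (im2col+GEMM convolution with dilation, batch normalization, 2x2 max
# pooling, bilinear x2 upsampling). Tensors are (H, W, C, N) arrays.

#' Network architecture configuration
#'
#' The default encoder plan follows the published layout: four blocks of
#' three conv-BN-ReLU layers with feature maps (32, 32, 64), (64, 64, 128),
#' then doubling of the subsampled maps up to a 256 cap; a bottleneck ASPP
#' with atrous rates 2, 4, 6 plus an image-pooling branch; a mirrored
#' decoder with bilinear upsampling, skip concatenation and conv-BN-ReLU
#' layers; and a 1x1 convolution + sigmoid head.
#'
#' @param inputSize (rows, cols); both must be divisible by 16 (four
#'   pooling stages).
#' @param channelsPlan list of four integer vectors, the conv feature-map
#'   counts per encoder block.
#' @param atrousRates strictly increasing positive dilation rates of the
#'   ASPP branches (default 2, 4, 6).
#' @param bottleneckChannels channels of each ASPP branch and of the fused
#'   bottleneck output (default: last encoder channel count).
#' @param dropout dropout rate applied to the bottleneck output during
#'   training (default 0.20).
#' @param useASPP replace the ASPP bottleneck by two plain 3x3 conv layers
#'   when FALSE (ablation variant).
#' @param useFPN insert the atrous feature-pyramid module on the skip
#'   paths (default FALSE; the plain skip connections are used).
#' @param fpnChannels channel width of the feature-pyramid laterals.
#' @return list of class `netConfig`.
#' @export
netConfig <- function(inputSize = c(64L, 64L),
                      channelsPlan = list(c(32L, 32L, 64L),
                                          c(64L, 64L, 128L),
                                          c(128L, 128L, 256L),
                                          c(256L, 256L, 256L)),
                      atrousRates = c(2L, 4L, 6L),
                      bottleneckChannels = NULL,
                      dropout = 0.20, useASPP = TRUE, useFPN = FALSE,
                      fpnChannels = 64L) {
  if (any(inputSize %% 16L != 0))
    stop("input rows and cols must be divisible by 16 (four pooling stages)")
  if (length(channelsPlan) != 4L)
    stop("channelsPlan must list four encoder blocks")
  if (any(diff(atrousRates) <= 0) || any(atrousRates < 1))
    stop("atrous rates must be strictly increasing positive integers")
  if (is.null(bottleneckChannels))
    bottleneckChannels <- tail(channelsPlan[[4]], 1)
  out <- list(inputSize = as.integer(inputSize),
              channelsPlan = lapply(channelsPlan, as.integer),
              atrousRates = as.integer(atrousRates),
              bottleneckChannels = as.integer(bottleneckChannels),
              dropout = dropout, useASPP = isTRUE(useASPP),
              useFPN = isTRUE(useFPN), fpnChannels = as.integer(fpnChannels))
  class(out) <- "netConfig"
  out
}

#' Training configuration
#'
#' Full-scale defaults follow the published settings (batch 12, 120
#' epochs, learning rate 0.01, dropout 0.20, pixelwise L2 loss); the
#' desk-scale runs used in tests pass smaller values explicitly. The
#' optimizer is stochastic gradient descent with momentum; the "L2" loss is
#' the pixelwise mean squared error between the sigmoid output and the
#' binary mask, with optional weight decay as the alternative reading.
#'
#' @param batchSize minibatch size (default 12).
#' @param epochs training epochs (default 120).
#' @param learningRate SGD learning rate (default 0.01).
#' @param momentum SGD momentum (default 0.9).
#' @param weightDecay optional L2 penalty on conv weights (default 0).
#' @param gradClip global gradient-norm clip (default 5).
#' @param valFraction held-out fraction when no explicit validation set is
#'   given (default 0.2).
#' @param bnMomentum running-statistics update rate (default 0.1).
#' @param seed one seed governing initialization order, shuffling and
#'   dropout.
#' @return list of class `trainConfig`.
#' @export
trainConfig <- function(batchSize = 12L, epochs = 120L, learningRate = 0.01,
                        momentum = 0.9, weightDecay = 0, gradClip = 5,
                        valFraction = 0.2, bnMomentum = 0.1, seed = 1L) {
  stopifnot(batchSize >= 1, epochs >= 1, learningRate > 0)
  out <- list(batchSize = as.integer(batchSize), epochs = as.integer(epochs),
              learningRate = learningRate, momentum = momentum,
              weightDecay = weightDecay, gradClip = gradClip,
              valFraction = valFraction, bnMomentum = bnMomentum,
              seed = as.integer(seed))
  class(out) <- "trainConfig"
  out
}

# ---- graph construction ----------------------------------------------------

.newGraphEnv <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- list(); e$params <- list(); e$bnStats <- list()
  e$channels <- integer(0); e$nConv <- 0L; e$nBN <- 0L
  e
}

.addNode <- function(e, op, inputs = integer(0), param = NA_character_,
                     attrs = list(), channels = NA_integer_) {
  # force arguments before reading the graph: nested .add* calls in the
  # arguments append nodes themselves
  inputs <- as.integer(inputs)
  force(channels)
  id <- length(e$nodes) + 1L
  e$nodes[[id]] <- list(id = id, op = op, inputs = as.integer(inputs),
                        param = param, attrs = attrs)
  e$channels[id] <- if (is.na(channels) && length(inputs))
    e$channels[inputs[1]] else channels
  id
}

.addConv <- function(e, input, cout, k = 3L, dilation = 1L) {
  force(input)
  cin <- e$channels[input]
  e$nConv <- e$nConv + 1L
  name <- sprintf("conv%03d", e$nConv)
  fanIn <- k * k * cin
  W <- array(rnorm(k * k * cin * cout, 0, sqrt(2 / fanIn)),
             c(k, k, cin, cout))
  e$params[[name]] <- list(W = W, b = numeric(cout))
  .addNode(e, "conv", input, param = name,
           attrs = list(k = k, dilation = as.integer(dilation)),
           channels = as.integer(cout))
}

.addBN <- function(e, input) {
  force(input)
  cc <- e$channels[input]
  e$nBN <- e$nBN + 1L
  name <- sprintf("bn%03d", e$nBN)
  e$params[[name]] <- list(gamma = rep(1, cc), beta = numeric(cc))
  e$bnStats[[name]] <- list(mean = numeric(cc), var = rep(1, cc))
  .addNode(e, "bn", input, param = name, channels = cc)
}

.addConvBNReLU <- function(e, input, cout, k = 3L, dilation = 1L) {
  .addNode(e, "relu", .addBN(e, .addConv(e, input, cout, k, dilation)))
}

.addConcat <- function(e, inputs) {
  force(inputs)
  .addNode(e, "concat", inputs,
           channels = sum(e$channels[inputs]))
}

# ASPP: parallel 1x1 conv, dilated 3x3 convs at the given rates, and an
# image-pooling branch (global average pool -> 1x1 conv -> broadcast),
# fused by a 1x1 convolution.
.addASPP <- function(e, input, cout, rates, mapSize) {
  branches <- c(
    .addConvBNReLU(e, input, cout, k = 1L),
    vapply(rates, function(r)
      .addConvBNReLU(e, input, cout, k = 3L, dilation = r), integer(1)))
  gap <- .addNode(e, "gap", input)
  gc <- .addConvBNReLU(e, gap, cout, k = 1L)
  bc <- .addNode(e, "broadcast", gc,
                 attrs = list(h = mapSize[1], w = mapSize[2]))
  cat_ <- .addConcat(e, c(branches, bc))
  .addConvBNReLU(e, cat_, cout, k = 1L)
}

#' Build the segmentation model
#'
#' Constructs the layer graph and He-initialized parameters for the
#' encoder-decoder network described by a [netConfig()]: four encoder
#' blocks (three conv-BN-ReLU layers each, skip copy before 2x2 max
#' pooling), a bottleneck ASPP (dilated 3x3 branches at the configured
#' rates plus an image-pooling branch, fused by a 1x1 convolution) with
#' dropout, four decoder blocks (bilinear upsample + 3x3 conv, skip
#' concatenation, two conv-BN-ReLU layers), and a 1x1 convolution +
#' sigmoid head.
#'
#' @param config a [netConfig()].
#' @param seed integer seed for weight initialization.
#' @return an untrained [SpineSegModel-class].
#' @export
buildModel <- function(config = netConfig(), seed = 1L) {
  stopifnot(inherits(config, "netConfig"))
  .withSeed(seed, {
    e <- .newGraphEnv()
    input <- .addNode(e, "input", channels = 1L)
    size <- config$inputSize
    cur <- input
    skips <- integer(4); skipSizes <- vector("list", 4)
    for (b in 1:4) {
      for (cc in config$channelsPlan[[b]])
        cur <- .addConvBNReLU(e, cur, cc)
      skips[b] <- cur; skipSizes[[b]] <- size
      cur <- .addNode(e, "maxpool", cur)
      size <- size %/% 2L
    }
    cb <- config$bottleneckChannels
    if (config$useASPP) {
      cur <- .addASPP(e, cur, cb, config$atrousRates, size)
    } else {
      cur <- .addConvBNReLU(e, cur, cb)
      cur <- .addConvBNReLU(e, cur, cb)
    }
    cur <- .addNode(e, "dropout", cur, attrs = list(rate = config$dropout))
    if (config$useFPN)
      skips <- .addFPNSubgraph(e, skips, skipSizes, config)
    for (b in 4:1) {
      cd <- tail(config$channelsPlan[[b]], 1)
      cur <- .addNode(e, "upsample", cur)
      cur <- .addConvBNReLU(e, cur, cd)          # post-upsample 3x3 conv
      cur <- .addConcat(e, c(cur, skips[b]))
      cur <- .addConvBNReLU(e, cur, cd)
      cur <- .addConvBNReLU(e, cur, cd)
    }
    head <- .addConv(e, cur, 1L, k = 1L)
    out <- .addNode(e, "sigmoid", head)
    stopifnot(out == length(e$nodes))
    new("SpineSegModel", graph = e$nodes, params = e$params,
        bnStats = e$bnStats, config = unclass(config), trained = FALSE,
        history = data.frame())
  })
}

# Atrous feature-pyramid subgraph over the four skip maps: 1x1 laterals,
# atrous modules (dilated 3x3 branches + image pooling, 1x1 fusion),
# top-down summation with extra edges joining the highest- and
# lowest-resolution levels, and an independent final 3x3 conv per level.
.addFPNSubgraph <- function(e, skips, skipSizes, config) {
  fc <- config$fpnChannels
  lat <- vapply(skips, function(s) .addConv(e, s, fc, k = 1L), integer(1))
  am <- vapply(1:4, function(b)
    .addASPP(e, lat[b], fc, config$atrousRates, skipSizes[[b]]), integer(1))
  fused <- integer(4)
  fused[4] <- am[4]
  for (b in 3:1) {
    up <- .addNode(e, "upsample", fused[b + 1])
    fused[b] <- .addNode(e, "add", c(am[b], up))
  }
  # extra edges between the extreme levels (F1 <-> F4), via 1x1 convs
  up8 <- fused[4]
  for (i in 1:3) up8 <- .addNode(e, "upsample", up8)
  fused[1] <- .addNode(e, "add",
                       c(fused[1], .addConv(e, up8, fc, k = 1L)))
  down8 <- .addNode(e, "avgpool", lat[1], attrs = list(factor = 8L))
  fused[4] <- .addNode(e, "add",
                       c(fused[4], .addConv(e, down8, fc, k = 1L)))
  vapply(1:4, function(b) .addConv(e, fused[b], fc, k = 3L), integer(1))
}

#' Build a standalone atrous feature-pyramid module
#'
#' The skip-path feature pyramid as its own model: four inputs (the encoder
#' skip maps, highest resolution first, halving each level), 1x1 lateral
#' convolutions, atrous modules at the configured rates, top-down fusion
#' with extra edges between the extreme levels, and an independent 3x3
#' convolution per fused map. Apply with [fpnForward()].
#'
#' @param inChannels integer(4), channels of the four input maps.
#' @param mapSize (rows, cols) of the highest-resolution map.
#' @param fpnChannels lateral width.
#' @param atrousRates dilation rates of the atrous modules.
#' @param seed initialization seed.
#' @return a [SpineSegModel-class] holding just the pyramid subgraph.
#' @export
buildAtrousFPN <- function(inChannels, mapSize, fpnChannels = 64L,
                           atrousRates = c(2L, 4L, 6L), seed = 1L) {
  if (length(inChannels) != 4L)
    stop("the feature pyramid takes exactly four input maps")
  cfg <- list(fpnChannels = as.integer(fpnChannels),
              atrousRates = as.integer(atrousRates))
  .withSeed(seed, {
    e <- .newGraphEnv()
    ins <- vapply(1:4, function(b)
      .addNode(e, "input", channels = as.integer(inChannels[b])),
      integer(1))
    sizes <- lapply(0:3, function(k) as.integer(mapSize %/% 2L^k))
    outs <- .addFPNSubgraph(e, ins, sizes,
                            list(fpnChannels = cfg$fpnChannels,
                                 atrousRates = cfg$atrousRates))
    new("SpineSegModel", graph = e$nodes, params = e$params,
        bnStats = e$bnStats,
        config = c(cfg, list(inputs = ins, outputs = outs)),
        trained = FALSE, history = data.frame())
  })
}

#' Layer description of a model
#'
#' @param model a [SpineSegModel-class].
#' @return data.frame with one row per graph node: id, op, channels (for
#'   conv nodes, the output feature maps), kernel and dilation.
#' @export
modelDescription <- function(model) {
  rows <- lapply(model@graph, function(nd) {
    k <- if (!is.null(nd$attrs$k)) nd$attrs$k else NA_integer_
    d <- if (!is.null(nd$attrs$dilation)) nd$attrs$dilation else NA_integer_
    cc <- if (nd$op == "conv") dim(model@params[[nd$param]]$W)[4]
          else NA_integer_
    data.frame(id = nd$id, op = nd$op, channels = cc, kernel = k,
               dilation = d)
  })
  do.call(rbind, rows)
}

#' Total number of trainable parameters
#'
#' @param model a [SpineSegModel-class].
#' @return integer count.
#' @export
modelParameterCount <- function(model) {
  sum(vapply(model@params, function(p)
    sum(vapply(p, length, integer(1))), integer(1)))
}
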