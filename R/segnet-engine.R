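# Forward/backward evaluation of the layer graph, SGD training, and
# inference helpers.

.concatChannels <- function(xs) {
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[3]
    out[, , (at + 1L):(at + cc), ] <- x
    at <- at + cc
  }
  out
}

.gapForward <- function(x) {
  d <- dim(x)
  m <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
  array(m, c(1L, 1L, d[3], d[4]))
}

.broadcastForward <- function(x, h, w) {
  d <- dim(x)
  out <- array(0, c(h, w, d[3], d[4]))
  out[] <- rep(as.vector(x), each = h * w)
  out
}

.avgPoolForward <- function(x, f) {
  d <- dim(x)
  ho <- d[1] %/% f; wo <- d[2] %/% f
  out <- array(0, c(ho, wo, d[3], d[4]))
  for (i in 1:f) for (j in 1:f)
    out <- out + x[seq(i, by = f, length.out = ho),
                   seq(j, by = f, length.out = wo), , , drop = FALSE]
  out / (f * f)
}

.avgPoolBackward <- function(dy, f, H, W) {
  d <- dim(dy)
  dx <- array(0, c(H, W, d[3], d[4]))
  g <- dy / (f * f)
  for (i in 1:f) for (j in 1:f)
    dx[seq(i, by = f, length.out = d[1]),
       seq(j, by = f, length.out = d[2]), , ] <- g
  dx
}

# Forward pass. `inputs` is a single (H, W, C, N) array, or a list of them
# for multi-input graphs (the standalone feature pyramid). Returns the
# activation list, a cache for the backward pass, and (when training)
# updated running batch-norm statistics.
.graphForward <- function(model, inputs, training = FALSE,
                          bnMomentum = 0.1) {
  nodes <- model@graph; params <- model@params; bnStats <- model@bnStats
  if (!is.list(inputs)) inputs <- list(inputs)
  acts <- vector("list", length(nodes))
  cache <- vector("list", length(nodes))
  nextInput <- 1L
  for (nd in nodes) {
    a <- if (length(nd$inputs)) acts[[nd$inputs[1]]]
    acts[[nd$id]] <- switch(nd$op,
      input = {
        x <- inputs[[nextInput]]; nextInput <- nextInput + 1L; x
      },
      conv = .conv2dForward(a, params[[nd$param]]$W,
                            params[[nd$param]]$b, nd$attrs$dilation),
      bn = {
        st <- bnStats[[nd$param]]
        r <- .bnForward(a, params[[nd$param]]$gamma,
                        params[[nd$param]]$beta, st$mean, st$var,
                        1e-5, training)
        cache[[nd$id]] <- list(mean = r$mean, invStd = r$invStd,
                               batch = training)
        if (training) {
          bnStats[[nd$param]]$mean <-
            (1 - bnMomentum) * st$mean + bnMomentum * r$mean
          bnStats[[nd$param]]$var <-
            (1 - bnMomentum) * st$var + bnMomentum * r$var
        }
        r$y
      },
      relu = pmax(a, 0),
      sigmoid = 1 / (1 + exp(-a)),
      maxpool = {
        r <- .maxPoolForward(a)
        cache[[nd$id]] <- list(idx = r$idx, H = dim(a)[1], W = dim(a)[2])
        r$y
      },
      upsample = .upsample2Forward(a),
      avgpool = {
        cache[[nd$id]] <- list(H = dim(a)[1], W = dim(a)[2])
        .avgPoolForward(a, nd$attrs$factor)
      },
      gap = .gapForward(a),
      broadcast = .broadcastForward(a, nd$attrs$h, nd$attrs$w),
      concat = .concatChannels(acts[nd$inputs]),
      add = acts[[nd$inputs[1]]] + acts[[nd$inputs[2]]],
      dropout = {
        if (training && nd$attrs$rate > 0) {
          mask <- array((runif(length(a)) >= nd$attrs$rate) /
                          (1 - nd$attrs$rate), dim(a))
          cache[[nd$id]] <- list(mask = mask)
          a * mask
        } else a
      },
      stop("unknown op: ", nd$op))
  }
  list(acts = acts, cache = cache, bnStats = bnStats)
}

# Backward pass from gradients at the given output nodes; returns the
# parameter-gradient list and the gradients at the input nodes.
.graphBackward <- function(model, fw, outGrads) {
  nodes <- model@graph; params <- model@params
  acts <- fw$acts; cache <- fw$cache
  grads <- vector("list", length(nodes))
  for (nm in names(outGrads)) {
    id <- as.integer(nm)
    grads[[id]] <- outGrads[[nm]]
  }
  pgrads <- list()
  addGrad <- function(id, g) {
    if (is.null(grads[[id]])) grads[[id]] <<- g
    else grads[[id]] <<- grads[[id]] + g
  }
  for (nd in rev(nodes)) {
    dy <- grads[[nd$id]]
    if (is.null(dy)) next
    a <- if (length(nd$inputs)) acts[[nd$inputs[1]]]
    switch(nd$op,
      input = NULL,
      conv = {
        r <- .conv2dBackward(a, params[[nd$param]]$W, dy, nd$attrs$dilation)
        pg <- pgrads[[nd$param]]
        if (is.null(pg)) pgrads[[nd$param]] <- list(W = r$dw, b = r$db)
        else pgrads[[nd$param]] <- list(W = pg$W + r$dw, b = pg$b + r$db)
        addGrad(nd$inputs[1], r$dx)
      },
      bn = {
        cc <- cache[[nd$id]]
        r <- .bnBackward(dy, a, params[[nd$param]]$gamma, cc$mean,
                         cc$invStd, cc$batch)
        pg <- pgrads[[nd$param]]
        if (is.null(pg))
          pgrads[[nd$param]] <- list(gamma = r$dgamma, beta = r$dbeta)
        else pgrads[[nd$param]] <- list(gamma = pg$gamma + r$dgamma,
                                        beta = pg$beta + r$dbeta)
        addGrad(nd$inputs[1], r$dx)
      },
      relu = addGrad(nd$inputs[1], dy * (a > 0)),
      sigmoid = {
        y <- acts[[nd$id]]
        addGrad(nd$inputs[1], dy * y * (1 - y))
      },
      maxpool = {
        cc <- cache[[nd$id]]
        addGrad(nd$inputs[1], .maxPoolBackward(dy, cc$idx, cc$H, cc$W))
      },
      upsample = addGrad(nd$inputs[1], .upsample2Backward(dy)),
      avgpool = {
        cc <- cache[[nd$id]]
        addGrad(nd$inputs[1],
                .avgPoolBackward(dy, nd$attrs$factor, cc$H, cc$W))
      },
      gap = {
        d <- dim(a)
        addGrad(nd$inputs[1],
                .broadcastForward(dy, d[1], d[2]) / (d[1] * d[2]))
      },
      broadcast = {
        d <- dim(dy)
        s <- colSums(matrix(dy, d[1] * d[2], d[3] * d[4]))
        addGrad(nd$inputs[1], array(s, c(1L, 1L, d[3], d[4])))
      },
      concat = {
        at <- 0L
        for (inp in nd$inputs) {
          cc <- dim(acts[[inp]])[3]
          addGrad(inp, dy[, , (at + 1L):(at + cc), , drop = FALSE])
          at <- at + cc
        }
      },
      add = {
        addGrad(nd$inputs[1], dy)
        addGrad(nd$inputs[2], dy)
      },
      dropout = {
        cc <- cache[[nd$id]]
        addGrad(nd$inputs[1], if (is.null(cc)) dy else dy * cc$mask)
      })
  }
  inputIds <- vapply(Filter(function(nd) nd$op == "input", nodes),
                     `[[`, integer(1), "id")
  list(pgrads = pgrads, inputGrads = grads[inputIds])
}

.asBatch <- function(images) {
  # images: list of matrices -> (H, W, 1, N)
  d <- dim(images[[1]])
  out <- array(0, c(d[1], d[2], 1L, length(images)))
  for (i in seq_along(images)) out[, , 1, i] <- images[[i]]
  out
}

.normalizeImage <- function(m) {
  if (max(m) > 1.5) m / 255 else m
}

.asCase <- function(x) {
  if (is(x, "SpinePhantom"))
    list(image = phantomImage(x), mask = phantomMask(x))
  else x
}

#' Raw forward pass of a model
#'
#' Evaluates the network on a batch of images (eval-mode batch
#' normalization, no dropout) and returns the per-pixel foreground
#' probabilities. Mostly a diagnostic entry point; see [segmentImage()]
#' for end-use inference.
#'
#' @param model a [SpineSegModel-class] built by [buildModel()].
#' @param images a matrix, a (H, W, 1, N) array, or a list of matrices;
#'   intensities either 0-255 or already in \[0, 1\].
#' @return (H, W, N) array of probabilities in (0, 1).
#' @export
netForward <- function(model, images) {
  if (is.matrix(images)) images <- list(images)
  x <- if (is.list(images)) .asBatch(lapply(images, .normalizeImage))
       else images
  fw <- .graphForward(model, x, training = FALSE)
  out <- fw$acts[[length(model@graph)]]
  array(out, dim(out)[c(1, 2, 4)])
}

#' Forward pass of a standalone feature-pyramid module
#'
#' @param fpn a model from [buildAtrousFPN()].
#' @param feats list of four (H, W, C, N) arrays, highest resolution
#'   first, spatial size halving per level.
#' @return list of four fused (H, W, fpnChannels, N) arrays matching the
#'   lateral sizes.
#' @export
fpnForward <- function(fpn, feats) {
  if (length(feats) != 4L) stop("the feature pyramid takes four maps")
  fw <- .graphForward(fpn, feats, training = FALSE)
  lapply(fpn@config$outputs, function(id) fw$acts[[id]])
}

# ---- training --------------------------------------------------------------

.flattenGradNorm <- function(pgrads) {
  sq <- 0
  for (p in pgrads) for (g in p) sq <- sq + sum(g * g)
  sqrt(sq)
}

#' Train the segmentation model
#'
#' Minimizes the pixelwise mean squared error between the sigmoid output
#' and the binary mask by SGD with momentum, gradient-norm clipping and
#' optional weight decay. Deterministic for a fixed `config$seed` (one
#' seed drives shuffling and dropout). History records per-epoch training
#' loss and, when a validation set exists, validation loss and Dice at
#' threshold 0.5.
#'
#' @param model an untrained (or previously trained) [SpineSegModel-class].
#' @param dataset list of cases (`list(image, mask)` or
#'   [SpinePhantom-class]); images must match the model's input size.
#' @param config a [trainConfig()].
#' @param valData optional explicit validation cases; if NULL,
#'   `config$valFraction` of the dataset is held out (seeded split).
#' @param verbose print per-epoch progress.
#' @return the trained model, with `trainingHistory()` filled in.
#' @export
trainModel <- function(model, dataset, config = trainConfig(),
                       valData = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "trainConfig"))
  dataset <- lapply(dataset, .asCase)
  insz <- model@config$inputSize
  for (cs in dataset) {
    if (!identical(dim(cs$image), dim(cs$mask)))
      stop("image/mask shape mismatch in the training data")
    if (!is.null(insz) && !identical(dim(cs$image), as.integer(insz)))
      stop("training images must match the model input size")
  }
  .withSeed(config$seed, {
    if (is.null(valData) && config$valFraction > 0 && length(dataset) > 1) {
      nVal <- max(1L, floor(config$valFraction * length(dataset)))
      vi <- sample(length(dataset), nVal)
      valData <- dataset[vi]
      dataset <- dataset[-vi]
    } else if (!is.null(valData)) {
      valData <- lapply(valData, .asCase)
    }
    vel <- list()
    history <- list()
    n <- length(dataset)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batchSize)
      epochLoss <- 0; nb <- 0L
      for (s in starts) {
        sel <- ord[s:min(s + config$batchSize - 1L, n)]
        x <- .asBatch(lapply(dataset[sel],
                             function(cs) .normalizeImage(cs$image)))
        y <- .asBatch(lapply(dataset[sel],
                             function(cs) (cs$mask != 0) * 1))
        st <- .trainStep(model, x, y, vel, config)
        model <- st$model; vel <- st$vel
        epochLoss <- epochLoss + st$loss; nb <- nb + 1L
      }
      row <- data.frame(epoch = epoch, trainLoss = epochLoss / nb,
                        valLoss = NA_real_, valDice = NA_real_)
      if (!is.null(valData) && length(valData)) {
        vm <- .evalCases(model, valData)
        row$valLoss <- vm["loss"]; row$valDice <- vm["dice"]
      }
      history[[epoch]] <- row
      if (verbose)
        message(sprintf("epoch %d: loss %.4f val Dice %.3f", epoch,
                        row$trainLoss, row$valDice))
    }
    model@history <- do.call(rbind, history)
    model@trained <- TRUE
    model
  })
}

# One SGD step; returns the updated model, velocity and batch loss.
.trainStep <- function(model, x, y, vel, config) {
  fw <- .graphForward(model, x, training = TRUE,
                      bnMomentum = config$bnMomentum)
  model@bnStats <- fw$bnStats
  outId <- length(model@graph)
  pred <- fw$acts[[outId]]
  diff <- pred - y
  loss <- mean(diff * diff)
  dOut <- 2 * diff / length(diff)
  bw <- .graphBackward(model, fw, setNames(list(dOut), outId))
  pg <- bw$pgrads
  if (config$weightDecay > 0)
    for (nm in names(pg))
      if (!is.null(pg[[nm]]$W))
        pg[[nm]]$W <- pg[[nm]]$W + config$weightDecay * model@params[[nm]]$W
  if (config$gradClip > 0) {
    gn <- .flattenGradNorm(pg)
    if (is.finite(gn) && gn > config$gradClip) {
      sc <- config$gradClip / gn
      for (nm in names(pg))
        pg[[nm]] <- lapply(pg[[nm]], function(g) g * sc)
    }
  }
  for (nm in names(pg)) {
    for (f in names(pg[[nm]])) {
      v <- vel[[nm]][[f]]
      if (is.null(v)) v <- 0
      v <- config$momentum * v - config$learningRate * pg[[nm]][[f]]
      if (is.null(vel[[nm]])) vel[[nm]] <- list()
      vel[[nm]][[f]] <- v
      model@params[[nm]][[f]] <- model@params[[nm]][[f]] + v
    }
  }
  list(model = model, vel = vel, loss = loss)
}

.evalCases <- function(model, cases, threshold = 0.5) {
  losses <- dices <- numeric(length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    p <- netForward(model, .normalizeImage(cs$image))[, , 1]
    m <- (cs$mask != 0) * 1
    losses[i] <- mean((p - m)^2)
    dices[i] <- maskDice(m, p >= threshold)
  }
  c(loss = mean(losses), dice = mean(dices))
}

#' Segment an image with a trained model
#'
#' Normalizes intensities to \[0, 1\], reflect-pads the image to a
#' multiple of 16 if needed, runs one forward pass, and thresholds the
#' probability map; connected components of the thresholded mask are
#' relabelled in top-to-bottom order.
#'
#' @param model a trained [SpineSegModel-class].
#' @param image numeric matrix.
#' @param threshold foreground probability threshold (default 0.5; pixels
#'   with `prob >= threshold` are foreground).
#' @param requireTrained error on an untrained model (default TRUE).
#' @return list with `prob` (probability matrix) and `mask` (integer label
#'   matrix, components ordered top to bottom).
#' @export
segmentImage <- function(model, image, threshold = 0.5,
                         requireTrained = TRUE) {
  if (requireTrained && !model@trained)
    stop("model has not been trained; pass requireTrained = FALSE to force")
  m <- .normalizeImage(image)
  nr <- nrow(m); nc <- ncol(m)
  pr <- (-nr) %% 16L; pc <- (-nc) %% 16L
  if (pr > 0 || pc > 0) {
    padded <- matrix(0, nr + pr, nc + pc)
    padded[seq_len(nr), seq_len(nc)] <- m
    if (pr > 0) padded[nr + seq_len(pr), seq_len(nc)] <-
      m[nr:(nr - pr + 1L), , drop = FALSE]
    if (pc > 0) padded[, nc + seq_len(pc)] <-
      padded[, nc:(nc - pc + 1L), drop = FALSE]
    m <- padded
  }
  if (!identical(dim(m), as.integer(model@config$inputSize)))
    stop("image size incompatible with the model input size")
  prob <- netForward(model, m)[, , 1][seq_len(nr), seq_len(nc), drop = FALSE]
  bin <- prob >= threshold
  lab <- if (any(bin)) .labelComponents(bin) else matrix(0L, nr, nc)
  if (max(lab) > 1L) {
    # relabel components top to bottom by centroid row
    ctr <- vapply(seq_len(max(lab)), function(k)
      mean((which(lab == k) - 1L) %% nrow(lab) + 1L), numeric(1))
    remap <- integer(max(lab)); remap[order(ctr)] <- seq_len(max(lab))
    lab <- matrix(c(0L, remap)[lab + 1L], nr, nc)
  }
  list(prob = prob, mask = lab)
}

#' Gradient-footprint receptive-field probe
#'
#' Measures the effective receptive field at the output center pixel: one
#' eval-mode forward/backward pass on a random input, returning the
#' maximal Chebyshev distance from the center of any input pixel with a
#' nonzero gradient. Used to verify that the ASPP bottleneck widens the
#' receptive field relative to the plain variant at equal depth.
#'
#' @param model a [SpineSegModel-class].
#' @param seed seed for the random probe input.
#' @return integer radius in px.
#' @export
receptiveFieldProbe <- function(model, seed = 1L) {
  insz <- model@config$inputSize
  x <- .withSeed(seed, array(runif(prod(insz)), c(insz[1], insz[2], 1L, 1L)))
  fw <- .graphForward(model, x, training = FALSE)
  outId <- length(model@graph)
  dOut <- array(0, dim(fw$acts[[outId]]))
  ctr <- insz %/% 2L
  dOut[ctr[1], ctr[2], 1, 1] <- 1
  bw <- .graphBackward(model, fw, setNames(list(dOut), outId))
  g <- abs(bw$inputGrads[[1]][, , 1, 1])
  hit <- which(g > 1e-12, arr.ind = TRUE)
  if (!nrow(hit)) return(0L)
  as.integer(max(pmax(abs(hit[, 1] - ctr[1]), abs(hit[, 2] - ctr[2]))))
}
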