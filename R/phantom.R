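# Synthetic anterior-posterior spine phantoms: a stack of bright
# rounded-corner rectangles (vertebrae) along a curved center line separated
# by darker disc gaps, over a noisy darker background. Every downstream
# stage of the pipeline can be exercised on these with pixel-exact masks and
# a known, constructed Cobb angle.

#' Specification of a synthetic spine phantom
#'
#' Geometry, intensity and degradation settings for [generatePhantom()].
#' Defaults draw a 17-vertebra thoracic + lumbar stack (TH01-TH12,
#' LU01-LU05) on a 1024 x 384 px canvas with 96 x 44 px vertebral bodies,
#' matching the scale of a cropped AP spine radiograph (where a vertebra
#' typically spans well over a hundred pixels); at much coarser scales the
#' +/-0.5 px rasterization noise of the mask starts to dominate endplate
#' angle estimates.
#'
#' @param imageHeight,imageWidth canvas size in px.
#' @param nVertebrae number of vertebrae (default 17).
#' @param vertebraHeight,vertebraWidth vertebra body size in px.
#' @param discGap inter-vertebra gap in px (rendered at background
#'   intensity).
#' @param centerlineModel one of `"straight"`, `"single-arc"`, `"s-curve"`.
#' @param amplitude lateral center-line amplitude in px.
#' @param phase phase offset (radians) for the s-curve model.
#' @param targetCobb requested Cobb angle in degrees, in \[0, 90); realized
#'   by tilting the extreme vertebrae symmetrically (cosine taper), on top
#'   of the local center-line tangent. The ground truth records the
#'   *realized* angle.
#' @param foregroundIntensity,backgroundIntensity 8-bit gray levels
#'   (bone bright, per AP radiograph convention).
#' @param lateralFalloff fraction of the foreground-background contrast
#'   lost at the lateral vertebra edges (default 0.3): AP radiographs are
#'   densest along the spine midline (vertebral body plus spinous
#'   process), dimming toward the lateral cortices. Gives the intensity
#'   ridge that center-line tracking keys on.
#' @param noiseSigma additive Gaussian noise std-dev (gray levels).
#' @param blurSigma Gaussian blur std-dev (px) applied before the noise.
#' @param seed integer; all randomness in the phantom flows through one
#'   seeded generator per call.
#' @return a validated list of class `phantomSpec`.
#' @export
phantomSpec <- function(imageHeight = 1024L, imageWidth = 384L,
                        nVertebrae = 17L, vertebraHeight = 44L,
                        vertebraWidth = 96L, discGap = 14L,
                        centerlineModel = c("s-curve", "single-arc", "straight"),
                        amplitude = 40, phase = 0, targetCobb = 20,
                        foregroundIntensity = 200, backgroundIntensity = 40,
                        lateralFalloff = 0.3,
                        noiseSigma = 5, blurSigma = 1.2, seed = 1L) {
  centerlineModel <- match.arg(centerlineModel)
  spec <- list(imageHeight = as.integer(imageHeight),
               imageWidth = as.integer(imageWidth),
               nVertebrae = as.integer(nVertebrae),
               vertebraHeight = as.integer(vertebraHeight),
               vertebraWidth = as.integer(vertebraWidth),
               discGap = as.integer(discGap),
               centerlineModel = centerlineModel,
               amplitude = amplitude, phase = phase,
               targetCobb = targetCobb,
               foregroundIntensity = foregroundIntensity,
               backgroundIntensity = backgroundIntensity,
               lateralFalloff = lateralFalloff,
               noiseSigma = noiseSigma, blurSigma = blurSigma,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(imageHeight >= 1, imageWidth >= 1, nVertebrae >= 1,
              vertebraHeight >= 1, vertebraWidth >= 1, discGap >= 0,
              noiseSigma >= 0, blurSigma >= 0)
    if (foregroundIntensity <= backgroundIntensity)
      stop("foregroundIntensity must exceed backgroundIntensity")
    if (targetCobb < 0 || targetCobb >= 90)
      stop("targetCobb must lie in [0, 90)")
    if (lateralFalloff < 0 || lateralFalloff >= 1)
      stop("lateralFalloff must lie in [0, 1)")
    if (nVertebrae * (vertebraHeight + discGap) > imageHeight)
      stop("infeasible packing: vertebrae do not fit the image height")
  })
  class(spec) <- "phantomSpec"
  spec
}

# Center-line column as a function of row, plus its derivative d(col)/d(row).
.centerlineFun <- function(spec, topRow, span) {
  c0 <- spec$imageWidth / 2
  A <- spec$amplitude
  switch(spec$centerlineModel,
    "straight" = list(
      col = function(r) rep(c0, length(r)),
      dcol = function(r) rep(0, length(r))),
    "single-arc" = list(
      col = function(r) c0 + A * sin(pi * (r - topRow) / span),
      dcol = function(r) A * cos(pi * (r - topRow) / span) * pi / span),
    "s-curve" = list(
      col = function(r) c0 + A * sin(2 * pi * (r - topRow) / span + spec$phase),
      dcol = function(r) A * cos(2 * pi * (r - topRow) / span + spec$phase) *
        2 * pi / span))
}

# Paint a rounded-corner rectangle centered at (r0, c0), rotated by theta
# (degrees; positive = clockwise tilt of the vertebra's horizontal axis in
# image coordinates with y down), into a logical matrix.
.paintVertebra <- function(nr, nc, r0, c0, halfW, halfH, thetaDeg, corner) {
  th <- thetaDeg * pi / 180
  reach <- ceiling(sqrt(halfW^2 + halfH^2)) + 1L
  rows <- max(1L, floor(r0 - reach)):min(nr, ceiling(r0 + reach))
  cols <- max(1L, floor(c0 - reach)):min(nc, ceiling(c0 + reach))
  rr <- matrix(rows - r0, length(rows), length(cols))
  cc <- matrix(cols - c0, length(rows), length(cols), byrow = TRUE)
  # u along the vertebra's horizontal axis, v along its vertical axis
  u <- cc * cos(th) + rr * sin(th)
  v <- -cc * sin(th) + rr * cos(th)
  du <- pmax(abs(u) - (halfW - corner), 0)
  dv <- pmax(abs(v) - (halfH - corner), 0)
  inside <- (du * du + dv * dv) <= corner * corner &
    abs(u) <= halfW & abs(v) <= halfH
  list(rows = rows, cols = cols, inside = inside, u = u)
}

#' Generate a synthetic spine phantom
#'
#' Renders the vertebra stack described by a [phantomSpec()], applies
#' Gaussian blur and additive Gaussian noise, and returns the image, the
#' pixel-exact label mask, and the geometric ground truth. The per-vertebra
#' tilt is the local center-line tangent plus a cosine taper that puts
#' +target/2 on the topmost and -target/2 on the bottommost vertebra; the
#' whole tilt profile is then rescaled so that the *realized* maximal
#' endplate angle equals the requested one, and the realized value (from the
#' same pairwise angle formula used by [cobbAngle()]) is stored as truth.
#'
#' @param spec a [phantomSpec()].
#' @return a [SpinePhantom-class].
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  nr <- spec$imageHeight; nc <- spec$imageWidth
  n <- spec$nVertebrae
  vh <- spec$vertebraHeight; vw <- spec$vertebraWidth; gap <- spec$discGap
  span <- n * vh + (n - 1L) * gap
  topRow <- floor((nr - span) / 2) + 1L
  cl <- .centerlineFun(spec, topRow, span)
  # space centers by arc length along the center line, so the perpendicular
  # disc gap is preserved where the curve runs oblique
  rGrid <- seq(topRow, nr, by = 0.25)
  ds <- sqrt(1 + cl$dcol(rGrid)^2) * 0.25
  sCum <- c(0, cumsum(ds[-length(ds)]))
  sTargets <- vh / 2 + (seq_len(n) - 1L) * (vh + gap)
  if (max(sCum) < sTargets[n])
    stop("infeasible packing: vertebrae do not fit along the center line")
  centerRows <- approx(sCum, rGrid, xout = sTargets)$y
  centerCols <- cl$col(centerRows)

  # tilt profile: center-line tangent + symmetric extreme tilt, rescaled so
  # the realized spread equals the requested Cobb angle
  # a vertebra sits perpendicular to the spine curve: its endplate tilts
  # opposite to the center line's lateral drift (slope -dcol/drow). A
  # cosine taper (+ at the top, - at the bottom) is added on top, with its
  # weight s solved so that the realized tilt spread (= the Cobb angle of
  # the stack) equals the request; among the two solutions of the convex
  # spread equation, the tilt profile closest to the perpendicular
  # alignment is kept, so vertebrae stay clear of their neighbours.
  perp <- -atan(cl$dcol(centerRows)) * 180 / pi
  taper <- if (n > 1) cos(pi * (seq_len(n) - 1L) / (n - 1L)) else 0
  target <- spec$targetCobb
  if (target == 0 || n == 1) {
    theta <- rep(0, n)
  } else {
    spreadAt <- function(s) {
      th <- perp + s * (target / 2) * taper
      max(th) - min(th)
    }
    lim <- 8
    opt <- optimize(spreadAt, c(-lim, lim))
    if (opt$objective > target) {
      # curvature alone exceeds the request: damp the whole profile
      th <- perp + (target / 2) * taper
      theta <- th * (target / (max(th) - min(th)))
    } else {
      cand <- list()
      if (spreadAt(lim) >= target)
        cand <- c(cand, uniroot(function(s) spreadAt(s) - target,
                                c(opt$minimum, lim))$root)
      if (spreadAt(-lim) >= target)
        cand <- c(cand, uniroot(function(s) spreadAt(s) - target,
                                c(-lim, opt$minimum))$root)
      thetas <- lapply(cand, function(s) perp + s * (target / 2) * taper)
      dev <- vapply(thetas, function(th) max(abs(th - perp)), numeric(1))
      theta <- thetas[[which.min(dev)]]
    }
  }

  corner <- max(1, min(3, vh / 4))
  fg <- spec$foregroundIntensity; bg <- spec$backgroundIntensity
  render <- function(theta) {
    mask <- matrix(0L, nr, nc)
    clean <- matrix(bg, nr, nc)
    for (k in seq_len(n)) {
      pv <- .paintVertebra(nr, nc, centerRows[k], centerCols[k],
                           vw / 2, vh / 2, theta[k], corner)
      sub <- mask[pv$rows, pv$cols, drop = FALSE]
      paint <- pv$inside & sub == 0L
      sub[paint] <- k
      mask[pv$rows, pv$cols] <- sub
      # radiographic density profile: brightest at the midline, dimming
      # toward the lateral cortices
      csub <- clean[pv$rows, pv$cols, drop = FALSE]
      shade <- fg - (fg - bg) * spec$lateralFalloff * (pv$u / (vw / 2))^2
      csub[paint] <- shade[paint]
      clean[pv$rows, pv$cols] <- csub
    }
    list(mask = mask, clean = clean,
         ok = max(.labelComponents(mask > 0)) == n)
  }
  # a cramped stack (small gaps, strong tilt) can fuse neighbouring
  # vertebrae when rasterized; damp the tilt profile toward (and then
  # past) the perpendicular alignment until the bodies render distinct.
  # The ground truth records the realized angle, not the request.
  rd <- render(theta)
  tries <- 0L
  while (!rd$ok && tries < 20L) {
    tries <- tries + 1L
    theta <- if (tries <= 10L) perp + 0.8 * (theta - perp) else 0.8 * theta
    rd <- render(theta)
  }
  if (!rd$ok)
    stop("infeasible packing: vertebrae overlap or are split after rendering")
  mask <- rd$mask; clean <- rd$clean
  image <- .withSeed(spec$seed, {
    out <- .gaussBlur(clean, spec$blurSigma)
    if (spec$noiseSigma > 0)
      out <- out + matrix(rnorm(nr * nc, 0, spec$noiseSigma), nr, nc)
    .clip(out, 0, 255)
  })

  slopes <- tan(theta * pi / 180)
  labels <- .vertebraLabels(n)
  truth <- data.frame(label = labels, centerRow = centerRows,
                      centerCol = centerCols, orientationDeg = theta,
                      upperSlope = slopes, lowerSlope = slopes,
                      stringsAsFactors = FALSE)
  if (n >= 2) {
    best <- .maxPairAngle(slopes, slopes)
    trueCobb <- best$angle
    trueUp <- labels[best$i]; trueLo <- labels[best$j]
  } else {
    trueCobb <- 0; trueUp <- labels[1]; trueLo <- labels[1]
  }
  ccoef <- .polyFit(centerRows, centerCols, min(4L, n - 1L))
  new("SpinePhantom", image = image, mask = mask, truth = truth,
      trueCobb = trueCobb, trueUpper = trueUp, trueLower = trueLo,
      centerCoefficients = ccoef, spec = unclass(spec))
}

#' Degrade an image with blur and additive Gaussian noise
#'
#' With both sigmas zero the input is returned unchanged (bit-identical);
#' output is clipped to \[0, 255\]. Deterministic for a fixed seed.
#'
#' @param image numeric matrix, 0-255 scale.
#' @param noiseSigma std-dev of additive Gaussian noise (gray levels).
#' @param blurSigma Gaussian blur std-dev in px (applied before the noise).
#' @param seed integer RNG seed.
#' @return numeric matrix of the same size.
#' @export
degradeImage <- function(image, noiseSigma, blurSigma, seed = 1L) {
  stopifnot(noiseSigma >= 0, blurSigma >= 0)
  if (noiseSigma == 0 && blurSigma == 0) return(image)
  .withSeed(seed, {
    out <- .gaussBlur(image, blurSigma)
    if (noiseSigma > 0)
      out <- out + matrix(rnorm(length(image), 0, noiseSigma),
                          nrow(image), ncol(image))
    .clip(out, 0, 255)
  })
}

#' Generate a set of small random phantoms for desk-scale training
#'
#' Draws `n` phantoms on a square canvas with randomized curvature (Cobb
#' angle uniform on `cobbRange`), centerline model, amplitude and noise,
#' sized so that several vertebrae fit a small network input. Used as the
#' training substrate for [trainModel()] and for cross-validation tests.
#'
#' @param n number of phantoms.
#' @param size canvas side in px (default 64).
#' @param cobbRange degrees, range of requested Cobb angles.
#' @param noiseSigma noise level passed to each phantom.
#' @param seed integer; phantom k uses seed `seed + k`.
#' @return list of [SpinePhantom-class] objects.
#' @export
phantomTrainingSet <- function(n, size = 64L, cobbRange = c(0, 45),
                               noiseSigma = 8, seed = 1L) {
  lapply(seq_len(n), function(k) {
    pars <- .withSeed(seed + k, list(
      cobb = runif(1, cobbRange[1], cobbRange[2]),
      model = sample(c("straight", "single-arc", "s-curve"), 1),
      amp = runif(1, 1.5, 4),
      phase = runif(1, 0, pi)))
    generatePhantom(phantomSpec(
      imageHeight = size, imageWidth = size, nVertebrae = 4L,
      vertebraHeight = 8L, vertebraWidth = 20L, discGap = 5L,
      centerlineModel = pars$model, amplitude = pars$amp,
      phase = pars$phase, targetCobb = pars$cobb,
      noiseSigma = noiseSigma, blurSigma = 0.7, seed = seed + k))
  })
}
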