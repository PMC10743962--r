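# Shared internal helpers: polynomial fits, seeded RNG scoping, box-filter
# local statistics with reflect padding, Otsu thresholding, component
# labelling (EBImage), and separable Gaussian blur.

.polyEval <- function(coefs, x) {
  y <- rep(coefs[1], length(x))
  xp <- rep(1, length(x))
  for (k in seq_along(coefs)[-1]) {
    xp <- xp * x
    y <- y + coefs[k] * xp
  }
  y
}

.polyDerivEval <- function(coefs, x) {
  if (length(coefs) < 2L) return(rep(0, length(x)))
  .polyEval(coefs[-1] * seq_len(length(coefs) - 1L), x)
}

.polyFit <- function(x, y, degree) {
  degree <- min(degree, length(unique(x)) - 1L)
  X <- outer(x, 0:degree, `^`)
  as.numeric(qr.solve(X, y, tol = 1e-12))
}

# Run expr with a fixed RNG seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Reflect-pad a matrix by (pr, pc) on each side (edge pixels not repeated,
# matching the usual "symmetric" convention about the pixel centers).
.reflectPad <- function(m, pr, pc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(pr, nr - 1)) + 1L), seq_len(nr),
          nr - seq_len(min(pr, nr - 1)))
  if (pr >= nr) ri <- pmin(pmax(ri, 1L), nr)  # degenerate tiny images
  ci <- c(rev(seq_len(min(pc, nc - 1)) + 1L), seq_len(nc),
          nc - seq_len(min(pc, nc - 1)))
  m[ri, ci, drop = FALSE]
}

# Local mean and mean-of-squares over an odd window, reflect padding,
# computed with integral images; returns matrices the size of m.
.localStats <- function(m, window) {
  wr <- window[1]; wc <- window[2]
  stopifnot(wr %% 2 == 1, wc %% 2 == 1)
  if (wr > nrow(m) || wc > ncol(m))
    stop("window larger than image")
  pr <- (wr - 1L) / 2L; pc <- (wc - 1L) / 2L
  boxSum <- function(p) {
    s <- apply(p, 2, cumsum)
    s <- rbind(0, s)
    s <- s[(1 + wr):nrow(s), , drop = FALSE] - s[1:(nrow(s) - wr), , drop = FALSE]
    s <- t(apply(s, 1, cumsum))
    s <- cbind(0, s)
    s[, (1 + wc):ncol(s), drop = FALSE] - s[, 1:(ncol(s) - wc), drop = FALSE]
  }
  p <- .reflectPad(m, pr, pc)
  n <- wr * wc
  mu <- boxSum(p) / n
  mu2 <- boxSum(p * p) / n
  list(mean = mu, var = pmax(mu2 - mu * mu, 0))
}

# Otsu threshold on a numeric matrix (any range).
.otsuThreshold <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) stop("cannot threshold a constant image")
  x <- (m - rng[1]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(t(x)), range = c(0, 1))
  rng[1] + t01 * diff(rng)
}

# Connected-component labelling of a logical/0-1 matrix via EBImage::bwlabel.
# EBImage stores images as (x, y) = (col, row), hence the transposes.
.labelComponents <- function(binary) {
  lab <- EBImage::bwlabel(EBImage::Image(t(binary * 1)))
  t(EBImage::imageData(lab))
}

# Separable Gaussian blur with reflect padding; sigma in px, radius 3*sigma.
.gaussBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(( -r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  p <- .reflectPad(m, r, r)
  conv1 <- function(mat, along) {
    # convolve rows (along = 1) or cols (along = 2) with kernel k, valid part
    if (along == 2) mat <- t(mat)
    out <- matrix(0, nrow(mat) - 2 * r, ncol(mat))
    for (i in seq_along(k))
      out <- out + k[i] * mat[i:(i + nrow(out) - 1L), , drop = FALSE]
    if (along == 2) t(out) else out
  }
  res <- conv1(conv1(p, 1), 2)
  res[, , drop = FALSE]
}

.clip <- function(m, lo, hi) pmin(pmax(m, lo), hi)

# Anatomical labels for an n-vertebra stack: the full thoracic + lumbar set
# when n = 17, otherwise generic ordinals.
.vertebraLabels <- function(n) {
  if (n == 17L)
    c(sprintf("TH%02d", 1:12), sprintf("LU%02d", 1:5))
  else sprintf("V%02d", seq_len(n))
}
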