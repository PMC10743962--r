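# Radiograph enhancement: weighted-channel grayscale standardization and an
# adaptive (local-statistics) spatial Wiener filter, plus image-quality
# scoring with a pixel-domain visual-information-fidelity (VIF)
# approximation and Pearson / Spearman score correlations.

#' Weighted-channel grayscale conversion
#'
#' Collapses an RGB radiograph to one channel with weights red 0.21,
#' green 0.59, blue 0.20 (weights sum to 1.00, so the output range equals
#' the input range; no renormalization is applied). Single-channel input
#' passes through unchanged.
#'
#' @param image numeric matrix (passed through) or (row, col, 3) array.
#' @return numeric matrix.
#' @export
toWeightedGray <- function(image) {
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) != 3L || !(d[3] %in% c(1L, 3L)))
    stop("image must have 1 or 3 channels")
  if (d[3] == 1L) return(image[, , 1])
  0.21 * image[, , 1] + 0.59 * image[, , 2] + 0.20 * image[, , 3]
}

#' Estimate the noise variance of an image
#'
#' Classic adaptive-Wiener convention: the mean of the local variances over
#' all pixels (local statistics over an odd window with reflect padding).
#' A constant image gives 0.
#'
#' @param image numeric matrix.
#' @param window odd window size, scalar or (rows, cols); default 3x3.
#' @return nonnegative scalar variance estimate.
#' @export
estimateNoiseVariance <- function(image, window = c(3L, 3L)) {
  if (length(window) == 1L) window <- c(window, window)
  mean(.localStats(image, window)$var)
}

#' Adaptive spatial Wiener filter
#'
#' At each pixel the output is the local mean plus the observed deviation
#' shrunk by the estimated local signal-to-noise ratio:
#' `out = m + s2 / (s2 + nv) * (z - m)` with `m` the local mean, `s2 =
#' max(0, localVar - nv)` the estimated signal variance and `nv` the noise
#' variance. Where `s2 + nv = 0` the output is the local mean. Local
#' statistics use an odd window (default 3x3) with reflect padding, so the
#' output has the input's shape; `nv` defaults to the mean local variance
#' ([estimateNoiseVariance()]).
#'
#' @param image numeric matrix.
#' @param window odd window size, scalar or (rows, cols); default 3x3.
#' @param noiseVariance optional nonnegative noise variance; estimated from
#'   the image when missing.
#' @return filtered numeric matrix, same shape as the input.
#' @export
wienerFilter <- function(image, window = c(3L, 3L), noiseVariance = NULL) {
  if (length(window) == 1L) window <- c(window, window)
  ls <- .localStats(image, window)
  nv <- if (is.null(noiseVariance)) mean(ls$var) else noiseVariance
  stopifnot(nv >= 0)
  s2 <- pmax(ls$var - nv, 0)
  denom <- s2 + nv
  gain <- ifelse(denom > 0, s2 / denom, 0)
  ls$mean + gain * (image - ls$mean)
}

#' Visual-information-fidelity score (pixel-domain approximation)
#'
#' Single-scale pixel-domain VIF over sliding 3x3 blocks with scalar
#' Gaussian-scale-mixture mutual-information terms: the ratio of summed
#' block-wise information in (reference, processed) over (reference,
#' reference through the noise channel), clamped to \[0, 1\]. An identical
#' processed image scores exactly 1; increasing degradation lowers the
#' score. This is an approximation of the full wavelet-domain metric.
#'
#' @param reference,processed numeric matrices of the same shape; the
#'   reference must not be constant.
#' @param window odd local-statistics window (default 3).
#' @param sigmaN visual-noise variance of the model (default 2, on the
#'   0-255 intensity scale).
#' @return scalar in \[0, 1\].
#' @export
vifScore <- function(reference, processed, window = 3L, sigmaN = 2) {
  if (!identical(dim(reference), dim(processed)))
    stop("reference and processed images must have the same shape")
  if (diff(range(reference)) == 0)
    stop("reference image is constant; VIF undefined")
  if (length(window) == 1L) window <- c(window, window)
  eps <- 1e-10
  lr <- .localStats(reference, window)
  lp <- .localStats(processed, window)
  # local covariance via the same box filter
  lc <- .localStats(reference + processed, window)$var
  covRP <- (lc - lr$var - lp$var) / 2
  g <- ifelse(lr$var > eps, covRP / lr$var, 0)
  sv2 <- pmax(lp$var - g * covRP, 0)
  num <- sum(log2(1 + g^2 * lr$var / (sv2 + sigmaN)))
  den <- sum(log2(1 + lr$var / sigmaN))
  .clip(num / den, 0, 1)
}

#' Pearson and Spearman correlation of two score sequences
#'
#' @param scoresA,scoresB numeric vectors of equal length >= 3, neither
#'   constant.
#' @return named numeric vector `c(cc = ..., srocc = ...)`: the Pearson
#'   correlation and the Pearson correlation of the rank vectors (average
#'   ranks on ties).
#' @export
ccSrocc <- function(scoresA, scoresB) {
  if (length(scoresA) != length(scoresB))
    stop("score sequences must have equal length")
  if (length(scoresA) < 3L)
    stop("need at least 3 paired scores")
  if (sd(scoresA) == 0 || sd(scoresB) == 0)
    stop("correlation undefined for constant sequences")
  c(cc = cor(scoresA, scoresB),
    srocc = cor(rank(scoresA, ties.method = "average"),
                rank(scoresB, ties.method = "average")))
}
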