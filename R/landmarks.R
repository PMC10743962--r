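# Spine landmarking: projection-based ROI crop, sliding-window center-line
# detection with a polynomial fit, lateral boundary detection from paired
# window intensity differences, and vertebra identification from summed
# zero-indicator projection histograms along four sampling lines.

#' Parameters for center-line and boundary detection
#'
#' @param W,H sliding-window width and height in px (defaults 12 and 52).
#' @param q maximal lateral displacement (px) of the window center between
#'   consecutive rows during the descent (default 12).
#' @param r reference-point thinning: every r-th descent row is kept as a
#'   reference point for the polynomial fit (default 5).
#' @param x,p auxiliary tuning constants carried for completeness
#'   (defaults 36 and 11); they take no part in the procedures here.
#' @param boundaryWindow (width, height) of the paired edge-search windows
#'   (default 12 x 5).
#' @param polyDegree polynomial degree for the center-line fit (default 4;
#'   the lateral boundary fits are always degree 4).
#' @return list of class `centerLineParams`.
#' @export
centerLineParams <- function(W = 12L, H = 52L, q = 12L, r = 5L,
                             x = 36L, p = 11L,
                             boundaryWindow = c(12L, 5L), polyDegree = 4L) {
  out <- list(W = as.integer(W), H = as.integer(H), q = as.integer(q),
              r = as.integer(r), x = as.integer(x), p = as.integer(p),
              boundaryWindow = as.integer(boundaryWindow),
              polyDegree = as.integer(polyDegree))
  stopifnot(out$W >= 1, out$H >= 1, out$q >= 1, out$r >= 1,
            all(out$boundaryWindow >= 1), out$polyDegree >= 1)
  class(out) <- "centerLineParams"
  out
}

#' Crop the spine region of interest
#'
#' With an explicit box, returns that exact sub-image. Without one, the
#' image is Otsu-thresholded, the foreground row/column projections define
#' the tight extent, and the crop is padded by 10 percent of the extent on each
#' side (clamped to the image). The returned offset maps cropped
#' coordinates back to the original frame:
#' `original = cropped + offset - 1`.
#'
#' @param image numeric matrix.
#' @param box optional integer vector `c(top, bottom, left, right)`
#'   (1-based, inclusive).
#' @param padFrac padding fraction per side for the automatic crop.
#' @return list with `image` (the crop) and `offset` (`c(row, col)` of the
#'   crop's top-left pixel in the original, 1-based).
#' @export
cropSpineROI <- function(image, box = NULL, padFrac = 0.1) {
  if (!is.null(box)) {
    stopifnot(length(box) == 4, box[1] <= box[2], box[3] <= box[4])
    return(list(image = image[box[1]:box[2], box[3]:box[4], drop = FALSE],
                offset = c(row = as.integer(box[1]), col = as.integer(box[3]))))
  }
  if (diff(range(image)) == 0)
    stop("blank image: cannot locate a spine without an explicit box")
  fg <- image > .otsuThreshold(image)
  if (!any(fg)) stop("no foreground after thresholding")
  rows <- range(which(rowSums(fg) > 0))
  cols <- range(which(colSums(fg) > 0))
  padR <- ceiling(padFrac * (rows[2] - rows[1] + 1))
  padC <- ceiling(padFrac * (cols[2] - cols[1] + 1))
  r1 <- max(1L, rows[1] - padR); r2 <- min(nrow(image), rows[2] + padR)
  c1 <- max(1L, cols[1] - padC); c2 <- min(ncol(image), cols[2] + padC)
  list(image = image[r1:r2, c1:c2, drop = FALSE],
       offset = c(row = as.integer(r1), col = as.integer(c1)))
}

#' Detect the spine center line
#'
#' Slides a W x H window horizontally in 1-px steps across the top of the
#' image and seats the first reference point at the center of the
#' maximum-sum window (ties: leftmost). The window then descends one pixel
#' at a time, re-centering on the maximum-sum window within lateral
#' distance `q` of the previous center; every `r`-th visited center is kept
#' as a reference point, and a polynomial of column on row (degree
#' `polyDegree`) is fitted through them.
#'
#' @param image numeric matrix (a cropped spine ROI).
#' @param params a [centerLineParams()].
#' @return a [CenterLine-class].
#' @export
detectCenterLine <- function(image, params = centerLineParams()) {
  if (diff(range(image)) == 0)
    stop("constant image: no intensity maximum to seat the center line")
  nr <- nrow(image); nc <- ncol(image)
  W <- min(params$W, nc); H <- min(params$H, nr)
  # integral image for O(1) window sums
  ii <- rbind(0, apply(image, 2, cumsum))
  ii <- cbind(0, t(apply(ii, 1, cumsum)))
  wsum <- function(r1, c1) # window with top-left (r1, c1), size H x W
    ii[r1 + H, c1 + W] - ii[r1, c1 + W] - ii[r1 + H, c1] + ii[r1, c1]
  halfW <- (W - 1) %/% 2
  topSums <- vapply(1:(nc - W + 1L), function(c1) wsum(1L, c1), numeric(1))
  c1 <- which.max(topSums)                      # leftmost max by which.max
  centers <- integer(0); rows <- integer(0)
  ctr <- c1 + halfW
  lastTop <- nr - H + 1L
  for (rTop in 1:lastTop) {
    if (rTop > 1L) {
      lo <- max(1L, ctr - halfW - params$q)
      hi <- min(nc - W + 1L, ctr - halfW + params$q)
      cand <- lo:hi
      s <- vapply(cand, function(cc) wsum(rTop, cc), numeric(1))
      ctr <- cand[which.max(s)] + halfW
    }
    centers <- c(centers, ctr)
    rows <- c(rows, rTop + (H - 1L) %/% 2L)
  }
  keep <- unique(c(seq(1L, length(rows), by = params$r), length(rows)))
  coefs <- .polyFit(rows[keep], centers[keep], params$polyDegree)
  new("CenterLine", coefficients = coefs,
      rowRange = as.integer(range(rows)))
}

#' Detect the lateral spine boundaries
#'
#' At each row of the center line's validity interval, small window
#' sections (default 12 x 5 px) are paired and slid outward from the
#' center on each side; the boundary candidate is the midpoint maximizing
#' the intensity difference between the inner (bright, spine) and outer
#' (dark, background) windows. A degree-4 polynomial of column on row is
#' fitted per side; rows where the fits cross the center line are flagged
#' and clamped at evaluation time so that left < center < right always
#' holds.
#'
#' @param image numeric matrix (same frame as the center line).
#' @param center a [CenterLine-class].
#' @param params a [centerLineParams()].
#' @return a [BoundaryPair-class].
#' @export
detectLateralBoundaries <- function(image, center,
                                    params = centerLineParams()) {
  nr <- nrow(image); nc <- ncol(image)
  bw <- params$boundaryWindow[1]; bh <- params$boundaryWindow[2]
  hh <- (bh - 1L) %/% 2L
  rows <- seq(max(center@rowRange[1], 1 + hh),
              min(center@rowRange[2], nr - hh))
  ctr <- round(curveColumns(center, rows))
  leftPts <- rightPts <- matrix(numeric(0), 0, 3)
  for (k in seq_along(rows)) {
    r <- rows[k]
    strip <- image[(r - hh):(r + hh), , drop = FALSE]
    colMean <- colMeans(strip)
    cs <- c(0, cumsum(colMean))
    wmean <- function(a, b) (cs[b + 1] - cs[a]) / (b - a + 1)
    # left side: inner window right of midpoint m, outer window left of it
    mRange <- (bw + 1L):(ctr[k] - 1L)
    if (length(mRange) > 0 && ctr[k] + bw - 1L <= nc) {
      score <- vapply(mRange, function(m)
        wmean(m, min(m + bw - 1L, nc)) - wmean(m - bw, m - 1L), numeric(1))
      leftPts <- rbind(leftPts, c(r, mRange[which.max(score)], max(score)))
    }
    mRange <- (ctr[k] + 1L):(nc - bw)
    if (length(mRange) > 0 && mRange[1] <= mRange[length(mRange)] &&
        ctr[k] - bw + 1L >= 1) {
      score <- vapply(mRange, function(m)
        wmean(max(m - bw, 1L), m - 1L) - wmean(m, m + bw - 1L), numeric(1))
      rightPts <- rbind(rightPts, c(r, mRange[which.max(score)], max(score)))
    }
  }
  # rows whose best contrast is weak (the strip sits over a disc gap or
  # off the spine) carry no real edge; drop them before fitting
  keepStrong <- function(pts) {
    if (!nrow(pts)) return(pts)
    pts[pts[, 3] >= 0.5 * median(pts[, 3]), , drop = FALSE]
  }
  leftPts <- keepStrong(leftPts)
  rightPts <- keepStrong(rightPts)
  deg <- 4L
  if (nrow(leftPts) < deg + 1 || nrow(rightPts) < deg + 1)
    stop("too few valid edge points to fit the lateral boundaries")
  lc <- .polyFit(leftPts[, 1], leftPts[, 2], deg)
  rc <- .polyFit(rightPts[, 1], rightPts[, 2], deg)
  ctrAll <- curveColumns(center, rows)
  lv <- .polyEval(lc, rows); rv <- .polyEval(rc, rows)
  flagged <- rows[lv >= ctrAll | rv <= ctrAll]
  new("BoundaryPair", leftCoefficients = lc, rightCoefficients = rc,
      rowRange = as.integer(range(rows)), center = center,
      flaggedRows = as.integer(flagged))
}

#' Summed zero-indicator histogram of line projections
#'
#' For each projection line t, the indicator feature is
#' `f_t(h) = 1` where `p_t(h) = 0` and 0 otherwise; the summed histogram
#' `S(h)` adds the indicators across lines. Bins where most lines are zero
#' (dark) mark inter-vertebral disc gaps.
#'
#' @param projections numeric matrix, one row per projection line, one
#'   column per bin (or a list of equal-length numeric vectors).
#' @return list with `projections`, `indicator` (0/1 matrix) and `summed`
#'   (numeric vector, `0 <= S <= nrow`).
#' @export
summedHistogram <- function(projections) {
  if (is.list(projections)) {
    len <- unique(lengths(projections))
    if (length(len) != 1) stop("projection lines must have equal length")
    projections <- do.call(rbind, projections)
  }
  if (!is.matrix(projections) || nrow(projections) < 1 ||
      ncol(projections) < 1)
    stop("need at least one non-empty projection line")
  ind <- (projections == 0) * 1L
  list(projections = projections, indicator = ind, summed = colSums(ind))
}

#' Identify vertebra regions between the boundaries
#'
#' Samples intensities along four equally spaced vertical lines between the
#' lateral boundaries, zeroes sub-threshold (Otsu) values to isolate the
#' bright foreground, and builds the summed zero-indicator histogram over
#' rows ([summedHistogram()]). Reference points are placed at significant
#' ascending shifts of S (a rise of at least half the maximal row-to-row
#' increase, with non-maximum suppression within `minVertebraHeight` rows);
#' each cut row is then refined to the darkest row (maximal S) within an
#' 18-row non-overlapping bin grid anchored at the lower spine boundary.
#' Rows between consecutive cuts become vertebra ROIs, ordered top to
#' bottom, labelled TH01..LU05 when exactly 17 remain.
#'
#' @param image numeric matrix (same frame as the boundaries).
#' @param boundaries a [BoundaryPair-class].
#' @param minVertebraHeight suppression window for nearby reference points
#'   (px, default 12).
#' @param shiftFrac ascending-shift significance threshold as a fraction of
#'   the maximal row-to-row increase of S (default 0.5).
#' @return data.frame with columns index, topRow, bottomRow, leftCol,
#'   rightCol, label.
#' @export
identifyVertebrae <- function(image, boundaries, minVertebraHeight = 12L,
                              shiftFrac = 0.5) {
  rows <- boundaries@rowRange[1]:boundaries@rowRange[2]
  bc <- curveColumns(boundaries, rows)
  thr <- .otsuThreshold(image)
  nLines <- 4L
  ctrCols <- curveColumns(boundaries@center, rows)
  dctr <- .polyDerivEval(boundaries@center@coefficients, rows)
  proj <- matrix(0, nLines, length(rows))
  for (t in seq_len(nLines)) {
    # four equally spaced lines across the central 40 percent of the
    # inter-boundary band: vertebra tilt displaces a disc gap by
    # (lateral offset) x tan(tilt) rows, so staying near the midline keeps
    # all lines inside the gap band even for strongly tilted vertebrae
    mid <- (bc[, "left"] + bc[, "right"]) / 2
    colT <- mid + (t / (nLines + 1) - 0.5) * 0.4 *
      (bc[, "right"] - bc[, "left"])
    colT <- .clip(round(colT), 1, ncol(image))
    v <- image[cbind(rows, colT)]
    pt <- ifelse(v > thr, v, 0)             # foreground-isolated projection
    # tilt correction: vertebrae sit perpendicular to the spine curve, so a
    # disc gap seen at lateral offset d from the midline is displaced by
    # about d * d(col)/d(row) rows; re-bin so gaps align across the lines
    rc <- rows + (colT - ctrCols) * dctr
    proj[t, ] <- approx(rc, pt, xout = rows, method = "constant",
                        rule = 2, ties = "ordered")$y
  }
  sh <- summedHistogram(proj)
  S <- sh$summed
  # ascending shifts over a short lag (the four lines enter a tilted disc
  # gap at slightly different rows, so the rise is spread over a few rows)
  lag <- max(3L, minVertebraHeight %/% 4L)
  d <- S[-(1:lag)] - S[seq_len(length(S) - lag)]
  if (max(d) <= 0)
    stop("no disc gaps detected: summed histogram has no ascending shift")
  cand <- which(d >= shiftFrac * max(d) &
                  S[seq_along(d) + lag] >= ceiling(0.75 * nLines))
  # non-maximum suppression: keep the strongest rise within each window
  cand <- cand[order(-d[cand], cand)]
  kept <- integer(0)
  for (cc in cand)
    if (!length(kept) || all(abs(kept - cc) >= minVertebraHeight))
      kept <- c(kept, cc)
  kept <- sort(kept)
  if (!length(kept)) stop("no disc gaps detected")
  # refinement: snap each cut to the darkest row (max S) within its 18-row
  # bin, binning anchored at the lower spine boundary
  nR <- length(S)
  binOf <- function(i) (nR - i) %/% 18L
  cuts <- vapply(kept, function(i) {
    win <- which(binOf(seq_len(nR)) == binOf(i))
    win <- win[win >= i & win < i + minVertebraHeight]
    if (!length(win)) return(i + 1L)
    win[which.max(S[win])]
  }, numeric(1))
  cuts <- sort(unique(round(cuts)))
  bright <- which(S < nLines)               # rows where any line is bright
  top <- min(bright); bottom <- max(bright)
  edges <- c(top, cuts[cuts > top & cuts < bottom], bottom + 1L)
  rois <- list()
  for (k in seq_len(length(edges) - 1L)) {
    rr <- edges[k]:(edges[k + 1L] - 1L)
    rr <- rr[S[rr] < nLines]                # drop pure-gap rows
    if (length(rr) < max(3L, minVertebraHeight %/% 2L)) next
    sel <- rows[range(rr)]
    bcc <- bc[rr[1]:rr[length(rr)], , drop = FALSE]
    rois[[length(rois) + 1L]] <- data.frame(
      topRow = sel[1], bottomRow = sel[2],
      leftCol = floor(min(bcc[, "left"])),
      rightCol = ceiling(max(bcc[, "right"])))
  }
  if (!length(rois)) stop("no vertebra regions found")
  out <- do.call(rbind, rois)
  out <- out[order(out$topRow), , drop = FALSE]
  out$index <- seq_len(nrow(out))
  out$label <- .vertebraLabels(nrow(out))
  rownames(out) <- NULL
  out[, c("index", "topRow", "bottomRow", "leftCol", "rightCol", "label")]
}
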