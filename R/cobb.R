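# Cobb-angle geometry: connected-component vertebra boxes (axis-aligned
# bounds + minimum-area oriented box), least-squares endplate slopes, the
# pairwise endplate angle, and severity classification.

# Angle (degrees) between two lines with slopes zi, zj (dy/dx, y down):
# |atan((zi - zj) / (1 + zi*zj))|, with the perpendicular case
# zi*zj = -1 defined as 90 degrees.
.slopeAngleDeg <- function(zi, zj) {
  denom <- 1 + zi * zj
  ifelse(abs(denom) < 1e-12, 90,
         abs(atan((zi - zj) / denom)) * 180 / pi)
}

# Maximal pairwise angle between upper slopes (i, above) and lower slopes
# (j, below); ties broken topmost pair first, then longest span.
.maxPairAngle <- function(upperSlopes, lowerSlopes) {
  n <- length(upperSlopes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  ang <- .slopeAngleDeg(upperSlopes[i], lowerSlopes[j])
  best <- which(ang >= max(ang) - 1e-9)
  best <- best[order(i[best], -(j[best] - i[best]))][1]
  list(angle = ang[best], i = i[best], j = j[best],
       table = data.frame(i = i, j = j, angle = ang))
}

# Minimum-area oriented bounding box of a point set (rotating calipers over
# the convex hull). Returns center, width/height, and the orientation (deg)
# of the box edge closest to horizontal, in (-45, 45].
.minAreaBox <- function(rows, cols) {
  pts <- unique(cbind(cols, rows))            # (x, y) with y down
  if (nrow(pts) == 1L)
    return(list(center = c(rows[1], cols[1]), width = 1, height = 1,
                orientation = 0))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  m <- nrow(hp)
  bestArea <- Inf; best <- NULL
  for (k in seq_len(m)) {
    e <- hp[k %% m + 1L, ] - hp[k, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    ex <- e / len; ey <- c(-ex[2], ex[1])
    u <- hp %*% ex; v <- hp %*% ey
    area <- (max(u) - min(u)) * (max(v) - min(v))
    if (area < bestArea - 1e-12) {
      bestArea <- area
      ctr <- (c(max(u) + min(u), max(v) + min(v)) / 2)
      best <- list(ex = ex, ey = ey,
                   du = max(u) - min(u), dv = max(v) - min(v),
                   cx = ctr[1] * ex[1] + ctr[2] * ey[1],
                   cy = ctr[1] * ex[2] + ctr[2] * ey[2])
    }
  }
  # orientation of whichever box axis is closest to horizontal
  angU <- atan2(best$ex[2], best$ex[1]) * 180 / pi
  angU <- ((angU + 90) %% 180) - 90         # into (-90, 90]
  if (abs(angU) <= 45) {
    orientation <- angU; width <- best$du; height <- best$dv
  } else {
    angV <- ((angU + 90 + 90) %% 180) - 90
    orientation <- angV; width <- best$dv; height <- best$du
  }
  list(center = c(best$cy, best$cx), width = width, height = height,
       orientation = orientation)
}

# Principal-axis orientation of a pixel set from second-order central
# moments (angle of the major axis from the column axis, degrees, positive
# = tilting down-right). Pools every pixel, so it is far more robust to
# rasterization (staircase) noise than an edge fit.
.momentOrientationDeg <- function(rows, cols) {
  mr <- mean(rows); mc <- mean(cols)
  muRC <- mean((rows - mr) * (cols - mc))
  muCC <- mean((cols - mc)^2); muRR <- mean((rows - mr)^2)
  0.5 * atan2(2 * muRC, muCC - muRR) * 180 / pi
}

# Least-squares endplate slopes of one component: a line through the
# per-column topmost pixels (upper endplate) and bottommost pixels (lower),
# restricted to the central fraction of the column extent so that the box
# corners (lateral edges) do not bias the fit.
.endplateSlopesFor <- function(rows, cols, centralFrac = 0.6) {
  cu <- sort(unique(cols))
  if (length(cu) < 2L)
    stop("degenerate single-column component; endplate slopes undefined")
  keep <- cu
  if (length(cu) >= 5L) {
    trim <- floor(length(cu) * (1 - centralFrac) / 2)
    keep <- cu[(1 + trim):(length(cu) - trim)]
  }
  top <- vapply(keep, function(cc) min(rows[cols == cc]), numeric(1))
  bot <- vapply(keep, function(cc) max(rows[cols == cc]), numeric(1))
  upper <- .polyFit(keep, top, 1L)[2]
  lower <- .polyFit(keep, bot, 1L)[2]
  c(upper = upper, lower = lower)
}

#' Extract oriented vertebra boxes from a label mask
#'
#' Labels the mask's connected components (unless already labeled), drops
#' components smaller than `minPixels`, and for each remaining component
#' records the axis-aligned bounds, the minimum-area oriented box with its
#' orientation, and the least-squares endplate slopes. Components are
#' ordered top to bottom by center row.
#'
#' @param mask numeric/integer/logical matrix; nonzero = foreground. An
#'   integer matrix with values > 1 is treated as already labeled.
#' @param minPixels minimum component size; default 0.1 percent of the image area
#'   (drops segmentation specks).
#' @param labels optional character vector of anatomical labels assigned in
#'   top-to-bottom order (defaults to TH01..LU05 when 17 components remain,
#'   generic ordinals otherwise).
#' @param slopeMethod `"moments"` (default) assigns both endplate slopes
#'   from the component's principal-axis orientation, which pools every
#'   pixel and is robust to the staircase noise of rasterized masks;
#'   `"edges"` fits each endplate separately by least squares on the edge
#'   pixels (use for wedge-shaped components whose endplates are not
#'   parallel).
#' @return a [VertebraBoxes-class].
#' @export
extractVertebraBoxes <- function(mask, minPixels = NULL, labels = NULL,
                                 slopeMethod = c("moments", "edges")) {
  slopeMethod <- match.arg(slopeMethod)
  if (all(mask == 0)) stop("empty mask: no foreground component")
  if (is.null(minPixels)) minPixels <- 0.001 * length(mask)
  lab <- if (max(mask) > 1) {
    storage.mode(mask) <- "integer"; mask
  } else .labelComponents(mask != 0)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  rec <- list()
  for (id in ids) {
    w <- which(lab == id)
    if (length(w) < minPixels) { lab[w] <- 0L; next }
    rows <- (w - 1L) %% nrow(lab) + 1L
    cols <- (w - 1L) %/% nrow(lab) + 1L
    ob <- .minAreaBox(rows, cols)
    sl <- if (slopeMethod == "moments") {
      z <- tan(.momentOrientationDeg(rows, cols) * pi / 180)
      c(upper = z, lower = z)
    } else .endplateSlopesFor(rows, cols)
    rec[[length(rec) + 1L]] <- data.frame(
      id = id, nPixels = length(w),
      minRow = min(rows), maxRow = max(rows),
      minCol = min(cols), maxCol = max(cols),
      centerRow = ob$center[1], centerCol = ob$center[2],
      boxWidth = ob$width, boxHeight = ob$height,
      orientationDeg = ob$orientation,
      upperSlope = sl["upper"], lowerSlope = sl["lower"])
  }
  if (!length(rec))
    stop("no component of at least minPixels pixels")
  boxes <- do.call(rbind, rec)
  rownames(boxes) <- NULL
  boxes <- boxes[order(boxes$centerRow), , drop = FALSE]
  boxes$label <- if (is.null(labels)) .vertebraLabels(nrow(boxes))
                 else labels[seq_len(nrow(boxes))]
  new("VertebraBoxes", boxes = boxes, labels = lab)
}

#' Endplate slopes of one vertebra component
#'
#' Least-squares line through the component's per-column topmost pixels
#' (upper endplate) and bottommost pixels (lower endplate), expressed as
#' dy/dx with y pointing down. The fit uses the central fraction of the
#' column extent so box corners do not bias it.
#'
#' @param boxes a [VertebraBoxes-class].
#' @param index ordinal index (top to bottom) of the vertebra.
#' @param centralFrac fraction of columns (centered) used in the fit.
#' @return named numeric `c(upper = ..., lower = ...)`.
#' @export
endplateSlopes <- function(boxes, index, centralFrac = 0.6) {
  stopifnot(is(boxes, "VertebraBoxes"))
  id <- boxTable(boxes)$id[index]
  w <- which(boxLabels(boxes) == id)
  rows <- (w - 1L) %% nrow(boxLabels(boxes)) + 1L
  cols <- (w - 1L) %/% nrow(boxLabels(boxes)) + 1L
  .endplateSlopesFor(rows, cols, centralFrac)
}

#' Cobb angle from a sequence of vertebra boxes
#'
#' For every ordered pair (i above j) the angle between the upper endplate
#' of i and the lower endplate of j is
#' `|atan((Zi - Zj) / (1 + Zi*Zj))|` in degrees, with the perpendicular
#' case `Zi*Zj = -1` defined as 90. The Cobb angle is the maximum over all
#' pairs (ties: topmost pair, then longest span); set `adjacentOnly = TRUE`
#' to restrict the search to neighbouring vertebrae.
#'
#' @param boxes a [VertebraBoxes-class] or a data.frame with columns
#'   `upperSlope`, `lowerSlope` and optionally `label`.
#' @param adjacentOnly restrict to pairs with j = i + 1.
#' @return a [CobbResult-class].
#' @export
cobbAngle <- function(boxes, adjacentOnly = FALSE) {
  tab <- if (is(boxes, "VertebraBoxes")) boxTable(boxes) else boxes
  if (nrow(tab) < 2L) stop("need at least 2 vertebra boxes")
  best <- .maxPairAngle(tab$upperSlope, tab$lowerSlope)
  pt <- best$table
  if (adjacentOnly) {
    pa <- pt[pt$j == pt$i + 1L, , drop = FALSE]
    k <- which(pa$angle >= max(pa$angle) - 1e-9)[1]
    best <- list(angle = pa$angle[k], i = pa$i[k], j = pa$j[k], table = pt)
  }
  labs <- if (!is.null(tab$label)) tab$label else .vertebraLabels(nrow(tab))
  ang <- min(best$angle, 90)
  new("CobbResult", angle = ang,
      upperIndex = as.integer(best$i), lowerIndex = as.integer(best$j),
      upperLabel = labs[best$i], lowerLabel = labs[best$j],
      pairTable = best$table, severity = classifySeverity(ang))
}

#' Severity class of a Cobb angle
#'
#' Standard Cobb-method categorization: \[0, 10) Normal, \[10, 20) Mild,
#' \[20, 40\] Moderate, (40, Inf) Severe. The overlapping printed interval
#' boundaries are resolved half-open on the left, with 40 assigned to
#' Moderate because Severe is strictly "> 40".
#'
#' @param angleDeg angle in degrees, nonnegative.
#' @return character scalar.
#' @export
classifySeverity <- function(angleDeg) {
  if (any(angleDeg < 0)) stop("angle must be nonnegative")
  ifelse(angleDeg < 10, "Normal",
    ifelse(angleDeg < 20, "Mild",
      ifelse(angleDeg <= 40, "Moderate", "Severe")))
}
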