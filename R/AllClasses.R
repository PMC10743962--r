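#' Polynomial spine center line
#'
#' A polynomial curve mapping image row to the column of the spine midline,
#' fitted to reference points found by sliding-window intensity maximization.
#' Coefficients are in increasing power order (intercept first).
#'
#' @slot coefficients numeric polynomial coefficients, increasing powers.
#' @slot rowRange integer length-2, first and last image row (1-based,
#'   inclusive) on which the fit is valid.
#' @export
setClass("CenterLine",
  representation(coefficients = "numeric", rowRange = "integer"),
  validity = function(object) {
    if (length(object@rowRange) != 2L || diff(object@rowRange) < 0)
      return("rowRange must be an increasing pair of rows")
    if (length(object@coefficients) < 1L || any(!is.finite(object@coefficients)))
      return("coefficients must be finite and non-empty")
    TRUE
  })

#' Lateral spine boundary pair
#'
#' Two degree-4 polynomials (row -> column) for the left and right lateral
#' boundaries of the spine, plus the rows where the raw edge search failed
#' and the boundary was clamped to stay on the correct side of the center
#' line.
#'
#' @slot leftCoefficients,rightCoefficients numeric polynomial coefficients,
#'   increasing powers.
#' @slot rowRange integer length-2 validity interval (rows, 1-based).
#' @slot center the [CenterLine-class] the pair was detected around.
#' @slot flaggedRows integer rows where left < center < right had to be
#'   enforced by clamping.
#' @export
setClass("BoundaryPair",
  representation(leftCoefficients = "numeric", rightCoefficients = "numeric",
                 rowRange = "integer", center = "CenterLine",
                 flaggedRows = "integer"))

#' Result of a Cobb-angle measurement
#'
#' Holds the maximal angle between the superior endplate of one vertebra and
#' the inferior endplate of a lower vertebra, the two reference vertebrae,
#' the full pairwise angle table, and the severity class.
#'
#' @slot angle numeric, the Cobb angle in degrees.
#' @slot upperIndex,lowerIndex integer ordinal indices (top to bottom) of the
#'   reference vertebrae; upperIndex < lowerIndex.
#' @slot upperLabel,lowerLabel character anatomical labels (e.g. "TH08"),
#'   possibly NA when no labelling was available.
#' @slot pairTable data.frame with columns i, j, angle for every ordered pair.
#' @slot severity character, one of Normal, Mild, Moderate, Severe.
#' @export
setClass("CobbResult",
  representation(angle = "numeric", upperIndex = "integer",
                 lowerIndex = "integer", upperLabel = "character",
                 lowerLabel = "character", pairTable = "data.frame",
                 severity = "character"),
  validity = function(object) {
    if (object@angle < 0 || object@angle > 90)
      return("angle must lie in [0, 90] degrees")
    if (object@upperIndex >= object@lowerIndex)
      return("upper reference vertebra must lie above the lower one")
    if (!identical(object@severity, classifySeverity(object@angle)))
      return("severity inconsistent with the angle")
    TRUE
  })

#' Synthetic spine phantom
#'
#' A rendered anterior-posterior spine phantom: a stack of bright rounded
#' rectangles (vertebrae) along a curved center line over a darker noisy
#' background, with its pixel-exact label mask and geometric ground truth.
#'
#' @slot image numeric matrix (rows x cols), intensities in \[0, 255\].
#' @slot mask integer matrix of per-pixel vertebra labels, 0 = background,
#'   k = k-th vertebra from the top.
#' @slot truth data.frame, one row per vertebra: label, centerRow, centerCol,
#'   orientationDeg, upperSlope, lowerSlope.
#' @slot trueCobb numeric, the realized Cobb angle in degrees.
#' @slot trueUpper,trueLower character labels of the reference vertebrae.
#' @slot centerCoefficients numeric coefficients of the generating center
#'   line (column as polynomial-free closed form is not stored; these are a
#'   least-squares polynomial summary used for landmark tests).
#' @slot spec list, the generating specification.
#' @export
setClass("SpinePhantom",
  representation(image = "matrix", mask = "matrix", truth = "data.frame",
                 trueCobb = "numeric", trueUpper = "character",
                 trueLower = "character", centerCoefficients = "numeric",
                 spec = "list"),
  validity = function(object) {
    if (!identical(dim(object@image), dim(object@mask)))
      return("image and mask dimensions differ")
    if (nrow(object@truth) != max(object@mask))
      return("ground-truth rows must match mask labels")
    if (is.unsorted(object@truth$centerRow))
      return("vertebra records must be ordered top to bottom")
    TRUE
  })

#' Oriented vertebra boxes extracted from a label mask
#'
#' One row per connected component kept after minimum-size filtering, with
#' axis-aligned bounds, the minimum-area oriented box, and least-squares
#' endplate slopes (dy/dx, y pointing down).
#'
#' @slot boxes data.frame with columns id, nPixels, minRow, maxRow, minCol,
#'   maxCol, centerRow, centerCol, boxWidth, boxHeight, orientationDeg,
#'   upperSlope, lowerSlope, label.
#' @slot labels integer matrix, the component labelling the boxes refer to.
#' @export
setClass("VertebraBoxes",
  representation(boxes = "data.frame", labels = "matrix"))

#' Encoder-decoder segmentation model
#'
#' A from-scratch convolutional encoder-decoder with skip connections and a
#' bottleneck atrous-spatial-pyramid-pooling block, represented as a layer
#' graph plus a flat parameter list. Train with [trainModel()], apply with
#' [segmentImage()].
#'
#' @slot graph list of node descriptions (op, inputs, parameter name, attrs).
#' @slot params named list of parameter arrays.
#' @slot bnStats named list of running batch-norm statistics.
#' @slot config list, the [netConfig()] used to build the model.
#' @slot trained logical.
#' @slot history data.frame of per-epoch losses and Dice (empty until
#'   trained).
#' @export
setClass("SpineSegModel",
  representation(graph = "list", params = "list", bnStats = "list",
                 config = "list", trained = "logical", history = "data.frame"))

setMethod("show", "CenterLine", function(object) {
  cat("CenterLine: degree", length(object@coefficients) - 1L,
      "fit over rows", object@rowRange[1], "-", object@rowRange[2], "\n")
})

setMethod("show", "BoundaryPair", function(object) {
  cat("BoundaryPair: degree-4 lateral fits over rows",
      object@rowRange[1], "-", object@rowRange[2])
  if (length(object@flaggedRows))
    cat(" (", length(object@flaggedRows), "rows clamped )")
  cat("\n")
})

setMethod("show", "CobbResult", function(object) {
  cat(sprintf("Cobb angle: %.1f deg (%s)\n", object@angle, object@severity))
  cat(sprintf("  reference vertebrae: %s (#%d) / %s (#%d)\n",
              object@upperLabel, object@upperIndex,
              object@lowerLabel, object@lowerIndex))
})

setMethod("show", "SpinePhantom", function(object) {
  cat(sprintf("SpinePhantom: %dx%d px, %d vertebrae, Cobb %.2f deg (%s-%s)\n",
              nrow(object@image), ncol(object@image), nrow(object@truth),
              object@trueCobb, object@trueUpper, object@trueLower))
})

setMethod("show", "VertebraBoxes", function(object) {
  cat("VertebraBoxes:", nrow(object@boxes), "components\n")
  if (nrow(object@boxes)) print(utils::head(object@boxes, 5))
})

setMethod("show", "SpineSegModel", function(object) {
  np <- sum(vapply(object@params, function(p)
    sum(vapply(p, length, integer(1))), integer(1)))
  cat(sprintf("SpineSegModel: %d nodes, %s parameters, %s\n",
              length(object@graph), format(np, big.mark = ","),
              if (object@trained) "trained" else "untrained"))
})

# ---- accessors ----

#' @describeIn CobbResult-class the angle in degrees
#' @param object a `CobbResult`
#' @export
cobbAngleDeg <- function(object) object@angle

#' @describeIn CobbResult-class the severity class
#' @export
severityClass <- function(object) object@severity

#' @describeIn CobbResult-class pairwise angle table (columns i, j, angle)
#' @export
anglePairs <- function(object) object@pairTable

#' @describeIn SpinePhantom-class the rendered image matrix
#' @param object a `SpinePhantom`
#' @export
phantomImage <- function(object) object@image

#' @describeIn SpinePhantom-class the label mask matrix
#' @export
phantomMask <- function(object) object@mask

#' @describeIn SpinePhantom-class the per-vertebra ground-truth table
#' @export
phantomTruth <- function(object) object@truth

#' @describeIn SpinePhantom-class the realized Cobb angle in degrees
#' @export
phantomCobb <- function(object) object@trueCobb

#' @describeIn VertebraBoxes-class the per-component box table
#' @param object a `VertebraBoxes`
#' @export
boxTable <- function(object) object@boxes

#' @describeIn VertebraBoxes-class the component label matrix
#' @export
boxLabels <- function(object) object@labels

#' @describeIn SpineSegModel-class per-epoch training history
#' @param object a `SpineSegModel`
#' @export
trainingHistory <- function(object) object@history

#' Evaluate a fitted curve at given rows
#'
#' @param object a [CenterLine-class] or [BoundaryPair-class]
#' @param rows integer rows (1-based)
#' @param ... unused
#' @return for a center line, a numeric vector of columns; for a boundary
#'   pair, a two-column matrix (left, right) clamped so that
#'   left < center < right.
#' @export
setGeneric("curveColumns", function(object, rows, ...)
  standardGeneric("curveColumns"))

#' @rdname curveColumns
#' @export
setMethod("curveColumns", "CenterLine", function(object, rows, ...) {
  .polyEval(object@coefficients, rows)
})

#' @rdname curveColumns
#' @export
setMethod("curveColumns", "BoundaryPair", function(object, rows, ...) {
  ctr <- curveColumns(object@center, rows)
  left <- .polyEval(object@leftCoefficients, rows)
  right <- .polyEval(object@rightCoefficients, rows)
  cbind(left = pmin(left, ctr - 1), right = pmax(right, ctr + 1))
})
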