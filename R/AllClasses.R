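#' @import methods
NULL

## Raster containers -------------------------------------------------------
##
## Pixel arrays are indexed [row = y, col = x, channel]; coordinates exposed
## to the user are 0-based with origin at the top-left corner, x = column,
## y = row, and every Rect is half-open on both axes.

#' RGBImage: an 8-bit three-channel raster
#'
#' The raw input of the pipeline: an integer array of dimension
#' \code{height x width x 3} with values in [0, 255] and channel order R, G, B
#' regardless of the source file's byte order.
#'
#' @slot pixels integer array \code{[y, x, channel]}, values in [0, 255].
#' @exportClass RGBImage
setClass("RGBImage", representation(pixels = "array"))

setValidity("RGBImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be a height x width x 3 array")
  if (dim(p)[1] < 1L || dim(p)[2] < 1L)
    return("image must be at least 1 x 1")
  if (anyNA(p) || min(p) < 0 || max(p) > 255)
    return("channel values must lie in [0, 255]")
  TRUE
})

#' NormalizedImage: per-channel reflectance estimates
#'
#' Result of the reference-patch normalization
#' \eqn{\eta = (I - Black)/(White - Black)}, clipped to [0, 1].
#'
#' @slot values numeric array \code{[y, x, channel]} in [0, 1].
#' @exportClass NormalizedImage
setClass("NormalizedImage", representation(values = "array"))

setValidity("NormalizedImage", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L || dim(v)[3] != 3L)
    return("values must be a height x width x 3 array")
  if (anyNA(v) || min(v) < 0 || max(v) > 1)
    return("normalized values must lie in [0, 1]")
  TRUE
})

#' BinaryMask: a two-valued segmentation raster
#'
#' @slot values logical matrix \code{[y, x]}; TRUE marks nail pixels.
#' @exportClass BinaryMask
setClass("BinaryMask", representation(values = "matrix"))

setValidity("BinaryMask", function(object) {
  v <- object@values
  if (!is.logical(v)) return("mask values must be logical")
  if (anyNA(v)) return("mask values must not contain NA")
  if (nrow(v) < 1L || ncol(v) < 1L) return("mask must be at least 1 x 1")
  TRUE
})

#' ProbabilityMask: per-pixel nail likelihood
#'
#' Intermediate between a segmentation backend and the threshold/morphology
#' post-processing; covers both soft CNN outputs loaded from file and the
#' hard 0/1 output of the classical baseline.
#'
#' @slot values numeric matrix \code{[y, x]} in [0, 1].
#' @exportClass ProbabilityMask
setClass("ProbabilityMask", representation(values = "matrix"))

setValidity("ProbabilityMask", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("probability values must be numeric")
  if (anyNA(v) || min(v) < 0 || max(v) > 1)
    return("probabilities must lie in [0, 1]")
  TRUE
})

## Geometry -----------------------------------------------------------------

#' Rect: an axis-aligned half-open rectangle
#'
#' 0-based, origin top-left; \code{[x0, x1)} by \code{[y0, y1)} so adjacent
#' rectangles tile without overlap.
#'
#' @slot x0,y0 top-left corner (inclusive).
#' @slot x1,y1 bottom-right corner (exclusive).
#' @exportClass Rect
setClass("Rect", representation(x0 = "integer", y0 = "integer",
                                x1 = "integer", y1 = "integer"))

setValidity("Rect", function(object) {
  if (object@x0 < 0L || object@y0 < 0L) return("corner must be non-negative")
  if (object@x1 <= object@x0 || object@y1 <= object@y0)
    return("rect must have positive width and height")
  TRUE
})

#' PatchLayout: reference-patch geometry
#'
#' Exactly four black reference squares flush to the image corners and three
#' white reference squares along the top band, centered at 25/50/75 percent
#' of the image width.
#'
#' @slot corners list of 4 \code{Rect} (black references).
#' @slot centrals list of 3 \code{Rect} (white references).
#' @slot patchSide side length of every patch, pixels.
#' @exportClass PatchLayout
setClass("PatchLayout", representation(corners = "list", centrals = "list",
                                       patchSide = "integer"))

setValidity("PatchLayout", function(object) {
  if (length(object@corners) != 4L) return("exactly 4 corner patches required")
  if (length(object@centrals) != 3L) return("exactly 3 central patches required")
  ok <- vapply(c(object@corners, object@centrals), is, logical(1), "Rect")
  if (!all(ok)) return("patches must be Rect objects")
  for (a in object@corners) for (b in object@centrals)
    if (rectsIntersect(a, b))
      return("corner patches must not intersect central patches")
  TRUE
})

#' FingerPartition: the five vertical finger guidance regions
#'
#' Five equal-width vertical bands spanning the full image left to right,
#' indexed 1..5; the last band absorbs the integer-division remainder.
#'
#' @slot regions list of 5 \code{Rect}.
#' @slot width,height image dimensions the partition was built for.
#' @exportClass FingerPartition
setClass("FingerPartition", representation(regions = "list",
                                           width = "integer",
                                           height = "integer"))

setValidity("FingerPartition", function(object) {
  r <- object@regions
  if (length(r) != 5L) return("exactly 5 finger regions required")
  if (!all(vapply(r, is, logical(1), "Rect"))) return("regions must be Rects")
  xs <- vapply(r, function(q) q@x0, integer(1))
  xe <- vapply(r, function(q) q@x1, integer(1))
  if (xs[1] != 0L || xe[5] != object@width ||
      any(xe[-5] != xs[-1]))
    return("regions must tile the full image width")
  w <- xe - xs
  if (max(w) - min(w) > max(1L, object@width %% 5L))
    return("region widths must be equal up to the division remainder")
  TRUE
})

## Reference values ---------------------------------------------------------

#' ReferenceValues: per-channel black and white reference levels
#'
#' The anchors of the linear normalization; construction enforces
#' \code{white > black} on every channel, the degenerate-reference guard
#' that signals missing or failed patches.
#'
#' @slot black numeric length-3 (R, G, B) black level.
#' @slot white numeric length-3 (R, G, B) white level.
#' @exportClass ReferenceValues
setClass("ReferenceValues", representation(black = "numeric",
                                           white = "numeric"))

setValidity("ReferenceValues", function(object) {
  if (length(object@black) != 3L || length(object@white) != 3L)
    return("black and white must be length-3 (R, G, B)")
  if (any(object@black < 0) || any(object@white > 255))
    return("reference levels must lie in [0, 255]")
  if (any(object@white <= object@black))
    return("white must exceed black on every channel")
  TRUE
})

## Contours -----------------------------------------------------------------

#' NailContour: one connected nail region
#'
#' An 8-connected component of the post-processed mask, with its pixel set
#' (0-based x, y columns), area, centroid and (once assigned) finger index.
#'
#' @slot pixels integer matrix, one row per pixel, columns \code{x}, \code{y}.
#' @slot area pixel count.
#' @slot centroid numeric length-2 (x, y), mean of the pixel coordinates.
#' @slot fingerIndex integer 1..5, or \code{NA_integer_} while unassigned.
#' @exportClass NailContour
setClass("NailContour", representation(pixels = "matrix", area = "integer",
                                       centroid = "numeric",
                                       fingerIndex = "integer"))

setValidity("NailContour", function(object) {
  if (ncol(object@pixels) != 2L) return("pixels must have columns x, y")
  if (object@area != nrow(object@pixels) || object@area < 1L)
    return("area must equal the pixel count and be >= 1")
  cx <- object@centroid[1]; cy <- object@centroid[2]
  if (cx < min(object@pixels[, 1]) || cx > max(object@pixels[, 1]) ||
      cy < min(object@pixels[, 2]) || cy > max(object@pixels[, 2]))
    return("centroid must lie inside the bounding box of the pixel set")
  TRUE
})

## Measurement history ------------------------------------------------------

#' MeasurementHistory: append-only per-finger color records
#'
#' One acquisition contributes exactly five rows (fingers 1..5); rows are
#' only ever appended through \code{\link{appendAcquisition}}.
#'
#' @slot records data.frame with columns timestamp, finger, pixel_count,
#'   missing, R, G, B, eta_R, eta_G, eta_B.
#' @exportClass MeasurementHistory
setClass("MeasurementHistory", representation(records = "data.frame"))

setValidity("MeasurementHistory", function(object) {
  r <- object@records
  need <- c("timestamp", "finger", "pixel_count", "missing",
            "R", "G", "B", "eta_R", "eta_G", "eta_B")
  if (!identical(names(r), need))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  if (nrow(r) %% 5L != 0L)
    return("history must hold whole acquisitions (5 rows each)")
  if (nrow(r) > 0L && !all(r$finger == rep(1:5, nrow(r) / 5L)))
    return("each acquisition must cover fingers 1..5 in order")
  TRUE
})

## Evaluation ---------------------------------------------------------------

#' EvalResult: segmentation quality over a paired mask dataset
#'
#' @slot perImage data.frame with columns image, iou, dice_loss.
#' @slot meanIoU arithmetic mean of per-image IoU.
#' @slot meanDiceLoss arithmetic mean of per-image Dice loss.
#' @slot nImages number of mask pairs scored.
#' @exportClass EvalResult
setClass("EvalResult", representation(perImage = "data.frame",
                                      meanIoU = "numeric",
                                      meanDiceLoss = "numeric",
                                      nImages = "integer"))

setValidity("EvalResult", function(object) {
  if (object@nImages < 1L) return("at least one image required")
  if (nrow(object@perImage) != object@nImages)
    return("perImage must have one row per image")
  if (abs(object@meanIoU - mean(object@perImage$iou)) > 1e-12 ||
      abs(object@meanDiceLoss - mean(object@perImage$dice_loss)) > 1e-12)
    return("means must be arithmetic means of the per-image values")
  TRUE
})

## Synthetic fixtures -------------------------------------------------------

#' SyntheticHandSpec: parameters of a synthetic guided hand image
#'
#' Describes one fixture under the guided-box acquisition convention:
#' skin-toned finger bars in five vertical bands, one elliptical nail of
#' known true color per finger, true-black corner patches and true-white
#' central patches rendered before illumination, then a per-channel affine
#' illumination model and additive Gaussian sensor noise.
#'
#' @slot imageSide square image side, pixels.
#' @slot patchFraction reference patch side as a fraction of the image side.
#' @slot nailColors 5x3 matrix of true nail RGB (rows = fingers).
#' @slot skinColor,backgroundColor RGB triplets.
#' @slot nailAxes 5x2 matrix of ellipse semi-axes (x, y), pixels.
#' @slot nailCenters 5x2 matrix of ellipse centers (x, y), pixels.
#' @slot gains,offsets per-channel illumination gain and offset.
#' @slot noiseSd Gaussian noise standard deviation, grey levels.
#' @slot occlude integer finger indices rendered without a nail.
#' @slot allowClip if FALSE (default) the affine illumination must keep every
#'   rendered value inside [0, 255]; noise tails are clamped as sensor
#'   saturation either way.
#' @slot seed RNG seed for the noise stream.
#' @exportClass SyntheticHandSpec
setClass("SyntheticHandSpec",
         representation(imageSide = "integer", patchFraction = "numeric",
                        nailColors = "matrix", skinColor = "numeric",
                        backgroundColor = "numeric", nailAxes = "matrix",
                        nailCenters = "matrix", gains = "numeric",
                        offsets = "numeric", noiseSd = "numeric",
                        occlude = "integer", allowClip = "logical",
                        seed = "integer"))

setValidity("SyntheticHandSpec", function(object) {
  if (object@imageSide < 100L) return("imageSide must be >= 100")
  if (!all(dim(object@nailColors) == c(5L, 3L)))
    return("nailColors must be 5 x 3")
  if (!all(dim(object@nailAxes) == c(5L, 2L)) ||
      !all(dim(object@nailCenters) == c(5L, 2L)))
    return("nailAxes and nailCenters must be 5 x 2")
  if (any(object@gains <= 0)) return("illumination gains must be positive")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (length(object@occlude) && !all(object@occlude %in% 1:5))
    return("occlude indices must be in 1..5")
  if (min(object@nailColors) < 0 || max(object@nailColors) > 255 ||
      min(object@skinColor) < 0 || max(object@skinColor) > 255 ||
      min(object@backgroundColor) < 0 || max(object@backgroundColor) > 255)
    return("colors must lie in [0, 255]")
  TRUE
})

#' SyntheticHandFixture: a rendered hand image with its ground truth
#'
#' @slot image the rendered \code{RGBImage}.
#' @slot gtMask \code{BinaryMask} marking exactly the nail ellipse pixels.
#' @slot truth data.frame: finger, R, G, B (true color), cx, cy, area,
#'   occluded.
#' @slot spec the generating \code{SyntheticHandSpec}.
#' @exportClass SyntheticHandFixture
setClass("SyntheticHandFixture",
         representation(image = "RGBImage", gtMask = "BinaryMask",
                        truth = "data.frame", spec = "SyntheticHandSpec"))
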