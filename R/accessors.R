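## Accessors and show methods for the core containers.

#' Pixel array of an RGBImage
#' @param x an \code{RGBImage}.
#' @return integer array \code{[y, x, channel]}.
#' @export
pixelArray <- function(x) {
  stopifnot(is(x, "RGBImage"))
  x@pixels
}

#' Value array of a NormalizedImage
#' @param x a \code{NormalizedImage}.
#' @return numeric array \code{[y, x, channel]} in [0, 1].
#' @export
etaArray <- function(x) {
  stopifnot(is(x, "NormalizedImage"))
  x@values
}

#' Logical matrix of a BinaryMask
#' @param x a \code{BinaryMask}.
#' @return logical matrix \code{[y, x]}.
#' @export
maskData <- function(x) {
  stopifnot(is(x, "BinaryMask"))
  x@values
}

#' Numeric matrix of a ProbabilityMask
#' @param x a \code{ProbabilityMask}.
#' @return numeric matrix \code{[y, x]} in [0, 1].
#' @export
probData <- function(x) {
  stopifnot(is(x, "ProbabilityMask"))
  x@values
}

#' @describeIn pixelArray image dimensions as \code{c(height, width, 3)}.
#' @export
setMethod("dim", "RGBImage", function(x) dim(x@pixels))

#' @rdname etaArray
#' @export
setMethod("dim", "NormalizedImage", function(x) dim(x@values))

#' @rdname maskData
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@values))

#' @rdname probData
#' @export
setMethod("dim", "ProbabilityMask", function(x) dim(x@values))

#' Black reference levels
#' @param x a \code{ReferenceValues}.
#' @return numeric length-3 (R, G, B).
#' @export
refBlack <- function(x) {
  stopifnot(is(x, "ReferenceValues"))
  x@black
}

#' White reference levels
#' @param x a \code{ReferenceValues}.
#' @return numeric length-3 (R, G, B).
#' @export
refWhite <- function(x) {
  stopifnot(is(x, "ReferenceValues"))
  x@white
}

#' Finger guidance regions
#' @param x a \code{FingerPartition}.
#' @return list of 5 \code{Rect}, left to right.
#' @export
fingerRegions <- function(x) {
  stopifnot(is(x, "FingerPartition"))
  x@regions
}

#' Contour accessors
#'
#' @param x a \code{NailContour}.
#' @return \code{contourPixels}: integer matrix of 0-based (x, y) pixels;
#'   \code{contourArea}: pixel count; \code{contourCentroid}: numeric (x, y);
#'   \code{fingerIndex}: assigned finger 1..5 or NA.
#' @export
contourPixels <- function(x) {
  stopifnot(is(x, "NailContour"))
  x@pixels
}

#' @rdname contourPixels
#' @export
contourArea <- function(x) {
  stopifnot(is(x, "NailContour"))
  x@area
}

#' @rdname contourPixels
#' @export
contourCentroid <- function(x) {
  stopifnot(is(x, "NailContour"))
  x@centroid
}

#' @rdname contourPixels
#' @export
fingerIndex <- function(x) {
  stopifnot(is(x, "NailContour"))
  x@fingerIndex
}

#' History records
#' @param x a \code{MeasurementHistory}.
#' @return data.frame of per-finger measurement rows.
#' @export
historyRecords <- function(x) {
  stopifnot(is(x, "MeasurementHistory"))
  x@records
}

#' Evaluation result accessors
#' @param x an \code{EvalResult}.
#' @return per-image score table or scalar summaries.
#' @export
perImageScores <- function(x) {
  stopifnot(is(x, "EvalResult"))
  x@perImage
}

#' @rdname perImageScores
#' @export
meanIoU <- function(x) {
  stopifnot(is(x, "EvalResult"))
  x@meanIoU
}

#' @rdname perImageScores
#' @export
meanDiceLoss <- function(x) {
  stopifnot(is(x, "EvalResult"))
  x@meanDiceLoss
}

#' Fixture accessors
#' @param x a \code{SyntheticHandFixture}.
#' @return the rendered image, its ground-truth mask, the per-finger truth
#'   table, or the generating spec.
#' @export
fixtureImage <- function(x) {
  stopifnot(is(x, "SyntheticHandFixture"))
  x@image
}

#' @rdname fixtureImage
#' @export
fixtureMask <- function(x) {
  stopifnot(is(x, "SyntheticHandFixture"))
  x@gtMask
}

#' @rdname fixtureImage
#' @export
fixtureTruth <- function(x) {
  stopifnot(is(x, "SyntheticHandFixture"))
  x@truth
}

#' @rdname fixtureImage
#' @export
fixtureSpec <- function(x) {
  stopifnot(is(x, "SyntheticHandFixture"))
  x@spec
}

setMethod("show", "RGBImage", function(object) {
  d <- dim(object@pixels)
  cat("RGBImage ", d[1], " x ", d[2], " (8-bit, R/G/B)\n", sep = "")
})

setMethod("show", "NormalizedImage", function(object) {
  d <- dim(object@values)
  cat("NormalizedImage ", d[1], " x ", d[2],
      " (eta in [0,1], per channel)\n", sep = "")
})

setMethod("show", "BinaryMask", function(object) {
  v <- object@values
  cat("BinaryMask ", nrow(v), " x ", ncol(v), "; ", sum(v),
      " nail pixels (", round(100 * mean(v), 2), "%)\n", sep = "")
})

setMethod("show", "ProbabilityMask", function(object) {
  v <- object@values
  cat("ProbabilityMask ", nrow(v), " x ", ncol(v), "; mean p = ",
      signif(mean(v), 4), "\n", sep = "")
})

setMethod("show", "Rect", function(object) {
  cat("Rect [", object@x0, ",", object@x1, ") x [", object@y0, ",",
      object@y1, ")\n", sep = "")
})

setMethod("show", "ReferenceValues", function(object) {
  cat("ReferenceValues\n  black (R,G,B): ",
      paste(signif(object@black, 5), collapse = ", "),
      "\n  white (R,G,B): ",
      paste(signif(object@white, 5), collapse = ", "), "\n", sep = "")
})

setMethod("show", "NailContour", function(object) {
  cat("NailContour area ", object@area, " px, centroid (",
      round(object@centroid[1], 1), ", ", round(object@centroid[2], 1),
      "), finger ",
      ifelse(is.na(object@fingerIndex), "unassigned", object@fingerIndex),
      "\n", sep = "")
})

setMethod("show", "MeasurementHistory", function(object) {
  n <- nrow(object@records) / 5L
  cat("MeasurementHistory: ", n, " acquisition(s), ",
      nrow(object@records), " rows\n", sep = "")
})

setMethod("show", "EvalResult", function(object) {
  cat("EvalResult over ", object@nImages, " image(s)\n",
      "  mean IoU:       ", signif(object@meanIoU, 4), "\n",
      "  mean Dice loss: ", signif(object@meanDiceLoss, 4), "\n", sep = "")
})

setMethod("show", "SyntheticHandFixture", function(object) {
  cat("SyntheticHandFixture ", object@spec@imageSide, " x ",
      object@spec@imageSide, ", ", sum(!object@truth$occluded),
      " nail(s), seed ", object@spec@seed, "\n", sep = "")
})
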