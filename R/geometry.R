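## Rectangle plumbing and the five-finger guidance partition.

#' Construct a half-open rectangle
#'
#' Coordinates are 0-based with origin at the top-left corner; x indexes
#' columns and y rows; the rectangle covers \code{[x0, x1) x [y0, y1)}.
#'
#' @param x0,y0 top-left corner (inclusive).
#' @param x1,y1 bottom-right corner (exclusive).
#' @return a \code{Rect}.
#' @export
rect <- function(x0, y0, x1, y1) {
  new("Rect", x0 = as.integer(x0), y0 = as.integer(y0),
      x1 = as.integer(x1), y1 = as.integer(y1))
}

rectWidth <- function(r) r@x1 - r@x0
rectHeight <- function(r) r@y1 - r@y0

rectsIntersect <- function(a, b) {
  a@x0 < b@x1 && b@x0 < a@x1 && a@y0 < b@y1 && b@y0 < a@y1
}

rectContainsPoint <- function(r, x, y) {
  x >= r@x0 & x < r@x1 & y >= r@y0 & y < r@y1
}

rectInsideDims <- function(r, height, width) {
  r@x0 >= 0L && r@y0 >= 0L && r@x1 <= width && r@y1 <= height
}

## 1-based row/col index vectors of a rect within a [y, x] matrix
rectRows <- function(r) (r@y0 + 1L):r@y1
rectCols <- function(r) (r@x0 + 1L):r@x1

#' Build the five-finger guidance partition
#'
#' Splits the image into five equal-width vertical bands spanning the full
#' height, indexed 1..5 left to right; the fifth band absorbs the integer
#' division remainder.
#'
#' @param width,height image dimensions in pixels.
#' @return a \code{FingerPartition}.
#' @export
#' @examples
#' p <- makeFingerPartition(800, 800)
#' vapply(fingerRegions(p), function(r) r@x0, integer(1))
makeFingerPartition <- function(width, height) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 5L)
    stopParameter("width must be >= 5 to hold five finger regions, got ",
                  width)
  if (height < 1L) stopParameter("height must be >= 1")
  w0 <- width %/% 5L
  x0 <- (0:4) * w0
  x1 <- c(x0[-1], width)
  regions <- mapply(function(a, b) rect(a, 0L, b, height), x0, x1)
  new("FingerPartition", regions = regions, width = width, height = height)
}

## logical [y, x] matrix marking pixels inside any of the given rects
rectsCoverMatrix <- function(rects, height, width) {
  m <- matrix(FALSE, height, width)
  for (r in rects) m[rectRows(r), rectCols(r)] <- TRUE
  m
}
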