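## Raster I/O and resizing. EBImage does the PNG/JPEG codec work and the
## bilinear interpolation; this layer fixes the package's conventions:
## integer 0-255 pixels, [row, col, channel] layout, channel order R,G,B.

#' Construct an RGBImage from an array
#'
#' @param pixels numeric or integer array \code{[y, x, 3]} with values in
#'   [0, 255]; a \code{[y, x]} matrix is replicated to three channels.
#' @return an \code{RGBImage}.
#' @export
rgbImage <- function(pixels) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 3L))
  storage.mode(pixels) <- "integer"
  new("RGBImage", pixels = pixels)
}

#' Load a PNG or JPEG image
#'
#' Channel order is R, G, B regardless of the file's byte order; grayscale
#' sources are replicated to three channels; an alpha channel, if present,
#' is dropped.
#'
#' @param path path to a PNG or JPEG file.
#' @return an \code{RGBImage}.
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stopInput("no such image file: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stopInput("cannot decode image '", path, "': ",
                              conditionMessage(e)))
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2L) {
    d <- array(rep(d, 3L), dim = c(dim(d), 3L))
  } else if (dim(d)[3] >= 3L) {
    d <- d[, , 1:3, drop = FALSE]
  } else {
    stopInput("unsupported channel count in '", path, "'")
  }
  if (any(dim(d)[1:2] == 0L)) stopInput("zero-sized image: ", path)
  px <- aperm(d, c(2L, 1L, 3L))      # EBImage stores [x, y, c]
  rgbImage(round(px * 255))
}

#' Write an RGBImage as PNG
#'
#' Always 8-bit PNG so that write/read round-trips are bit-exact.
#'
#' @param image an \code{RGBImage}.
#' @param path output path (extension .png).
#' @return \code{path}, invisibly.
#' @export
saveImage <- function(image, path) {
  stopifnot(is(image, "RGBImage"))
  d <- aperm(image@pixels / 255, c(2L, 1L, 3L))
  img <- EBImage::Image(d, colormode = "Color")
  EBImage::writeImage(img, path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

#' Write a BinaryMask as single-channel PNG
#'
#' 0 = background, 255 = nail, the package's mask-file convention.
#'
#' @param mask a \code{BinaryMask}.
#' @param path output path (extension .png).
#' @return \code{path}, invisibly.
#' @export
saveMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  img <- EBImage::Image(t(mask@values) * 1)
  EBImage::writeImage(img, path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

#' Resize an image to the square working size
#'
#' Bilinear interpolation to \code{side x side}; the aspect ratio is not
#' preserved (non-square frames are stretched, matching the guided
#' acquisition where the hand box fills the frame). When the input already
#' has the target size the pixels are returned unchanged.
#'
#' @param image an \code{RGBImage}.
#' @param side target side in pixels, default 800 (the working size the
#'   whole pipeline is calibrated at).
#' @return an \code{RGBImage} of dimension \code{side x side}.
#' @export
resizeToWorking <- function(image, side = 800L) {
  stopifnot(is(image, "RGBImage"))
  side <- as.integer(side)
  if (side < 32L) stopParameter("working side must be >= 32, got ", side)
  d <- dim(image@pixels)
  if (d[1] == side && d[2] == side) return(image)
  img <- EBImage::Image(aperm(image@pixels / 255, c(2L, 1L, 3L)),
                        colormode = "Color")
  out <- EBImage::resize(img, w = side, h = side, filter = "bilinear")
  px <- aperm(EBImage::imageData(out), c(2L, 1L, 3L))
  rgbImage(pmin(pmax(round(px * 255), 0), 255))
}

#' Apply a per-channel affine illumination model
#'
#' Computes \code{round(gain * I + offset)} per channel — the illumination
#' model the reference-patch normalization is designed to invert. With
#' \code{clamp = FALSE} any value leaving [0, 255] raises a parameter error;
#' with \code{clamp = TRUE} values saturate at the range ends.
#'
#' @param image an \code{RGBImage}.
#' @param gains,offsets numeric length-3 (or scalar) per-channel gain and
#'   offset.
#' @param clamp saturate out-of-range values instead of erroring.
#' @return an \code{RGBImage}.
#' @export
applyIllumination <- function(image, gains, offsets, clamp = FALSE) {
  stopifnot(is(image, "RGBImage"))
  gains <- rep_len(as.numeric(gains), 3L)
  offsets <- rep_len(as.numeric(offsets), 3L)
  if (any(gains <= 0)) stopParameter("illumination gains must be positive")
  px <- image@pixels
  out <- array(0, dim = dim(px))
  for (ch in 1:3) out[, , ch] <- gains[ch] * px[, , ch] + offsets[ch]
  out <- round(out)
  if (min(out) < 0 || max(out) > 255) {
    if (!clamp)
      stopParameter("illumination drives pixel values outside [0, 255]; ",
                    "range is [", min(out), ", ", max(out), "]")
    out <- pmin(pmax(out, 0), 255)
  }
  rgbImage(out)
}
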