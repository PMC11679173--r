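## Reference-patch location and the per-channel linear normalization
## eta = (I - Black) / (White - Black), the core radiometric step: with
## black patches of zero reflectance and white patches of full reflectance
## imaged under per-channel affine illumination I = gain * reflectance +
## offset, eta cancels both gain and offset exactly.

#' Build the reference-patch layout
#'
#' Four black reference squares flush to the four image corners and three
#' white reference squares centered at 25, 50 and 75 percent of the image
#' width along the top band (y from 0 to the patch side). The patch side is
#' \code{round(patch_fraction * min(width, height))}.
#'
#' @param width,height image dimensions in pixels.
#' @param patch_fraction patch side as a fraction of the short image side;
#'   must lie in (0, 0.2].
#' @return a \code{PatchLayout}.
#' @export
#' @examples
#' makePatchLayout(800, 800, 0.05)  # 40 px patches
makePatchLayout <- function(width, height, patch_fraction = 0.05) {
  width <- as.integer(width); height <- as.integer(height)
  if (patch_fraction <= 0 || patch_fraction > 0.2)
    stopParameter("patch_fraction must lie in (0, 0.2], got ", patch_fraction)
  side <- as.integer(round(patch_fraction * min(width, height)))
  if (side < 2L)
    stopParameter("patch side ", side, " px is degenerate (< 2)")
  corners <- list(
    rect(0L, 0L, side, side),
    rect(width - side, 0L, width, side),
    rect(0L, height - side, side, height),
    rect(width - side, height - side, width, height))
  centrals <- lapply(c(0.25, 0.5, 0.75), function(q) {
    x0 <- as.integer(round(q * width - side / 2))
    rect(x0, 0L, x0 + side, side)
  })
  for (r in c(corners, centrals))
    if (!rectInsideDims(r, height, width))
      stopParameter("patch layout exceeds image bounds")
  for (i in 1:2) for (ce in centrals)     # top-edge corners vs centrals
    if (rectsIntersect(corners[[i]], ce))
      stopParameter("corner and central patches overlap; ",
                    "reduce patch_fraction")
  if (rectsIntersect(centrals[[1]], centrals[[2]]) ||
      rectsIntersect(centrals[[2]], centrals[[3]]))
    stopParameter("central patches overlap; reduce patch_fraction")
  new("PatchLayout", corners = corners, centrals = centrals,
      patchSide = side)
}

#' Extract per-channel black and white reference levels
#'
#' The black level of a channel is taken over the union of the four corner
#' patches, the white level over the union of the three central patches,
#' independently per channel. \code{stat = "minmax"} uses the plain
#' minimum/maximum; \code{stat = "patchmean"} is a robust variant that
#' averages each patch first and then takes the min/max across patches —
#' unbiased under zero-mean sensor noise, where the extreme order statistic
#' of thousands of noisy pixels sits several noise-SDs beyond the true
#' level.
#'
#' @param image an \code{RGBImage}.
#' @param layout a \code{PatchLayout} that fits inside the image.
#' @param stat \code{"minmax"} (default) or \code{"patchmean"}.
#' @return a \code{ReferenceValues}; a degenerate-reference error is raised
#'   when any channel has white <= black (missing or failed patches).
#' @export
extractReferences <- function(image, layout,
                              stat = c("minmax", "patchmean")) {
  stopifnot(is(image, "RGBImage"), is(layout, "PatchLayout"))
  stat <- match.arg(stat)
  px <- image@pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  for (r in c(layout@corners, layout@centrals))
    if (!rectInsideDims(r, h, w))
      stopInput("patch layout does not fit inside the ", h, " x ", w,
                " image")
  chanStat <- function(rects, combine) {
    vapply(1:3, function(ch) {
      per <- vapply(rects, function(r)
        if (stat == "minmax") combine(px[rectRows(r), rectCols(r), ch])
        else mean(px[rectRows(r), rectCols(r), ch]), numeric(1))
      combine(per)
    }, numeric(1))
  }
  black <- chanStat(layout@corners, min)
  white <- chanStat(layout@centrals, max)
  if (any(white <= black))
    stopDegenerateReference(
      "white reference does not exceed black reference on channel(s) ",
      paste(c("R", "G", "B")[white <= black], collapse = ", "),
      "; reference patches missing or unusable")
  new("ReferenceValues", black = black, white = white)
}

#' Normalize a channel value against reference levels
#'
#' \code{clip((I - black) / (white - black), 0, 1)}; vectorized in \code{I}.
#'
#' @param I channel value(s) on the 0-255 scale.
#' @param black,white reference levels with \code{white > black}.
#' @return normalized value(s) in [0, 1].
#' @export
normalizeValue <- function(I, black, white) {
  if (white <= black)
    stopDegenerateReference("white (", white,
                            ") must exceed black (", black, ")")
  pmin(pmax((I - black) / (white - black), 0), 1)
}

#' Normalize an image against extracted reference levels
#'
#' Applies \code{\link{normalizeValue}} per pixel per channel.
#'
#' @param image an \code{RGBImage}.
#' @param refs a \code{ReferenceValues}.
#' @return a \code{NormalizedImage} of the same dimensions.
#' @export
normalizeImage <- function(image, refs) {
  stopifnot(is(image, "RGBImage"), is(refs, "ReferenceValues"))
  px <- image@pixels
  out <- array(0, dim = dim(px))
  for (ch in 1:3)
    out[, , ch] <- normalizeValue(px[, , ch], refs@black[ch],
                                  refs@white[ch])
  new("NormalizedImage", values = out)
}
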