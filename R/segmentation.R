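## Segmentation backends. The pipeline is backend-agnostic: anything that
## yields a per-pixel nail probability map plugs in. Two backends ship —
## a deterministic classical baseline operating on the normalized image,
## and a loader for mask files produced by an external model (e.g. an
## encoder-decoder CNN).

#' Classical brightness/saturation nail baseline
#'
#' Scores a pixel as nail (probability 1) iff, in normalized coordinates,
#' its brightness \code{max(eta_R, eta_G, eta_B)} is at least
#' \code{brightness_min}, its saturation \code{(max - min)/max} (0 when max
#' is 0) is at most \code{saturation_max}, and it lies inside a finger
#' guidance rectangle. Nail plates are bright and weakly saturated while
#' skin is strongly saturated, so the two thresholds separate them once
#' illumination has been normalized out; because the test runs on eta
#' values the baseline inherits the normalization's illumination
#' invariance.
#'
#' @param norm a \code{NormalizedImage}.
#' @param partition a \code{FingerPartition} (or list of \code{Rect}) whose
#'   dimensions match the image; pixels outside every rect score 0.
#' @param brightness_min minimum normalized brightness in [0, 1), default
#'   0.6.
#' @param saturation_max maximum saturation in (0, 1], default 0.35.
#' @return a 0/1 \code{ProbabilityMask}.
#' @export
segmentClassical <- function(norm, partition, brightness_min = 0.6,
                             saturation_max = 0.35) {
  stopifnot(is(norm, "NormalizedImage"))
  if (brightness_min < 0 || brightness_min >= 1)
    stopParameter("brightness_min must lie in [0, 1), got ", brightness_min)
  if (saturation_max <= 0 || saturation_max > 1)
    stopParameter("saturation_max must lie in (0, 1], got ", saturation_max)
  v <- norm@values
  h <- dim(v)[1]; w <- dim(v)[2]
  rects <- if (is(partition, "FingerPartition")) {
    if (partition@width != w || partition@height != h)
      stopInput("partition is ", partition@height, " x ", partition@width,
                " but image is ", h, " x ", w)
    partition@regions
  } else partition
  for (r in rects)
    if (!rectInsideDims(r, h, w))
      stopInput("guidance rect exceeds image bounds")
  mx <- pmax(v[, , 1], v[, , 2], v[, , 3])
  mn <- pmin(v[, , 1], v[, , 2], v[, , 3])
  sat <- ifelse(mx == 0, 0, (mx - mn) / mx)
  score <- (mx >= brightness_min) & (sat <= saturation_max) &
    rectsCoverMatrix(rects, h, w)
  new("ProbabilityMask", values = score * 1)
}

#' Load a mask file produced by an external segmentation model
#'
#' Reads a single-channel image; pixel value v (0-255) maps to probability
#' v/255. Dimension agreement with the paired image is the caller's check.
#'
#' @param path path to a single-channel PNG.
#' @return a \code{ProbabilityMask}.
#' @export
loadMask <- function(path) {
  if (!file.exists(path)) stopInput("no such mask file: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stopInput("cannot decode mask '", path, "': ",
                              conditionMessage(e)))
  d <- EBImage::imageData(img)
  if (length(dim(d)) != 2L)
    stopInput("mask '", path, "' must be single-channel, found ",
              dim(d)[3], " channels")
  new("ProbabilityMask", values = t(pmin(pmax(d, 0), 1)))
}
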