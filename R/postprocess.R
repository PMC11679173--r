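## Mask post-processing: threshold, majority (median) hole filling, square
## structuring-element erosion, 8-connected components, finger assignment
## and size regulation. The fixed pipeline order is
##   binarize -> fillHolesMedian -> erodeMask -> extractNailContours
##   -> assignContours.
##
## All square-window operations run on one integral-image primitive so an
## even structuring-element side (the stock erode_filter = 70) is honored
## exactly: the window for output pixel (y, x) spans rows y-a .. y-a+k-1,
## cols x-a .. x-a+k-1 with anchor a = floor(k/2).

## counts of TRUE in each k x k window; pad = "zero" treats outside as
## FALSE (erosion/dilation), pad = "replicate" extends edge values
## (majority filter)
boxCount <- function(m, k, pad = c("zero", "replicate")) {
  pad <- match.arg(pad)
  h <- nrow(m); w <- ncol(m)
  a <- k %/% 2L
  ph <- h + k - 1L; pw <- w + k - 1L
  if (pad == "zero") {
    P <- matrix(0, ph, pw)
    P[(a + 1L):(a + h), (a + 1L):(a + w)] <- m
  } else {
    ri <- pmin(pmax(seq_len(ph) - a, 1L), h)
    ci <- pmin(pmax(seq_len(pw) - a, 1L), w)
    P <- (m * 1)[ri, ci, drop = FALSE]
  }
  A <- apply(P, 2, cumsum)
  B <- t(apply(A, 1, cumsum))
  S <- matrix(0, ph + 1L, pw + 1L)
  S[-1L, -1L] <- B
  S[(k + 1L):(h + k), (k + 1L):(w + k)] -
    S[1:h, (k + 1L):(w + k)] -
    S[(k + 1L):(h + k), 1:w] +
    S[1:h, 1:w]
}

erodeValues <- function(v, k) boxCount(v, k, "zero") >= k * k - 0.5

dilateValues <- function(v, k) boxCount(v, k, "zero") > 0.5

#' Threshold a probability mask
#'
#' @param prob a \code{ProbabilityMask}.
#' @param threshold cut in (0, 1); a pixel is nail iff its probability is
#'   \code{>= threshold}.
#' @return a \code{BinaryMask}.
#' @export
binarize <- function(prob, threshold = 0.5) {
  stopifnot(is(prob, "ProbabilityMask"))
  if (threshold <= 0 || threshold >= 1)
    stopParameter("threshold must lie in (0, 1), got ", threshold)
  new("BinaryMask", values = prob@values >= threshold)
}

#' Fill mask holes with a majority (median) filter
#'
#' Each output pixel takes the majority value of its \code{kernel x kernel}
#' neighborhood — the binary case of a median blur, used to fill pinholes
#' left by the segmentation backend. Borders are handled by edge
#' replication.
#'
#' @param mask a \code{BinaryMask}.
#' @param kernel odd window side, >= 3.
#' @return a \code{BinaryMask}.
#' @export
fillHolesMedian <- function(mask, kernel = 3L) {
  stopifnot(is(mask, "BinaryMask"))
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L)
    stopParameter("kernel must be odd and >= 3, got ", kernel)
  cnt <- boxCount(mask@values, kernel, "replicate")
  new("BinaryMask", values = 2 * cnt > kernel * kernel)
}

#' Erode a mask with a square structuring element
#'
#' Output pixels are nail only where the full \code{erode_filter x
#' erode_filter} square fits inside the input's nail region (pixels outside
#' the image count as background). Erosion severs thin bridges between
#' touching nail regions so each finger yields a clean separate contour.
#'
#' @param mask a \code{BinaryMask}.
#' @param erode_filter structuring-element side in pixels, >= 1 (1 is the
#'   identity). The stock values are 70 and 92 at the 800 px working size.
#' @return a \code{BinaryMask}.
#' @export
erodeMask <- function(mask, erode_filter) {
  stopifnot(is(mask, "BinaryMask"))
  k <- as.integer(erode_filter)
  if (k < 1L) stopParameter("erode_filter must be >= 1, got ", k)
  if (k == 1L) return(mask)
  new("BinaryMask", values = erodeValues(mask@values, k))
}

## 8-connected labeling by row runs + union-find; labels are compacted in
## order of first appearance (row-major), so the result is deterministic.
labelComponents <- function(m) {
  h <- nrow(m); w <- ncol(m)
  parent <- integer(0)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  runRow <- vector("list", h)
  nrun <- 0L
  for (r in seq_len(h)) {
    x <- m[r, ]
    if (!any(x)) next
    rl <- rle(x)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    s <- starts[rl$values]; e <- ends[rl$values]
    ids <- nrun + seq_along(s)
    nrun <- nrun + length(s)
    parent <- c(parent, ids)
    runRow[[r]] <- cbind(s, e, ids)
    if (r > 1L && !is.null(runRow[[r - 1L]])) {
      prev <- runRow[[r - 1L]]
      i <- 1L; j <- 1L
      while (i <= nrow(prev) && j <= length(s)) {
        if (prev[i, 1] <= e[j] + 1L && s[j] <= prev[i, 2] + 1L) {
          ra <- findRoot(prev[i, 3]); rb <- findRoot(ids[j])
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
        if (prev[i, 2] < e[j]) i <- i + 1L else j <- j + 1L
      }
    }
  }
  lab <- matrix(0L, h, w)
  if (nrun == 0L) return(list(labels = lab, n = 0L))
  roots <- vapply(seq_len(nrun), findRoot, integer(1))
  newId <- integer(nrun)
  counter <- 0L
  for (r in seq_len(h)) {
    rr <- runRow[[r]]
    if (is.null(rr)) next
    for (q in seq_len(nrow(rr))) {
      root <- roots[rr[q, 3]]
      if (newId[root] == 0L) {
        counter <- counter + 1L
        newId[root] <- counter
      }
      lab[r, rr[q, 1]:rr[q, 2]] <- newId[root]
    }
  }
  list(labels = lab, n = counter)
}

newContour <- function(pixels, fingerIndex = NA_integer_) {
  new("NailContour", pixels = pixels, area = nrow(pixels),
      centroid = c(mean(pixels[, 1]), mean(pixels[, 2])),
      fingerIndex = as.integer(fingerIndex))
}

#' Extract nail contours from a binary mask
#'
#' 8-connected components with area >= \code{min_area}, ordered by
#' descending area (ties keep first-appearance order).
#'
#' @param mask a \code{BinaryMask}.
#' @param min_area minimum component area in pixels, >= 1.
#' @return list of \code{NailContour} (possibly empty).
#' @export
extractNailContours <- function(mask, min_area = 50L) {
  stopifnot(is(mask, "BinaryMask"))
  min_area <- as.integer(min_area)
  if (min_area < 1L) stopParameter("min_area must be >= 1, got ", min_area)
  lab <- labelComponents(mask@values)
  if (lab$n == 0L) return(list())
  areas <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n)
  keep <- which(areas >= min_area)
  keep <- keep[order(-areas[keep], keep)]
  lapply(keep, function(id) {
    rc <- which(lab$labels == id, arr.ind = TRUE)
    px <- cbind(x = rc[, 2] - 1L, y = rc[, 1] - 1L)
    newContour(px)
  })
}

#' Assign contours to finger regions
#'
#' Each contour is assigned to the guidance region containing its centroid;
#' when several contours land in the same region the largest-area one is
#' kept (ties broken by leftmost centroid), the rest are discarded. Regions
#' with no contour map to missing.
#'
#' @param contours list of \code{NailContour}.
#' @param partition a \code{FingerPartition}.
#' @return list of length 5; element i is the \code{NailContour} assigned
#'   to finger i (with \code{fingerIndex} set) or \code{NULL} if missing.
#' @export
assignContours <- function(contours, partition) {
  stopifnot(is(partition, "FingerPartition"))
  out <- vector("list", 5L)
  if (!length(contours)) return(out)
  cx <- vapply(contours, function(ct) ct@centroid[1], numeric(1))
  cy <- vapply(contours, function(ct) ct@centroid[2], numeric(1))
  area <- vapply(contours, function(ct) ct@area, integer(1))
  for (i in 1:5) {
    r <- partition@regions[[i]]
    inside <- which(rectContainsPoint(r, cx, cy))
    if (!length(inside)) next
    best <- inside[order(-area[inside], cx[inside])][1]
    ct <- contours[[best]]
    ct@fingerIndex <- i
    out[[i]] <- ct
  }
  out
}

#' Regulate a nail region's size
#'
#' The batch counterpart of the GUI size cursor: \code{factor < 1} shrinks
#' the contour by iterated 3x3 erosion until its area is at most
#' \code{factor} times the original (but never below one pixel);
#' \code{factor > 1} grows it by iterated 3x3 dilation, clipped to
#' \code{clip_rect} (normally the contour's finger region), until the area
#' is at least \code{factor} times the original or growth stalls.
#'
#' @param contour a \code{NailContour}.
#' @param factor scale factor in [0.2, 3].
#' @param clip_rect optional \code{Rect} limiting dilation.
#' @return a \code{NailContour} with the same \code{fingerIndex}.
#' @export
scaleRegion <- function(contour, factor, clip_rect = NULL) {
  stopifnot(is(contour, "NailContour"))
  if (factor < 0.2 || factor > 3)
    stopParameter("region scale factor must lie in [0.2, 3], got ", factor)
  if (factor == 1) return(contour)
  px <- contour@pixels
  pad <- if (factor > 1)
    as.integer(ceiling((sqrt(factor) - 1) / 2 *
                       max(diff(range(px[, 1])), diff(range(px[, 2]))))) + 2L
  else 1L
  x0 <- min(px[, 1]) - pad; y0 <- min(px[, 2]) - pad
  if (!is.null(clip_rect)) {
    x0 <- min(x0, clip_rect@x0); y0 <- min(y0, clip_rect@y0)
  }
  w <- max(px[, 1]) + pad - x0 + 1L
  h <- max(px[, 2]) + pad - y0 + 1L
  if (!is.null(clip_rect)) {
    w <- max(w, clip_rect@x1 - x0); h <- max(h, clip_rect@y1 - y0)
  }
  m <- matrix(FALSE, h, w)
  m[cbind(px[, 2] - y0 + 1L, px[, 1] - x0 + 1L)] <- TRUE
  clip <- matrix(TRUE, h, w)
  if (!is.null(clip_rect)) {
    clip[] <- FALSE
    rr <- (max(clip_rect@y0, y0) - y0 + 1L):(min(clip_rect@y1 - 1L, y0 + h - 1L) - y0 + 1L)
    cc <- (max(clip_rect@x0, x0) - x0 + 1L):(min(clip_rect@x1 - 1L, x0 + w - 1L) - x0 + 1L)
    clip[rr, cc] <- TRUE
  }
  target <- factor * contour@area
  if (factor < 1) {
    while (sum(m) > target) {
      nxt <- erodeValues(m, 3L)
      if (!any(nxt)) break
      m <- nxt
    }
  } else {
    while (sum(m) < target) {
      nxt <- dilateValues(m, 3L) & clip
      if (identical(nxt, m) || !any(nxt != m)) break
      m <- nxt
    }
  }
  rc <- which(m, arr.ind = TRUE)
  newContour(cbind(x = rc[, 2] + x0 - 1L, y = rc[, 1] + y0 - 1L),
             contour@fingerIndex)
}

#' Rasterize contours back into a binary mask
#'
#' Union of the pixel sets of the given contours (NULL entries are
#' skipped), e.g. to score an assignment against a ground-truth mask.
#'
#' @param contours list of \code{NailContour} or NULL entries.
#' @param height,width output mask dimensions.
#' @return a \code{BinaryMask}.
#' @export
contoursToMask <- function(contours, height, width) {
  m <- matrix(FALSE, height, width)
  for (ct in contours) {
    if (is.null(ct)) next
    m[cbind(ct@pixels[, 2] + 1L, ct@pixels[, 1] + 1L)] <- TRUE
  }
  new("BinaryMask", values = m)
}
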