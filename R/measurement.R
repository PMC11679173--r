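## Per-finger color measurement and the append-only history. The canonical
## output is the mean of the per-pixel normalized values (mean-of-eta);
## raw-channel means are kept alongside for display. Because the
## normalization is affine, the two orders of operation agree on clip-free
## regions up to 8-bit quantization.

historyColumns <- c("timestamp", "finger", "pixel_count", "missing",
                    "R", "G", "B", "eta_R", "eta_G", "eta_B")

emptyRecords <- function() {
  data.frame(timestamp = character(0), finger = integer(0),
             pixel_count = integer(0), missing = logical(0),
             R = numeric(0), G = numeric(0), B = numeric(0),
             eta_R = numeric(0), eta_G = numeric(0), eta_B = numeric(0),
             stringsAsFactors = FALSE)
}

#' Measure per-finger nail colors
#'
#' For every assigned finger, the arithmetic mean of the raw R, G, B
#' channels and of the normalized eta channels over the contour's pixel
#' set; fingers without an assigned contour yield a missing measurement
#' (pixel_count 0, NA color cells) — the semantics of an occluded or
#' undetectable nail.
#'
#' @param image the working-size \code{RGBImage}.
#' @param norm its \code{NormalizedImage}.
#' @param assignment list of length 5 from \code{\link{assignContours}}.
#' @param timestamp acquisition label; an ISO-8601 time or a sequence
#'   index. Default "0".
#' @return data.frame with 5 rows and columns timestamp, finger,
#'   pixel_count, missing, R, G, B, eta_R, eta_G, eta_B.
#' @export
measureNails <- function(image, norm, assignment, timestamp = "0") {
  stopifnot(is(image, "RGBImage"), is(norm, "NormalizedImage"))
  if (!identical(dim(image@pixels), dim(norm@values)))
    stopInput("image and normalized image dimensions differ")
  h <- dim(image@pixels)[1]
  rows <- lapply(1:5, function(i) {
    ct <- assignment[[i]]
    if (is.null(ct))
      return(data.frame(timestamp = as.character(timestamp), finger = i,
                        pixel_count = 0L, missing = TRUE,
                        R = NA_real_, G = NA_real_, B = NA_real_,
                        eta_R = NA_real_, eta_G = NA_real_,
                        eta_B = NA_real_, stringsAsFactors = FALSE))
    idx <- ct@pixels[, 2] + 1L + h * ct@pixels[, 1]   # linear [y,x] index
    mr <- vapply(1:3, function(ch)
      mean(image@pixels[idx + (ch - 1L) * h * dim(image@pixels)[2]]),
      numeric(1))
    me <- vapply(1:3, function(ch)
      mean(norm@values[idx + (ch - 1L) * h * dim(norm@values)[2]]),
      numeric(1))
    data.frame(timestamp = as.character(timestamp), finger = i,
               pixel_count = ct@area, missing = FALSE,
               R = mr[1], G = mr[2], B = mr[3],
               eta_R = me[1], eta_G = me[2], eta_B = me[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Create an empty measurement history
#'
#' @return a \code{MeasurementHistory} with no acquisitions.
#' @export
newHistory <- function() new("MeasurementHistory", records = emptyRecords())

#' Append one acquisition to a history
#'
#' The only way records enter a history; each acquisition is the 5-row
#' data.frame produced by \code{\link{measureNails}}.
#'
#' @param history a \code{MeasurementHistory}.
#' @param measurement a 5-row measurement data.frame.
#' @return the extended \code{MeasurementHistory}.
#' @export
appendAcquisition <- function(history, measurement) {
  stopifnot(is(history, "MeasurementHistory"))
  if (!identical(names(measurement), historyColumns) ||
      nrow(measurement) != 5L)
    stopInput("measurement must be the 5-row frame from measureNails()")
  new("MeasurementHistory",
      records = rbind(history@records, measurement))
}

#' Export a measurement history as CSV
#'
#' One row per finger per acquisition; missing measurements carry empty
#' color cells.
#'
#' @param history a \code{MeasurementHistory}.
#' @param path output CSV path.
#' @return number of data rows written (5 x acquisitions).
#' @export
exportHistory <- function(history, path) {
  stopifnot(is(history, "MeasurementHistory"))
  r <- history@records
  num <- c("R", "G", "B", "eta_R", "eta_G", "eta_B")
  out <- r
  for (cn in num) out[[cn]] <- ifelse(is.na(r[[cn]]), "",
                                      sprintf("%.6f", r[[cn]]))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopInput("cannot write history CSV to ", path)
  nrow(r)
}

#' Read a measurement history back from CSV
#'
#' Inverse of \code{\link{exportHistory}}; empty color cells become NA and
#' the missing flag is restored.
#'
#' @param path CSV path written by \code{\link{exportHistory}}.
#' @return a \code{MeasurementHistory}.
#' @export
readHistory <- function(path) {
  if (!file.exists(path)) stopInput("no such history file: ", path)
  r <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(timestamp = "character"))
  if (!nrow(r)) return(newHistory())
  for (cn in c("R", "G", "B", "eta_R", "eta_G", "eta_B"))
    r[[cn]] <- suppressWarnings(as.numeric(r[[cn]]))
  r$missing <- as.logical(r$missing)
  r$finger <- as.integer(r$finger)
  r$pixel_count <- as.integer(r$pixel_count)
  new("MeasurementHistory", records = r[historyColumns])
}

#' Plot per-finger normalized color series
#'
#' Three curves (R, G, B on the 0-255 scale, from the normalized means)
#' per finger across acquisitions, one panel per finger; missing
#' measurements leave gaps.
#'
#' @param history a \code{MeasurementHistory} with >= 1 acquisition.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
plotHistory <- function(history, path) {
  stopifnot(is(history, "MeasurementHistory"))
  r <- history@records
  if (!nrow(r)) stopInput("history is empty; nothing to plot")
  n <- nrow(r) / 5L
  grDevices::png(path, width = 900, height = 600)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  for (i in 1:5) {
    ri <- r[r$finger == i, ]
    graphics::plot(NA, xlim = c(1, max(n, 2)), ylim = c(0, 255),
                   xlab = "acquisition", ylab = "normalized value x 255",
                   main = paste("finger", i))
    for (ch in c("eta_R", "eta_G", "eta_B"))
      graphics::lines(seq_len(n), 255 * ri[[ch]],
                      col = c(eta_R = "red", eta_G = "darkgreen",
                              eta_B = "blue")[[ch]])
  }
  invisible(path)
}
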