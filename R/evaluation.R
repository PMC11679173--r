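## Segmentation quality: IoU (Jaccard) and hard-mask Dice loss against
## ground-truth masks, per image and averaged over a paired directory
## dataset. Note the Dice loss here is the set complement 1 - 2|A^B|/(|A|+|B|)
## computed on hard masks, not a soft training-time loss; for any mask pair
## IoU <= Dice coefficient, with equality exactly at IoU 0 or 1.

#' Intersection over Union of two binary masks
#'
#' \code{|pred & gt| / |pred | gt|}; 1 when both masks are empty.
#'
#' @param pred,gt \code{BinaryMask}s of identical dimensions.
#' @return IoU in [0, 1].
#' @export
maskIoU <- function(pred, gt) {
  stopifnot(is(pred, "BinaryMask"), is(gt, "BinaryMask"))
  if (!identical(dim(pred@values), dim(gt@values)))
    stopInput("mask dimensions differ: ",
              paste(dim(pred@values), collapse = "x"), " vs ",
              paste(dim(gt@values), collapse = "x"))
  u <- sum(pred@values | gt@values)
  if (u == 0L) return(1)
  sum(pred@values & gt@values) / u
}

#' Dice loss of two binary masks
#'
#' \code{1 - 2 |pred & gt| / (|pred| + |gt|)}; 0 when both masks are empty.
#'
#' @param pred,gt \code{BinaryMask}s of identical dimensions.
#' @return Dice loss in [0, 1].
#' @export
diceLoss <- function(pred, gt) {
  stopifnot(is(pred, "BinaryMask"), is(gt, "BinaryMask"))
  if (!identical(dim(pred@values), dim(gt@values)))
    stopInput("mask dimensions differ: ",
              paste(dim(pred@values), collapse = "x"), " vs ",
              paste(dim(gt@values), collapse = "x"))
  s <- sum(pred@values) + sum(gt@values)
  if (s == 0L) return(0)
  1 - 2 * sum(pred@values & gt@values) / s
}

maskFileStem <- function(path) {
  sub("\\.[^.]*$", "", basename(path))
}

#' Evaluate a directory of predicted masks against ground truth
#'
#' Mask files are paired by filename stem (extension matching is
#' case-insensitive); an optional square erosion with side
#' \code{erode_filter} is applied to the predictions before scoring,
#' mirroring the mask clean-up the pipeline applies in production.
#'
#' @param pred_dir directory of predicted masks (single-channel PNG,
#'   0 = background, 255 = nail).
#' @param gt_dir directory of ground-truth masks, same stems.
#' @param erode_filter optional erosion side in pixels applied to
#'   predictions; NULL for none.
#' @param report optional CSV path; per-image rows plus a "mean" summary
#'   row are written there.
#' @param threshold binarization cut applied to the loaded masks,
#'   default 0.5.
#' @return an \code{EvalResult}.
#' @export
evaluateDataset <- function(pred_dir, gt_dir, erode_filter = NULL,
                            report = NULL, threshold = 0.5) {
  listMasks <- function(d) {
    if (!dir.exists(d)) stopInput("no such directory: ", d)
    f <- list.files(d, pattern = "\\.(png|PNG)$", full.names = TRUE)
    if (!length(f)) stopInput("no mask files found in ", d)
    sort(f)
  }
  pf <- listMasks(pred_dir)
  gf <- listMasks(gt_dir)
  ps <- maskFileStem(pf); gs <- maskFileStem(gf)
  orphans <- c(setdiff(ps, gs), setdiff(gs, ps))
  if (length(orphans))
    stopInput("unpaired mask file(s): ", paste(orphans, collapse = ", "))
  gf <- gf[match(ps, gs)]
  rows <- lapply(seq_along(pf), function(i) {
    pred <- binarize(loadMask(pf[i]), threshold)
    gt <- binarize(loadMask(gf[i]), threshold)
    if (!is.null(erode_filter) && erode_filter > 1L)
      pred <- erodeMask(pred, erode_filter)
    data.frame(image = ps[i], iou = maskIoU(pred, gt),
               dice_loss = diceLoss(pred, gt), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  res <- new("EvalResult", perImage = per, meanIoU = mean(per$iou),
             meanDiceLoss = mean(per$dice_loss),
             nImages = nrow(per))
  if (!is.null(report)) {
    out <- rbind(per, data.frame(image = "mean", iou = res@meanIoU,
                                 dice_loss = res@meanDiceLoss))
    utils::write.csv(out, report, row.names = FALSE)
  }
  res
}
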