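#' Match predicted regions to ground truth by one-pixel overlap
#'
#' A ground-truth cluster counts as detected (one TP) when at least one
#' predicted region shares at least one pixel with it; surplus predictions
#' overlapping an already-matched ground truth are ignored — neither TP nor
#' FP — because the aim is counting clusters, not localizing them.
#' Predictions overlapping no ground truth are FP; ground truths with no
#' overlapping prediction are FN. True negatives are not counted (they play
#' no role in precision/recall/F1).
#'
#' Matching is greedy over ground truths in their given (deterministic)
#' order; each prediction can be consumed by at most one ground truth, the
#' first in order that overlaps it.
#'
#' @param gt,pred lists of [region()] in one image frame.
#' @return An `fna_match_counts` object: list with integer `tp`, `fp`, `fn`,
#'   `ignored_preds`. Invariants: `tp + fn == length(gt)` and
#'   `tp + fp + ignored_preds == length(pred)`.
#' @export
#' @examples
#' gt <- list(region("i", bbox = c(0, 0, 10, 10)))
#' pr <- list(region("i", bbox = c(2, 2, 4, 4)), region("i", bbox = c(6, 6, 8, 8)))
#' match_regions(gt, pr)  # tp 1, fp 0, ignored 1
match_regions <- function(gt, pred) {
  n_gt <- length(gt); n_pr <- length(pred)
  overlaps <- matrix(FALSE, nrow = n_gt, ncol = n_pr)
  if (n_gt && n_pr)
    for (i in seq_len(n_gt))
      for (j in seq_len(n_pr))
        overlaps[i, j] <- region_overlap(gt[[i]], pred[[j]]) > 0L
  consumed <- rep(FALSE, n_pr)
  tp <- 0L
  for (i in seq_len(n_gt)) {
    j <- which(overlaps[i, ] & !consumed)
    if (length(j)) {
      consumed[j[1L]] <- TRUE
      tp <- tp + 1L
    }
  }
  pred_touches_gt <- if (n_gt) apply(overlaps, 2, any) else rep(FALSE, n_pr)
  ignored <- sum(pred_touches_gt & !consumed)
  fp <- sum(!pred_touches_gt)
  structure(list(tp = tp, fp = as.integer(fp), fn = n_gt - tp,
                 ignored_preds = as.integer(ignored)),
            class = "fna_match_counts")
}

#' @export
print.fna_match_counts <- function(x, ...) {
  cat(sprintf("<fna_match_counts tp=%d fp=%d fn=%d ignored=%d>\n",
              x$tp, x$fp, x$fn, x$ignored_preds))
  invisible(x)
}

#' Whole-image intersection-over-union
#'
#' IOU of the predicted foreground against the ground-truth foreground over
#' the whole image: `|gt AND pred| / |gt OR pred|`. An image with no ground
#' truth and no prediction carries no information and is excluded
#' (`NA_real_`) rather than scored; a false-positive-only image scores 0.
#'
#' @param gt_mask,pred_mask equal-shape logical (or 0/1) masks.
#' @return IOU in `[0, 1]`, or `NA_real_` when both masks are empty
#'   (excluded image).
#' @export
image_iou <- function(gt_mask, pred_mask) {
  gt_mask <- .as_logical_mask(gt_mask)
  pred_mask <- .as_logical_mask(pred_mask)
  if (!identical(dim(gt_mask), dim(pred_mask)))
    stop("gt and prediction masks must have identical shape")
  uni <- sum(gt_mask | pred_mask)
  if (uni == 0L) return(NA_real_)
  sum(gt_mask & pred_mask) / uni
}

#' Precision, recall and F1 from match counts
#'
#' `Precision = TP / (TP + FP)`, `Recall = TP / (TP + FN)`,
#' `F1 = 2 * Precision * Recall / (Precision + Recall)`. A metric whose
#' denominator is zero is undefined and reported as `NA_real_`, never
#' coerced to 0; F1 is 0 when both precision and recall are defined and 0.
#'
#' @param counts `fna_match_counts` (or any list with `tp`, `fp`, `fn`).
#' @return list with `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
        else if (precision + recall > 0) 2 * precision * recall / (precision + recall)
        else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' Aggregate per-fold metrics
#'
#' Mean and sample standard deviation (n - 1 denominator) of each metric
#' across cross-validation folds. Undefined/excluded entries (`NA`) are
#' dropped per metric, with the retained count reported and the drops
#' messaged.
#'
#' @param per_fold data.frame with one row per fold; every numeric column is
#'   treated as a metric.
#' @return data.frame with `metric`, `mean`, `sd`, `n`.
#' @export
aggregate_folds <- function(per_fold) {
  stopifnot(is.data.frame(per_fold), nrow(per_fold) >= 2L)
  metrics <- names(per_fold)[vapply(per_fold, is.numeric, logical(1))]
  out <- lapply(metrics, function(m) {
    v <- per_fold[[m]]
    n_dropped <- sum(is.na(v))
    if (n_dropped)
      message(sprintf("aggregate_folds: dropped %d undefined value(s) for %s",
                      n_dropped, m))
    v <- v[!is.na(v)]
    data.frame(metric = m,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2L) sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Evaluate one detector against ground truth over a set of images
#'
#' Sums match counts over the images (fold-level counting) and derives
#' precision/recall/F1 plus the mean whole-image IOU with excluded images
#' dropped.
#'
#' @param gt_regions named list (by image id) of ground-truth region lists.
#' @param detections named list (by image id) of `fna_detections`.
#' @param frames data.frame with `image_id`, `width`, `height` (needed for
#'   the IOU rasters).
#' @return list with `counts` (`fna_match_counts` summed over images),
#'   `precision`, `recall`, `f1`, `iou` (mean over non-excluded images),
#'   `n_iou_images`, and `per_image` data.frame.
#' @export
evaluate_detections <- function(gt_regions, detections, frames) {
  ids <- names(gt_regions)
  per_image <- lapply(ids, function(id) {
    det <- detections[[id]]
    preds <- if (is.null(det)) list() else det$regions
    m <- match_regions(gt_regions[[id]], preds)
    fr <- frames[frames$image_id == id, , drop = FALSE]
    iou <- image_iou(
      rasterize_regions(gt_regions[[id]], fr$width, fr$height),
      rasterize_regions(preds, fr$width, fr$height))
    data.frame(image_id = id, tp = m$tp, fp = m$fp, fn = m$fn,
               ignored_preds = m$ignored_preds, iou = iou,
               stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, per_image)
  counts <- structure(list(tp = sum(per_image$tp), fp = sum(per_image$fp),
                           fn = sum(per_image$fn),
                           ignored_preds = sum(per_image$ignored_preds)),
                      class = "fna_match_counts")
  prf <- precision_recall_f1(counts)
  ious <- per_image$iou[!is.na(per_image$iou)]
  c(list(counts = counts), prf,
    list(iou = if (length(ious)) mean(ious) else NA_real_,
         n_iou_images = length(ious), per_image = per_image))
}
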