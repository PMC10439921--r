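#' Slide adequacy classification and threshold-sweep screening
#'
#' A slide is called adequate when its predicted follicular-cluster count
#' reaches the user threshold; it is truly adequate when its ground-truth
#' count reaches the ground-truth threshold (6 per the standard adequacy
#' criterion, or 10 for a stricter one). The screening positive class is the
#' inadequate (non-diagnostic) slide: a TP is an inadequate slide correctly
#' flagged, so that recall measures how few non-diagnostic slides slip
#' through.
#'
#' @param pred_count predicted follicular-cluster count of the slide.
#' @param user_threshold minimum predicted count to call the slide adequate
#'   (>= 1).
#' @return `classify_slide`: `"adequate"` or `"inadequate"`.
#' @export
#' @examples
#' classify_slide(6, 6)  # adequate (>= threshold)
#' classify_slide(5, 6)  # inadequate
classify_slide <- function(pred_count, user_threshold) {
  stopifnot(user_threshold >= 1)
  if (pred_count >= user_threshold) "adequate" else "inadequate"
}

#' @rdname classify_slide
#' @param slides data.frame with columns `gt_count` and `pred_count`, one
#'   row per (bootstrapped) slide.
#' @param gt_threshold minimum true count defining an adequate slide.
#' @return `screen_confusion`: list with `tp`, `fp`, `fn`, `tn` (positive =
#'   inadequate), summing to `nrow(slides)`.
#' @export
screen_confusion <- function(slides, user_threshold, gt_threshold) {
  stopifnot(user_threshold >= 1, gt_threshold >= 1,
            all(c("gt_count", "pred_count") %in% names(slides)))
  truly_inadequate <- slides$gt_count < gt_threshold
  called_inadequate <- slides$pred_count < user_threshold
  list(tp = sum(truly_inadequate & called_inadequate),
       fp = sum(!truly_inadequate & called_inadequate),
       fn = sum(truly_inadequate & !called_inadequate),
       tn = sum(!truly_inadequate & !called_inadequate))
}

#' Sweep the user threshold and trace screening precision/recall/F1
#'
#' One screening confusion per user threshold. Raising the threshold flags
#' more slides inadequate, so recall (of inadequate slides) is
#' non-decreasing while precision typically falls; the sweep exposes the
#' precision-recall trade-off and the max-F1 operating point. Default sweep
#' ranges: 1..23 for ground-truth threshold 6 and 1..39 for 10.
#'
#' @inheritParams screen_confusion
#' @param thr_min,thr_max sweep bounds (inclusive); defaults depend on
#'   `gt_threshold`.
#' @return An `fna_threshold_curve`: list with `gt_threshold`, `points`
#'   (data.frame `user_threshold, tp, fp, fn, tn, precision, recall, f1`,
#'   `NA` where undefined), `auc` ([pr_auc()] of the points), `max_f1`
#'   (row of `points` attaining the largest defined F1), and `baseline`
#'   ([baseline_precision()]).
#' @export
threshold_sweep <- function(slides, gt_threshold,
                            thr_min = 1L,
                            thr_max = if (gt_threshold <= 6) 23L else 39L) {
  if (nrow(slides) == 0L) stop("empty slide set")
  stopifnot(thr_min >= 1L, thr_max >= thr_min)
  pts <- lapply(seq.int(thr_min, thr_max), function(t) {
    cm <- screen_confusion(slides, t, gt_threshold)
    prf <- precision_recall_f1(cm)
    data.frame(user_threshold = t, tp = cm$tp, fp = cm$fp, fn = cm$fn,
               tn = cm$tn, precision = prf$precision, recall = prf$recall,
               f1 = prf$f1)
  })
  points <- do.call(rbind, pts)
  max_f1 <- if (all(is.na(points$f1))) NULL
            else points[which.max(points$f1), , drop = FALSE]
  structure(list(gt_threshold = gt_threshold, points = points,
                 auc = tryCatch(pr_auc(points), error = function(e) NA_real_),
                 max_f1 = max_f1,
                 baseline = baseline_precision(slides, gt_threshold)),
            class = "fna_threshold_curve")
}

#' @export
print.fna_threshold_curve <- function(x, ...) {
  cat(sprintf("<fna_threshold_curve gt_threshold=%d: %d points, AUC=%.3f, baseline=%.3f>\n",
              x$gt_threshold, nrow(x$points), x$auc, x$baseline))
  if (!is.null(x$max_f1))
    cat(sprintf("  max F1 %.3f at user threshold %d (precision %.3f, recall %.3f)\n",
                x$max_f1$f1, x$max_f1$user_threshold,
                x$max_f1$precision, x$max_f1$recall))
  invisible(x)
}

#' Area under the screening precision-recall curve
#'
#' Trapezoidal integration over the sweep's (recall, precision) points.
#' Points with undefined precision are dropped; equal recalls are
#' deduplicated keeping the maximum precision; the leftmost point's
#' precision is extended horizontally to recall 0, and no extrapolation is
#' made beyond the largest attained recall.
#'
#' @param points data.frame with `precision` and `recall` columns (e.g. the
#'   `points` of a [threshold_sweep()]).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' pr_auc(data.frame(recall = c(0, 1), precision = c(1, 0.5)))  # 0.75
pr_auc <- function(points) {
  if (inherits(points, "fna_threshold_curve")) points <- points$points
  ok <- !is.na(points$precision) & !is.na(points$recall)
  if (!any(ok)) stop("no defined precision-recall points")
  r <- points$recall[ok]; p <- points$precision[ok]
  o <- order(r)
  r <- r[o]; p <- p[o]
  # deduplicate equal recalls, keeping max precision
  keep_p <- tapply(p, r, max)
  r <- as.numeric(names(keep_p)); p <- as.numeric(keep_p)
  if (r[1] > 0) { r <- c(0, r); p <- c(p[1], p) }
  if (length(r) == 1L) return(0)
  sum(diff(r) * (head(p, -1) + p[-1]) / 2)
}

#' @rdname classify_slide
#' @return `baseline_precision`: the prevalence of truly inadequate slides —
#'   the precision of the classifier that flags every slide inadequate (the
#'   flat baseline of the precision-recall plot).
#' @export
baseline_precision <- function(slides, gt_threshold) {
  stopifnot(nrow(slides) > 0)
  mean(slides$gt_count < gt_threshold)
}
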