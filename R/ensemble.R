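#' Ensemble two detectors by pixel-wise intersection
#'
#' The final detection set keeps only image area that both detectors marked:
#' the two detection sets are rasterized, intersected pixel-wise, and the
#' connected components of the intersection become the ensemble's regions.
#' Because every ensemble pixel lies in both inputs, the ensemble can only
#' shed false positives — the mechanism by which intersecting a
#' high-precision/low-recall detector with a high-recall/low-precision one
#' raises precision.
#'
#' @param det_a,det_b [image_detections()] for the same image.
#' @param width,height image frame in pixels.
#' @param connectivity 4 or 8 for the componentization of the intersection.
#' @param min_region_pixels drop intersected components smaller than this
#'   (default 1 = keep all).
#' @param detector_id name for the combined detector.
#' @return `fna_detections` whose regions are run-length masks.
#' @export
#' @examples
#' a <- image_detections("i", list(region("i", bbox = c(0, 0, 10, 10))), "A")
#' b <- image_detections("i", list(region("i", bbox = c(5, 5, 15, 15))), "B")
#' e <- intersect_detections(a, b, width = 20, height = 20)
#' region_area(e$regions[[1]])  # 25: the [5,10) x [5,10) square
intersect_detections <- function(det_a, det_b, width, height,
                                 connectivity = 8, min_region_pixels = 1L,
                                 detector_id = NULL) {
  if (det_a$image_id != det_b$image_id)
    stop(sprintf("image_id mismatch: %s vs %s", det_a$image_id, det_b$image_id))
  stopifnot(min_region_pixels >= 1L)
  ra <- rasterize_regions(det_a$regions, width, height)
  rb <- rasterize_regions(det_b$regions, width, height)
  inter <- ra & rb
  regs <- regions_from_mask(inter, image_id = det_a$image_id,
                            connectivity = connectivity)
  if (min_region_pixels > 1L)
    regs <- Filter(function(r) region_area(r) >= min_region_pixels, regs)
  if (is.null(detector_id))
    detector_id <- paste(det_a$detector_id, det_b$detector_id, sep = "+")
  image_detections(det_a$image_id, regs, detector_id = detector_id)
}

#' @rdname intersect_detections
#' @param dets_a,dets_b named lists of `fna_detections` (as returned by
#'   [read_detections()]); image ids must match pairwise.
#' @param frames data.frame with `image_id`, `width`, `height`.
#' @return `ensemble_detections`: named list of `fna_detections`.
#' @export
ensemble_detections <- function(dets_a, dets_b, frames, ...) {
  ids <- vapply(dets_a, function(d) d$image_id, character(1))
  ids_b <- vapply(dets_b, function(d) d$image_id, character(1))
  orphans <- c(setdiff(ids, ids_b), setdiff(ids_b, ids))
  if (length(orphans))
    stop(sprintf("image_id present in only one detector: %s",
                 paste(orphans, collapse = ", ")))
  out <- lapply(ids, function(id) {
    fr <- frames[frames$image_id == id, , drop = FALSE]
    if (nrow(fr) != 1L) stop(sprintf("no unique frame for image %s", id))
    intersect_detections(dets_a[[id]], dets_b[[id]],
                         width = fr$width, height = fr$height, ...)
  })
  names(out) <- ids
  out
}
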