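#' Detection regions
#'
#' A region is one countable follicular-cluster detection (predicted or
#' ground truth): a nonempty, connected set of pixels in a single image,
#' represented either as a bounding box or as a run-length-encoded binary
#' mask. Coordinates are 0-based; boxes are half-open
#' `[x_min, x_max) x [y_min, y_max)` so that the pixel area is
#' `(x_max - x_min) * (y_max - y_min)`.
#'
#' @param image_id character scalar, the image the region belongs to.
#' @param bbox numeric length-4 vector `c(x_min, y_min, x_max, y_max)`, or
#'   `NULL` when `rle` is given.
#' @param rle run-length encoding as produced by [rle_encode()]: a list with
#'   `size = c(height, width)` and integer `counts` (alternating
#'   background/foreground run lengths in column-major order, starting with
#'   background), or `NULL` when `bbox` is given.
#' @param score optional detection confidence in `[0, 1]`.
#'
#' @return An object of class `fna_region`.
#' @export
#' @examples
#' region("img1", bbox = c(0, 0, 10, 10))
region <- function(image_id, bbox = NULL, rle = NULL, score = NULL) {
  stopifnot(is.character(image_id), length(image_id) == 1L)
  if (is.null(bbox) == is.null(rle))
    stop("exactly one of bbox or rle must be given")
  if (!is.null(bbox)) {
    bbox <- as.numeric(bbox)
    if (length(bbox) != 4L || anyNA(bbox))
      stop("bbox must be c(x_min, y_min, x_max, y_max)")
    if (any(bbox[1:2] < 0))
      stop(sprintf("bbox for image %s has negative coordinates", image_id))
    if (bbox[3] <= bbox[1] || bbox[4] <= bbox[2])
      stop(sprintf(
        "degenerate bbox for image %s: need x_max > x_min and y_max > y_min, got [%s]",
        image_id, paste(bbox, collapse = ", ")))
  } else {
    if (!is.list(rle) || !all(c("size", "counts") %in% names(rle)))
      stop("rle must be a list with fields size and counts")
    if (sum(rle$counts) != prod(rle$size))
      stop("rle counts do not sum to size[1] * size[2]")
    if (sum(rle$counts[seq(2, length(rle$counts), by = 2)]) == 0)
      stop(sprintf("empty rle region for image %s", image_id))
  }
  if (!is.null(score)) {
    score <- as.numeric(score)
    stopifnot(length(score) == 1L, score >= 0, score <= 1)
  }
  structure(list(image_id = image_id, bbox = bbox, rle = rle, score = score),
            class = "fna_region")
}

#' @export
print.fna_region <- function(x, ...) {
  bb <- region_bbox(x)
  cat(sprintf("<fna_region %s: %s bbox=[%g,%g,%g,%g) area=%d%s>\n",
              x$image_id, if (is.null(x$rle)) "bbox" else "rle",
              bb[1], bb[2], bb[3], bb[4], region_area(x),
              if (is.null(x$score)) "" else sprintf(" score=%.3f", x$score)))
  invisible(x)
}

#' Run-length encode / decode a binary mask
#'
#' Column-major run-length encoding: `counts` alternates background and
#' foreground run lengths, starting with background (a leading 0 when the
#' first pixel is foreground), like the COCO mask convention.
#'
#' @param mask logical (or 0/1) matrix, `nrow` = height, `ncol` = width.
#' @return `rle_encode`: list with `size = c(height, width)` and `counts`.
#' @export
rle_encode <- function(mask) {
  mask <- .as_logical_mask(mask)
  r <- rle(as.vector(mask))
  counts <- r$lengths
  if (length(r$values) == 0L || r$values[1L]) counts <- c(0L, counts)
  list(size = c(nrow(mask), ncol(mask)), counts = as.integer(counts))
}

#' @rdname rle_encode
#' @param x an encoding produced by `rle_encode`.
#' @return `rle_decode`: the logical mask.
#' @export
rle_decode <- function(x) {
  vals <- rep(rep(c(FALSE, TRUE), length.out = length(x$counts)), x$counts)
  matrix(vals, nrow = x$size[1], ncol = x$size[2])
}

#' @rdname region
#' @param r an `fna_region`.
#' @return `region_bbox`: `c(x_min, y_min, x_max, y_max)` (tight for rle
#'   regions); `region_area`: the pixel count.
#' @export
region_bbox <- function(r) {
  if (!is.null(r$bbox)) return(r$bbox)
  if (!is.null(r$.bbox_cache)) return(r$.bbox_cache)
  m <- rle_decode(r$rle)
  idx <- which(m, arr.ind = TRUE)
  c(min(idx[, 2]) - 1, min(idx[, 1]) - 1, max(idx[, 2]), max(idx[, 1]))
}

#' @rdname region
#' @export
region_area <- function(r) {
  if (!is.null(r$bbox))
    return(as.integer((r$bbox[3] - r$bbox[1]) * (r$bbox[4] - r$bbox[2])))
  ct <- r$rle$counts
  as.integer(sum(ct[seq(2, length(ct), by = 2)]))
}

# Region's pixel mask restricted to a window [x0, x1) x [y0, y1), 0-based.
.region_window_mask <- function(r, x0, y0, x1, y1) {
  wm <- matrix(FALSE, nrow = y1 - y0, ncol = x1 - x0)
  if (!is.null(r$bbox)) {
    bx0 <- max(r$bbox[1], x0); by0 <- max(r$bbox[2], y0)
    bx1 <- min(r$bbox[3], x1); by1 <- min(r$bbox[4], y1)
    if (bx1 > bx0 && by1 > by0)
      wm[(by0 - y0 + 1):(by1 - y0), (bx0 - x0 + 1):(bx1 - x0)] <- TRUE
  } else {
    m <- rle_decode(r$rle)
    sy0 <- max(y0, 0); sx0 <- max(x0, 0)
    sy1 <- min(y1, nrow(m)); sx1 <- min(x1, ncol(m))
    if (sy1 > sy0 && sx1 > sx0)
      wm[(sy0 - y0 + 1):(sy1 - y0), (sx0 - x0 + 1):(sx1 - x0)] <-
        m[(sy0 + 1):sy1, (sx0 + 1):sx1]
  }
  wm
}

#' Number of pixels shared by two regions
#'
#' The matching rule counts a predicted region as overlapping a ground-truth
#' region when they share at least one pixel; this computes the exact shared
#' pixel count (bbox-bbox overlaps in closed form, anything involving an rle
#' mask by rasterizing the bbox-intersection window).
#'
#' @param a,b `fna_region` objects in the same image frame.
#' @return integer pixel count (0 when disjoint).
#' @export
region_overlap <- function(a, b) {
  ba <- region_bbox(a); bb <- region_bbox(b)
  x0 <- max(ba[1], bb[1]); y0 <- max(ba[2], bb[2])
  x1 <- min(ba[3], bb[3]); y1 <- min(ba[4], bb[4])
  if (x1 <= x0 || y1 <= y0) return(0L)
  if (!is.null(a$bbox) && !is.null(b$bbox))
    return(as.integer((x1 - x0) * (y1 - y0)))
  ma <- .region_window_mask(a, x0, y0, x1, y1)
  mb <- .region_window_mask(b, x0, y0, x1, y1)
  sum(ma & mb)
}

#' Rasterize regions onto an image frame
#'
#' Foreground is the union of the regions' pixel sets. Errors if any region
#' extends outside the frame (silent clipping would corrupt counts).
#'
#' @param regions list of `fna_region`.
#' @param width,height frame size in pixels.
#' @return logical `height x width` matrix.
#' @export
rasterize_regions <- function(regions, width, height) {
  out <- matrix(FALSE, nrow = height, ncol = width)
  for (r in regions) {
    bb <- region_bbox(r)
    if (bb[1] < 0 || bb[2] < 0 || bb[3] > width || bb[4] > height)
      stop(sprintf("region in image %s out of %dx%d frame: [%s]",
                   r$image_id, width, height, paste(bb, collapse = ", ")))
    out <- out | .region_window_mask(r, 0L, 0L, width, height)
  }
  out
}

#' Extract regions as connected components of a binary mask
#'
#' Each connected component of the foreground becomes one `fna_region`
#' (run-length representation). Components are ordered row-major by their
#' top-left pixel, so the output is deterministic.
#'
#' @param mask logical (or 0/1) matrix.
#' @param image_id image identifier stamped on the regions.
#' @param connectivity 4 or 8 (default 8, merging diagonal stitching
#'   artifacts into one detection).
#' @return list of `fna_region` (empty for an all-background mask).
#' @export
regions_from_mask <- function(mask, image_id = "image", connectivity = 8) {
  mask <- .as_logical_mask(mask)
  lab <- .label_components(mask, as.integer(connectivity))
  k <- max(lab)
  if (k == 0L) return(list())
  lapply(seq_len(k), function(i) {
    comp <- lab == i
    r <- region(image_id, rle = rle_encode(comp))
    idx <- which(comp, arr.ind = TRUE)
    r$.bbox_cache <- c(min(idx[, 2]) - 1, min(idx[, 1]) - 1,
                       max(idx[, 2]), max(idx[, 1]))
    r
  })
}
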