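#' Patch grids over a whole image
#'
#' Whole-slide images are cropped into square patches (default 256x256) with
#' 50% overlap (stride 128). Anchors are the 0-based top-left corners, laid
#' out at every multiple of `stride` along each axis; when the last multiple
#' does not reach the image edge, one extra edge-snapped anchor at
#' `dim - patch_size` is appended so every pixel is covered without padding.
#'
#' @param width,height image size in pixels; must be >= `patch_size`.
#' @param patch_size patch side length (default 256).
#' @param stride anchor spacing, `1 <= stride <= patch_size` (default 128,
#'   i.e. 50% overlap).
#' @return An object of class `fna_patch_grid`: list with `width`, `height`,
#'   `patch_size`, `stride` and `anchors` (data.frame of `x`, `y`, row-major
#'   order).
#' @export
#' @examples
#' g <- make_patch_grid(512, 512)   # 3 x 3 = 9 anchors
#' nrow(g$anchors)
make_patch_grid <- function(width, height, patch_size = 256L, stride = 128L) {
  width <- as.integer(width); height <- as.integer(height)
  patch_size <- as.integer(patch_size); stride <- as.integer(stride)
  if (patch_size > min(width, height))
    stop(sprintf("patch_size %d exceeds image %dx%d (no implicit padding)",
                 patch_size, width, height))
  if (stride < 1L || stride > patch_size)
    stop("stride must satisfy 1 <= stride <= patch_size")
  axis_anchors <- function(dim) {
    last <- dim - patch_size
    a <- seq.int(0L, last, by = stride)
    if (a[length(a)] < last) a <- c(a, last)  # edge-snapped anchor
    a
  }
  xs <- axis_anchors(width)
  ys <- axis_anchors(height)
  anchors <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)[, c("x", "y")]
  anchors <- anchors[order(anchors$y, anchors$x), , drop = FALSE]
  rownames(anchors) <- NULL
  structure(list(width = width, height = height, patch_size = patch_size,
                 stride = stride, anchors = anchors),
            class = "fna_patch_grid")
}

#' @export
print.fna_patch_grid <- function(x, ...) {
  cat(sprintf("<fna_patch_grid %dx%d: %d anchors (patch %d, stride %d)>\n",
              x$width, x$height, nrow(x$anchors), x$patch_size, x$stride))
  invisible(x)
}

#' Patch positivity cutoff
#'
#' The integer foreground-area cutoff above which (strictly) a patch counts
#' as containing a follicular cluster: `floor(fraction * patch_size^2)`,
#' which is 655 pixels at the 256-pixel patch and 1% defaults.
#'
#' @param patch_size patch side length.
#' @param fraction area fraction (default 0.01).
#' @return integer cutoff.
#' @export
positivity_pixels <- function(patch_size = 256L, fraction = 0.01) {
  as.integer(floor(fraction * as.numeric(patch_size)^2))
}

#' Label one patch from its ground-truth mask crop
#'
#' A patch is `"follicular"` iff its foreground pixel count strictly exceeds
#' `positivity_pixels` (so 656 foreground pixels are positive at defaults,
#' 655 are not).
#'
#' @param gt_mask_patch logical (or 0/1) square matrix of side `patch_size`.
#' @param positivity_pixels strict cutoff; default [positivity_pixels()] of
#'   the patch side.
#' @return `"follicular"` or `"background"`.
#' @export
label_patch <- function(gt_mask_patch,
                        positivity_pixels = fnascreen::positivity_pixels(nrow(gt_mask_patch))) {
  gt_mask_patch <- .as_logical_mask(gt_mask_patch)
  if (nrow(gt_mask_patch) != ncol(gt_mask_patch))
    stop(sprintf("patch must be square, got %dx%d",
                 nrow(gt_mask_patch), ncol(gt_mask_patch)))
  if (sum(gt_mask_patch) > positivity_pixels) "follicular" else "background"
}

#' Label every patch of a grid against a full-image mask
#'
#' @param grid [make_patch_grid()] result.
#' @param mask full-image ground-truth mask (dims must match the grid).
#' @param positivity_fraction area fraction for the strict cutoff.
#' @return An `fna_patch_labels` object: the grid plus a character vector
#'   `labels`, one per anchor.
#' @export
label_patches <- function(grid, mask, positivity_fraction = 0.01) {
  mask <- .as_logical_mask(mask)
  if (nrow(mask) != grid$height || ncol(mask) != grid$width)
    stop("mask dimensions do not match grid frame")
  cutoff <- positivity_pixels(grid$patch_size, positivity_fraction)
  p <- grid$patch_size
  labels <- vapply(seq_len(nrow(grid$anchors)), function(i) {
    x <- grid$anchors$x[i]; y <- grid$anchors$y[i]
    patch <- mask[(y + 1):(y + p), (x + 1):(x + p)]
    label_patch(patch, cutoff)
  }, character(1))
  structure(list(grid = grid, labels = labels), class = "fna_patch_labels")
}

#' Stitch patch labels back into a full-image detection mask
#'
#' A pixel is foreground iff it lies inside at least one patch labeled
#' `"follicular"` (union rule), reproducing how patch-wise classifications
#' are assembled into one whole-image detection result.
#'
#' @param label_map [label_patches()] result, or a grid plus `labels`.
#' @return logical `height x width` matrix.
#' @export
stitch_patch_labels <- function(label_map) {
  grid <- label_map$grid
  labels <- label_map$labels
  if (length(labels) != nrow(grid$anchors))
    stop("one label per anchor required")
  out <- matrix(FALSE, nrow = grid$height, ncol = grid$width)
  p <- grid$patch_size
  for (i in which(labels == "follicular")) {
    x <- grid$anchors$x[i]; y <- grid$anchors$y[i]
    out[(y + 1):(y + p), (x + 1):(x + p)] <- TRUE
  }
  out
}
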