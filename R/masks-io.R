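#' Read and write binary ground-truth masks
#'
#' Masks are stored as 8-bit grayscale PNG with foreground (follicular
#' cluster) white = 255 and background black = 0. On read, any nonzero pixel
#' of a strictly binary raster is foreground; rasters with intermediate
#' values are rejected unless `binarize = TRUE`, in which case values >= 128
#' (0.5 in the PNG unit scale) become foreground.
#'
#' @param mask logical (or 0/1) matrix, `nrow` = height, `ncol` = width.
#' @param path PNG file path (TIFF also readable when the tiff package is
#'   installed).
#' @param binarize allow non-binary input rasters, thresholding at >= 128.
#' @return `read_mask`: logical matrix.
#' @export
write_mask <- function(mask, path) {
  mask <- .as_logical_mask(mask)
  png::writePNG(mask * 1.0, path)  # 0 / 255 in the 8-bit file
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, binarize = FALSE) {
  img <- read_raster(path)
  vals <- unique(as.vector(img))
  if (!all(vals %in% c(0, 1))) {
    if (!binarize)
      stop(sprintf(
        "raster %s has %d distinct values; not a binary mask (set binarize = TRUE to threshold at >= 128)",
        path, length(vals)))
    return(img >= 128 / 255)
  }
  img > 0
}

#' Read a grayscale raster
#'
#' Reads PNG (always) or TIFF (when the tiff package is installed) into a
#' numeric matrix in `[0, 1]`, `nrow` = height. RGB input is averaged to
#' grayscale.
#'
#' @param path file path; format chosen by extension.
#' @return numeric matrix.
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}

#' @rdname read_raster
#' @param raster numeric matrix in `[0, 1]`.
#' @export
write_raster <- function(raster, path) {
  stopifnot(is.matrix(raster))
  png::writePNG(pmin(pmax(raster, 0), 1), path)
  invisible(path)
}
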