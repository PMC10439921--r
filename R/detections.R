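#' Per-image detection sets
#'
#' All regions one detector emitted for one image.
#'
#' @param image_id character scalar.
#' @param regions list of [region()] objects; each must carry `image_id`.
#' @param detector_id character scalar naming the detector.
#' @return An object of class `fna_detections`.
#' @export
image_detections <- function(image_id, regions = list(), detector_id = "detector") {
  stopifnot(is.character(image_id), length(image_id) == 1L, is.list(regions))
  for (r in regions) {
    if (!inherits(r, "fna_region")) stop("regions must be fna_region objects")
    if (r$image_id != image_id)
      stop(sprintf("region image_id %s does not match %s", r$image_id, image_id))
  }
  structure(list(image_id = image_id, detector_id = detector_id,
                 regions = regions),
            class = "fna_detections")
}

#' @export
print.fna_detections <- function(x, ...) {
  cat(sprintf("<fna_detections %s/%s: %d region(s)>\n",
              x$detector_id, x$image_id, length(x$regions)))
  invisible(x)
}

.region_to_json <- function(r) {
  out <- list()
  if (!is.null(r$bbox)) out$bbox <- as.numeric(r$bbox)
  if (!is.null(r$rle)) out$rle <- list(size = as.integer(r$rle$size),
                                       counts = as.integer(r$rle$counts))
  if (!is.null(r$score)) out$score <- r$score
  out
}

.region_from_json <- function(rec, image_id, strict) {
  known <- c("bbox", "rle", "score")
  extra <- setdiff(names(rec), known)
  if (length(extra) && strict)
    stop(sprintf("unknown field(s) %s in region of image %s",
                 paste(extra, collapse = ", "), image_id))
  region(image_id,
         bbox = rec$bbox,
         rle = if (!is.null(rec$rle))
           list(size = as.integer(unlist(rec$rle$size)),
                counts = as.integer(unlist(rec$rle$counts))),
         score = rec$score)
}

#' Read and write detection JSON
#'
#' Detection files hold one detector's regions for a set of images:
#' `{"detector_id": ..., "images": [{"image_id": ..., "regions":
#' [{"bbox": [x_min, y_min, x_max, y_max], "score": ...} | {"rle": ...}]}]}`.
#' The round trip `read_detections(write_detections(x))` is lossless.
#'
#' @param detections list of [image_detections()] (one per image, unique ids),
#'   all from the same detector.
#' @param path file path.
#' @param strict reject unknown fields and malformed records (default); when
#'   `FALSE`, unknown region fields are dropped with a warning.
#' @return `read_detections`: named list of `fna_detections`, names =
#'   image ids.
#' @export
write_detections <- function(detections, path) {
  stopifnot(is.list(detections))
  ids <- vapply(detections, function(d) d$image_id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate image_id in detections: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  det_id <- if (length(detections)) detections[[1]]$detector_id else "detector"
  doc <- list(
    detector_id = det_id,
    images = lapply(detections, function(d) list(
      image_id = d$image_id,
      regions = lapply(d$regions, .region_to_json))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path, strict = TRUE) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$images)) stop("detection JSON lacks an 'images' array")
  det_id <- if (is.null(doc$detector_id)) "detector" else doc$detector_id
  out <- lapply(doc$images, function(im) {
    if (is.null(im$image_id)) stop("detection record without image_id")
    regions <- lapply(im$regions, function(rec) {
      if (!is.null(rec$bbox)) rec$bbox <- as.numeric(unlist(rec$bbox))
      if (!strict) {
        extra <- setdiff(names(rec), c("bbox", "rle", "score"))
        if (length(extra)) {
          warning(sprintf("dropping unknown field(s) %s in image %s",
                          paste(extra, collapse = ", "), im$image_id))
          rec <- rec[setdiff(names(rec), extra)]
        }
      }
      .region_from_json(rec, im$image_id, strict = strict)
    })
    image_detections(im$image_id, regions, detector_id = det_id)
  })
  names(out) <- vapply(out, function(d) d$image_id, character(1))
  out
}
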