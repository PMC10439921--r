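#' Dataset manifests
#'
#' A manifest is the bookkeeping table of a whole-image dataset: one row per
#' image with its patient, cross-validation group, size, class label
#' (`follicular` when the ground-truth mask has at least one foreground
#' pixel, else `background`) and file paths. CSV columns: `image_id,
#' patient_id, group_id, class_label, width, height, image_path, mask_path`.
#'
#' @param path CSV path.
#' @return A `data.frame` of class `fna_manifest` with the columns above and
#'   attributes `patch_size`, `stride`, `positivity_fraction` (tiling
#'   defaults recorded with the dataset).
#' @export
load_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("image_id", "patient_id", "group_id", "class_label",
                "width", "height", "image_path", "mask_path")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("manifest %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")))
  df$width <- as.integer(df$width)
  df$height <- as.integer(df$height)
  validate_manifest(df)
  if (nrow(df) == 0L) warning(sprintf("manifest %s is empty", path))
  else message(sprintf(
    "manifest %s: %d images (%d follicular / %d background) in %d group(s), %d patient(s)",
    path, nrow(df), sum(df$class_label == "follicular"),
    sum(df$class_label == "background"),
    length(unique(df$group_id)), length(unique(df$patient_id))))
  structure(df, class = c("fna_manifest", "data.frame"),
            patch_size = 256L, stride = 128L, positivity_fraction = 0.01)
}

#' @rdname load_manifest
#' @param manifest manifest data.frame.
#' @export
validate_manifest <- function(manifest) {
  probs <- character()
  dup <- unique(manifest$image_id[duplicated(manifest$image_id)])
  if (length(dup))
    probs <- c(probs, sprintf("duplicate image_id: %s", paste(dup, collapse = ", ")))
  bad <- setdiff(unique(manifest$class_label), c("follicular", "background"))
  if (length(bad))
    probs <- c(probs, sprintf("unknown class_label: %s", paste(bad, collapse = ", ")))
  if (nrow(manifest) && any(manifest$width < 1 | manifest$height < 1, na.rm = TRUE))
    probs <- c(probs, "width and height must be >= 1")
  if (length(probs)) stop(paste(probs, collapse = "; "))
  invisible(manifest)
}

#' @rdname load_manifest
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.csv(as.data.frame(manifest), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-group, per-class image counts of a manifest
#'
#' @param manifest manifest data.frame.
#' @return data.frame with `group_id`, `follicular`, `background`, `total`.
#' @export
manifest_counts <- function(manifest) {
  tab <- table(manifest$group_id, manifest$class_label)
  groups <- rownames(tab)
  fol <- if ("follicular" %in% colnames(tab)) as.integer(tab[, "follicular"]) else 0L
  bg <- if ("background" %in% colnames(tab)) as.integer(tab[, "background"]) else 0L
  data.frame(group_id = groups, follicular = fol, background = bg,
             total = fol + bg, stringsAsFactors = FALSE)
}
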