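#' Synthetic FNA fixture generator
#'
#' Generates datasets with the study's structure — by default 7
#' cross-validation groups of 33 background + 8 follicular images (287
#' total) attributed round-robin to 6 patients — with elliptical
#' follicular-cluster blobs as ground truth. Images are parametric: the
#' fixture stores each image's blob parameters and renders masks/rasters on
#' demand, so native-scale frames need not be held in memory.
#'
#' @param n_groups number of cross-validation groups (default 7).
#' @param n_background_per_group,n_follicular_per_group images per group by
#'   class (defaults 33 and 8).
#' @param n_patients patients the images are attributed to (default 6).
#' @param width,height image frame in pixels (default 2592 x 1944; pass
#'   e.g. 512 x 512 for desk-scale work).
#' @param blob_count_range min/max blobs per follicular image (default 1-3).
#' @param blob_area_range min/max blob area in pixels (default 1000-30000;
#'   the minimum must exceed the patch positivity cutoff so no follicular
#'   image is undetectable by the tiling rule).
#' @param bg_mean,bg_sd,blob_mean,blob_sd intensity model on the `[0, 1]`
#'   grayscale (Gaussian background noise, brighter blobs).
#' @param seed integer seed.
#' @return `fixture_config`: an `fna_fixture_config` object.
#' @export
fixture_config <- function(n_groups = 7L, n_background_per_group = 33L,
                           n_follicular_per_group = 8L, n_patients = 6L,
                           width = 2592L, height = 1944L,
                           blob_count_range = c(1L, 3L),
                           blob_area_range = c(1000, 30000),
                           bg_mean = 0.2, bg_sd = 0.05,
                           blob_mean = 0.7, blob_sd = 0.05,
                           seed = 1L) {
  stopifnot(n_groups >= 1L, n_background_per_group >= 0L,
            n_follicular_per_group >= 0L, n_patients >= 1L,
            blob_area_range[1] > 0, blob_area_range[2] >= blob_area_range[1],
            blob_count_range[1] >= 1L)
  # a blob must fit inside the frame: bounding box of the largest ellipse
  max_diam <- 2 * sqrt(blob_area_range[2] * 2.5 / pi)
  if (max_diam > min(width, height))
    stop(sprintf(
      "blob_area_range upper bound %g incompatible with %dx%d frame",
      blob_area_range[2], width, height))
  structure(list(n_groups = as.integer(n_groups),
                 n_background_per_group = as.integer(n_background_per_group),
                 n_follicular_per_group = as.integer(n_follicular_per_group),
                 n_patients = as.integer(n_patients),
                 width = as.integer(width), height = as.integer(height),
                 blob_count_range = as.integer(blob_count_range),
                 blob_area_range = as.numeric(blob_area_range),
                 bg_mean = bg_mean, bg_sd = bg_sd,
                 blob_mean = blob_mean, blob_sd = blob_sd,
                 seed = as.integer(seed)),
            class = "fna_fixture_config")
}

.render_ellipse_mask <- function(blobs, width, height) {
  mask <- matrix(FALSE, nrow = height, ncol = width)
  for (b in blobs) {
    x0 <- max(0L, floor(b$cx - b$a)); x1 <- min(width - 1L, ceiling(b$cx + b$a))
    y0 <- max(0L, floor(b$cy - b$b)); y1 <- min(height - 1L, ceiling(b$cy + b$b))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    # pixel centers at integer coordinates
    dx2 <- ((xs - b$cx) / b$a)^2
    dy2 <- ((ys - b$cy) / b$b)^2
    inside <- outer(dy2, dx2, "+") <= 1
    mask[ys + 1L, xs + 1L] <- mask[ys + 1L, xs + 1L] | inside
  }
  mask
}

#' Generate a synthetic fixture
#'
#' @param cfg [fixture_config()].
#' @return An `fna_fixture`: list with `config`, `manifest` (in-memory
#'   manifest data.frame; paths filled in by [write_fixture()]), and `blobs`
#'   (per-image ellipse parameter lists). Use [fixture_mask()],
#'   [fixture_raster()] and [fixture_gt_regions()] to materialize images.
#' @export
#' @examples
#' fx <- generate_fixture(fixture_config(width = 512, height = 512,
#'                                       blob_area_range = c(800, 8000)))
#' nrow(fx$manifest)  # 287
generate_fixture <- function(cfg = fixture_config()) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  per_group <- cfg$n_background_per_group + cfg$n_follicular_per_group
  n_total <- cfg$n_groups * per_group
  rows <- vector("list", n_total)
  blobs <- vector("list", n_total)
  k <- 0L
  for (g in seq_len(cfg$n_groups)) {
    classes <- c(rep("follicular", cfg$n_follicular_per_group),
                 rep("background", cfg$n_background_per_group))
    for (cl in classes) {
      k <- k + 1L
      id <- sprintf("img_%03d", k)
      bl <- list()
      if (cl == "follicular") {
        n_blob <- sample.int(cfg$blob_count_range[2] - cfg$blob_count_range[1] + 1L,
                             1L) + cfg$blob_count_range[1] - 1L
        # blobs are placed with a minimum bbox separation so each cluster is
        # a distinct, unambiguous detection target (no near-touching pairs)
        sep <- 40
        for (j in seq_len(n_blob)) {
          area <- runif(1, cfg$blob_area_range[1], cfg$blob_area_range[2])
          aspect <- runif(1, 1, 2.5)
          a <- sqrt(area * aspect / pi)   # semi-axes; pi*a*b = area
          b <- a / aspect
          for (try in 1:100) {
            cand <- list(cx = runif(1, a + 1, cfg$width - a - 2),
                         cy = runif(1, b + 1, cfg$height - b - 2),
                         a = a, b = b)
            clear <- all(vapply(bl, function(o) {
              abs(cand$cx - o$cx) > cand$a + o$a + sep ||
                abs(cand$cy - o$cy) > cand$b + o$b + sep
            }, logical(1)))
            if (clear) { bl[[length(bl) + 1L]] <- cand; break }
          }
        }
      }
      rows[[k]] <- data.frame(
        image_id = id,
        patient_id = sprintf("patient_%d", ((k - 1L) %% cfg$n_patients) + 1L),
        group_id = sprintf("group_%d", g),
        class_label = cl,
        width = cfg$width, height = cfg$height,
        image_path = paste0(id, ".png"),
        mask_path = paste0(id, "_mask.png"),
        stringsAsFactors = FALSE)
      blobs[[k]] <- bl
    }
  }
  manifest <- do.call(rbind, rows)
  validate_manifest(manifest)
  fx <- structure(list(config = cfg, manifest = manifest,
                       blobs = setNames(blobs, manifest$image_id)),
                  class = "fna_fixture")
  fx
}

#' @rdname generate_fixture
#' @param fixture an `fna_fixture`.
#' @param image_id image to materialize.
#' @return `fixture_mask`: the ground-truth logical mask.
#' @export
fixture_mask <- function(fixture, image_id) {
  .render_ellipse_mask(fixture$blobs[[image_id]],
                       fixture$config$width, fixture$config$height)
}

#' @rdname generate_fixture
#' @return `fixture_gt_regions`: list of ground-truth [region()]s (connected
#'   components of the mask; overlapping blobs merge into one region).
#' @export
fixture_gt_regions <- function(fixture, image_id) {
  if (length(fixture$blobs[[image_id]]) == 0L) return(list())
  regions_from_mask(fixture_mask(fixture, image_id), image_id = image_id)
}

#' @rdname generate_fixture
#' @return `fixture_raster`: the grayscale image (background noise plus
#'   brighter blob interiors), deterministic per image id.
#' @export
fixture_raster <- function(fixture, image_id) {
  cfg <- fixture$config
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  # per-image deterministic stream (seed kept below 2^31)
  set.seed((cfg$seed + 7919L * match(image_id, fixture$manifest$image_id)) %% .Machine$integer.max)
  img <- matrix(rnorm(cfg$height * cfg$width, cfg$bg_mean, cfg$bg_sd),
                nrow = cfg$height, ncol = cfg$width)
  mask <- fixture_mask(fixture, image_id)
  if (any(mask))
    img[mask] <- rnorm(sum(mask), cfg$blob_mean, cfg$blob_sd)
  pmin(pmax(img, 0), 1)
}

#' @rdname generate_fixture
#' @param dir output directory (created if needed).
#' @return `write_fixture`: the directory, after writing every image PNG,
#'   mask PNG and `manifest.csv`.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- fixture$manifest
  man$image_path <- file.path(dir, man$image_path)
  man$mask_path <- file.path(dir, man$mask_path)
  for (i in seq_len(nrow(man))) {
    id <- man$image_id[i]
    write_raster(fixture_raster(fixture, id), man$image_path[i])
    write_mask(fixture_mask(fixture, id), man$mask_path[i])
  }
  write_manifest(man, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Simulated detectors with controllable error character
#'
#' @param p_detect probability each ground-truth region is detected.
#' @param fp_rate mean number of spurious (false-positive) regions per image
#'   (Poisson-distributed count).
#' @param dilate_px enlarge each emitted box by this margin
#'   (over-segmentation).
#' @param jitter_px translate each emitted box by a uniform offset in
#'   `[-jitter_px, jitter_px]` per axis; overlap with the source region is
#'   preserved when `jitter_px` is smaller than the region's width/height.
#' @param fp_size_range pixel side-length range of spurious boxes.
#' @param fp_clearance_px minimum gap kept between a spurious box and every
#'   ground-truth bbox, so a simulated false positive is genuinely spurious
#'   rather than a halo artifact of an over-segmented true detection. When
#'   detectors are paired, the clearance must cover the largest halo either
#'   detector can produce (see [make_paired_detectors()]); the default
#'   covers this detector's own `dilate_px + jitter_px` plus 2.
#' @return `detector_error_model`: an `fna_detector_model`.
#' @export
detector_error_model <- function(p_detect = 0.8, fp_rate = 1,
                                 dilate_px = 0L, jitter_px = 0L,
                                 fp_size_range = c(10L, 40L),
                                 fp_clearance_px = dilate_px + jitter_px + 2L) {
  stopifnot(p_detect >= 0, p_detect <= 1, fp_rate >= 0,
            dilate_px >= 0L, jitter_px >= 0L, fp_clearance_px >= 0L)
  structure(list(p_detect = p_detect, fp_rate = fp_rate,
                 dilate_px = as.integer(dilate_px),
                 jitter_px = as.integer(jitter_px),
                 fp_size_range = as.integer(fp_size_range),
                 fp_clearance_px = as.integer(fp_clearance_px)),
            class = "fna_detector_model")
}

#' @rdname detector_error_model
#' @param gt_regions list of ground-truth [region()]s for one image.
#' @param model `fna_detector_model`.
#' @param width,height image frame.
#' @param image_id image id for the emitted detections.
#' @param detector_id detector name.
#' @return `simulate_detector`: `fna_detections` with bbox regions; uses the
#'   current RNG state (seed upstream for reproducibility).
#' @export
simulate_detector <- function(gt_regions, model, width, height,
                              image_id = "image", detector_id = "sim") {
  regs <- list()
  for (g in gt_regions) {
    if (rbinom(1, 1, model$p_detect) == 0) next
    bb <- region_bbox(g)
    d <- model$dilate_px
    w_box <- bb[3] - bb[1]; h_box <- bb[4] - bb[2]
    jx <- if (model$jitter_px > 0)
      sample.int(2L * min(model$jitter_px, w_box - 1L) + 1L, 1L) -
        min(model$jitter_px, w_box - 1L) - 1L else 0L
    jy <- if (model$jitter_px > 0)
      sample.int(2L * min(model$jitter_px, h_box - 1L) + 1L, 1L) -
        min(model$jitter_px, h_box - 1L) - 1L else 0L
    nb <- c(max(0, bb[1] - d + jx), max(0, bb[2] - d + jy),
            min(width, bb[3] + d + jx), min(height, bb[4] + d + jy))
    if (nb[3] > nb[1] && nb[4] > nb[2])
      regs[[length(regs) + 1L]] <- region(image_id, bbox = nb)
  }
  n_fp <- rpois(1, model$fp_rate)
  # spurious boxes keep clearance from ground-truth neighborhoods (the gt
  # bbox inflated by fp_clearance_px), so a simulated false positive is
  # genuinely spurious rather than a halo artifact of an over-segmented
  # true detection
  clearance <- model$fp_clearance_px
  gt_boxes <- lapply(gt_regions, function(g) {
    bb <- region_bbox(g)
    c(bb[1] - clearance, bb[2] - clearance, bb[3] + clearance, bb[4] + clearance)
  })
  placed <- 0L; tries <- 0L
  while (placed < n_fp && tries < 50L * max(n_fp, 1L)) {
    tries <- tries + 1L
    side <- sample.int(model$fp_size_range[2] - model$fp_size_range[1] + 1L, 2L,
                       replace = TRUE) + model$fp_size_range[1] - 1L
    if (side[1] >= width || side[2] >= height) next
    x0 <- sample.int(width - side[1], 1L) - 1L
    y0 <- sample.int(height - side[2], 1L) - 1L
    box <- c(x0, y0, x0 + side[1], y0 + side[2])
    hits_gt <- any(vapply(gt_boxes, function(g)
      box[1] < g[3] && g[1] < box[3] && box[2] < g[4] && g[2] < box[4],
      logical(1)))
    if (hits_gt) next
    regs[[length(regs) + 1L]] <- region(image_id, bbox = box)
    placed <- placed + 1L
  }
  image_detections(image_id, regs, detector_id = detector_id)
}

#' Deterministic intensity-threshold reference detector
#'
#' A non-learning detector that exercises the full patch pipeline: the image
#' is thresholded at an intensity cutoff, each patch of the grid is labeled
#' follicular when its above-cutoff pixel count strictly exceeds the patch
#' positivity cutoff, positive patches are union-stitched, and connected
#' components of the stitched mask become the detections.
#'
#' @param raster grayscale matrix in `[0, 1]`.
#' @param intensity_cutoff foreground intensity cutoff (default 0.45, midway
#'   between the fixture's background and blob means).
#' @param patch_size,stride tiling parameters.
#' @param positivity_fraction patch positivity area fraction.
#' @param image_id,connectivity as elsewhere.
#' @return `fna_detections` with run-length regions.
#' @export
intensity_threshold_detector <- function(raster, intensity_cutoff = 0.45,
                                         patch_size = 256L, stride = 128L,
                                         positivity_fraction = 0.01,
                                         image_id = "image",
                                         connectivity = 8) {
  fg <- raster > intensity_cutoff
  grid <- make_patch_grid(ncol(raster), nrow(raster), patch_size, stride)
  labels <- label_patches(grid, fg, positivity_fraction)
  stitched <- stitch_patch_labels(labels)
  image_detections(image_id,
                   regions_from_mask(stitched, image_id, connectivity),
                   detector_id = "intensity")
}

#' Archetype detector pair emulating the two-model contrast
#'
#' Preset A emulates a high-precision / low-recall detector (few spurious
#' regions, moderate detection rate, coarse over-segmented regions, like a
#' patch classifier emitting stitched footprints); preset B a high-recall /
#' low-precision one (detects nearly everything but with many spurious
#' regions and tight boxes, like a region-proposal detector). Intersecting
#' them is the ensemble's favorable regime.
#'
#' @return list of two `fna_detector_model`s, named `A` and `B`.
#' @export
archetype_models <- function() {
  list(A = detector_error_model(p_detect = 0.65, fp_rate = 0.2,
                                dilate_px = 12L, jitter_px = 2L),
       B = detector_error_model(p_detect = 0.95, fp_rate = 2,
                                dilate_px = 1L, jitter_px = 2L))
}

#' @rdname archetype_models
#' @param fixture an `fna_fixture`.
#' @param models list of two `fna_detector_model`s (default
#'   [archetype_models()]).
#' @param seed integer seed for the simulation stream.
#' @param image_ids subset of images (default: all in the manifest).
#' @return `make_paired_detectors`: list with `A` and `B`, each a named list
#'   of `fna_detections` over the images, plus `gt` (named list of
#'   ground-truth region lists) and `frames`.
#' @export
make_paired_detectors <- function(fixture, models = archetype_models(),
                                  seed = 1L, image_ids = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  if (is.null(image_ids)) image_ids <- fixture$manifest$image_id
  # both detectors' spurious boxes must clear the larger of the two halos,
  # otherwise one detector's FP can clip the other's over-segmentation
  # margin and masquerade as an ensemble false positive
  shared <- max(models$A$dilate_px + models$A$jitter_px,
                models$B$dilate_px + models$B$jitter_px) + 2L
  models$A$fp_clearance_px <- max(models$A$fp_clearance_px, shared)
  models$B$fp_clearance_px <- max(models$B$fp_clearance_px, shared)
  w <- fixture$config$width; h <- fixture$config$height
  gt <- lapply(image_ids, function(id) fixture_gt_regions(fixture, id))
  names(gt) <- image_ids
  det_a <- lapply(image_ids, function(id)
    simulate_detector(gt[[id]], models$A, w, h, id, "A"))
  det_b <- lapply(image_ids, function(id)
    simulate_detector(gt[[id]], models$B, w, h, id, "B"))
  names(det_a) <- image_ids; names(det_b) <- image_ids
  list(A = det_a, B = det_b, gt = gt,
       frames = data.frame(image_id = image_ids, width = w, height = h,
                           stringsAsFactors = FALSE))
}
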