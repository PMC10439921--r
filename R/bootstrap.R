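#' Hierarchical (patient-then-image) bootstrap of slides
#'
#' The test data are multilevel: images nest within patients. To simulate
#' many slides from a small test set while preserving that structure,
#' resampling is hierarchical: a group of patients is drawn uniformly with
#' replacement, then a slide's worth of images is drawn from the pooled
#' images of those patients, and the slide's ground-truth and predicted
#' follicular-cluster counts are the sums over its images. Defaults follow
#' the study design: 10,000 groups of 6 patients, 41 images per slide,
#' image draws with replacement.
#'
#' @param patients data.frame with columns `patient_id`, `image_id`,
#'   `gt_count`, `pred_count`, one row per image.
#' @return `patient_pool`: an `fna_patient_pool` object.
#' @export
patient_pool <- function(patients) {
  req <- c("patient_id", "image_id", "gt_count", "pred_count")
  stopifnot(all(req %in% names(patients)), nrow(patients) >= 1L,
            all(patients$gt_count >= 0), all(patients$pred_count >= 0))
  structure(list(images = as.data.frame(patients)[req],
                 patient_ids = unique(patients$patient_id)),
            class = "fna_patient_pool")
}

#' @rdname patient_pool
#' @param n_groups number of bootstrapped slides (default 10000).
#' @param group_size patients per bootstrapped group (default 6).
#' @param images_per_slide images per bootstrapped slide (default 41).
#' @param image_sampling `"with_replacement"` (default) or
#'   `"without_replacement"`.
#' @param image_selection `"pooled_uniform"` (default): images drawn
#'   uniformly from the union of the group's patients' images, a patient
#'   drawn k times contributing its images k-fold; `"patient_then_image"`:
#'   each draw first picks a patient from the group, then one of that
#'   patient's images.
#' @param seed integer seed; all bootstrap randomness flows from it.
#' @export
bootstrap_config <- function(n_groups = 10000L, group_size = 6L,
                             images_per_slide = 41L,
                             image_sampling = c("with_replacement",
                                                "without_replacement"),
                             image_selection = c("pooled_uniform",
                                                 "patient_then_image"),
                             seed = 1L) {
  stopifnot(n_groups >= 1L, group_size >= 1L, images_per_slide >= 1L)
  structure(list(n_groups = as.integer(n_groups),
                 group_size = as.integer(group_size),
                 images_per_slide = as.integer(images_per_slide),
                 image_sampling = match.arg(image_sampling),
                 image_selection = match.arg(image_selection),
                 seed = as.integer(seed)),
            class = "fna_bootstrap_config")
}

#' Draw one bootstrapped patient group
#'
#' `group_size` uniform draws with replacement from the pool's patients.
#'
#' @param pool [patient_pool()].
#' @param group_size number of draws.
#' @return character vector of patient ids (a multiset).
#' @export
sample_patient_group <- function(pool, group_size = 6L) {
  if (length(pool$patient_ids) == 0L) stop("empty patient pool")
  sample(pool$patient_ids, size = group_size, replace = TRUE)
}

#' Draw one bootstrapped slide from a patient group
#'
#' @param pool [patient_pool()].
#' @param group patient-id multiset from [sample_patient_group()].
#' @param cfg [bootstrap_config()] (its `n_groups`/`seed` are ignored here;
#'   sampling uses the current RNG state).
#' @return one-row data.frame `gt_count`, `pred_count` plus the sampled
#'   `image_id`s as the attribute `provenance`.
#' @export
sample_slide <- function(pool, group, cfg = bootstrap_config()) {
  # pooled image table honoring patient multiplicity
  idx_by_patient <- split(seq_len(nrow(pool$images)), pool$images$patient_id)
  pooled <- unlist(idx_by_patient[group], use.names = FALSE)
  if (length(pooled) == 0L) stop("patient group has no images")
  m <- cfg$images_per_slide
  if (cfg$image_selection == "pooled_uniform") {
    if (cfg$image_sampling == "without_replacement" && length(pooled) < m)
      stop(sprintf("without_replacement needs >= %d pooled images, have %d",
                   m, length(pooled)))
    take <- sample(pooled, size = m,
                   replace = cfg$image_sampling == "with_replacement")
  } else {
    if (cfg$image_sampling == "without_replacement")
      stop("patient_then_image selection supports with_replacement only")
    pats <- sample(group, size = m, replace = TRUE)
    take <- vapply(pats, function(p) {
      cand <- idx_by_patient[[p]]
      cand[sample.int(length(cand), 1L)]
    }, integer(1))
  }
  out <- data.frame(gt_count = sum(pool$images$gt_count[take]),
                    pred_count = sum(pool$images$pred_count[take]))
  attr(out, "provenance") <- pool$images$image_id[take]
  out
}

#' Run the full hierarchical bootstrap
#'
#' @param pool [patient_pool()].
#' @param cfg [bootstrap_config()].
#' @param provenance keep per-slide sampled patients/images as an attribute.
#' @return data.frame with `slide_id`, `gt_count`, `pred_count`
#'   (`cfg$n_groups` rows), reproducible from `cfg$seed`.
#' @export
#' @examples
#' pool <- patient_pool(data.frame(patient_id = "p1", image_id = "i1",
#'                                 gt_count = 1, pred_count = 2))
#' run_bootstrap(pool, bootstrap_config(n_groups = 3, images_per_slide = 41))
run_bootstrap <- function(pool, cfg = bootstrap_config(), provenance = FALSE) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  prov <- if (provenance) vector("list", cfg$n_groups)
  gt <- integer(cfg$n_groups); pred <- integer(cfg$n_groups)
  for (i in seq_len(cfg$n_groups)) {
    group <- sample_patient_group(pool, cfg$group_size)
    sl <- sample_slide(pool, group, cfg)
    gt[i] <- sl$gt_count; pred[i] <- sl$pred_count
    if (provenance)
      prov[[i]] <- list(patients = group, images = attr(sl, "provenance"))
  }
  out <- data.frame(slide_id = sprintf("slide_%05d", seq_len(cfg$n_groups)),
                    gt_count = gt, pred_count = pred,
                    stringsAsFactors = FALSE)
  if (provenance) attr(out, "provenance") <- prov
  out
}
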