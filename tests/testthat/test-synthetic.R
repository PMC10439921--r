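test_that("fixture generation reproduces the study structure deterministically", {
  fx <- small_fixture(seed = 2)
  expect_equal(nrow(fx$manifest), 287L)
  expect_equal(sum(fx$manifest$class_label == "follicular"), 56L)
  expect_equal(sum(fx$manifest$class_label == "background"), 231L)
  counts <- manifest_counts(fx$manifest)
  expect_equal(nrow(counts), 7L)
  expect_true(all(counts$follicular == 8L))
  expect_true(all(counts$background == 33L))
  expect_equal(length(unique(fx$manifest$patient_id)), 6L)

  fx2 <- small_fixture(seed = 2)
  expect_identical(fx$manifest, fx2$manifest)
  expect_identical(fx$blobs, fx2$blobs)
  fx3 <- small_fixture(seed = 3)
  expect_false(identical(fx$blobs, fx3$blobs))

  # no-follicular configuration: all labels background, all masks empty
  fx0 <- generate_fixture(fixture_config(
    n_groups = 2, n_background_per_group = 3, n_follicular_per_group = 0,
    width = 256, height = 256, blob_area_range = c(800, 4000), seed = 1))
  expect_true(all(fx0$manifest$class_label == "background"))
  expect_false(any(fixture_mask(fx0, fx0$manifest$image_id[1])))

  expect_error(fixture_config(width = 64, height = 64,
                              blob_area_range = c(1000, 30000)),
               "incompatible")
})

test_that("follicular masks always clear the patch positivity cutoff somewhere", {
  fx <- small_fixture(seed = 6, n_bg = 0, n_fol = 2)
  cutoff <- positivity_pixels(256)
  for (id in fx$manifest$image_id) {
    mask <- fixture_mask(fx, id)
    expect_true(any(mask))
    grid <- make_patch_grid(512, 512, 256, 128)
    labels <- label_patches(grid, mask)
    expect_true(any(labels$labels == "follicular"),
                info = sprintf("image %s has no positive patch (cutoff %d)", id, cutoff))
  }
})

test_that("simulated detector calibration matches its error model within 3 SE", {
  fx <- small_fixture(seed = 12, n_bg = 0, n_fol = 2)
  gt2 <- list(region("im", bbox = c(50, 50, 120, 110)),
              region("im", bbox = c(300, 200, 380, 290)))
  model <- detector_error_model(p_detect = 0.5, fp_rate = 2,
                                dilate_px = 0, jitter_px = 0)
  set.seed(33)
  n_img <- 400
  hits <- 0L; fps <- 0L
  for (i in seq_len(n_img)) {
    det <- simulate_detector(gt2, model, 512, 512, "im")
    m <- match_regions(gt2, det$regions)
    hits <- hits + m$tp
    fps <- fps + m$fp
  }
  p_hat <- hits / (2 * n_img)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.5 * 0.5 / (2 * n_img)))
  fp_hat <- fps / n_img
  expect_lt(abs(fp_hat - 2), 3 * sqrt(2 / n_img))

  # degenerate models
  set.seed(1)
  perfect <- simulate_detector(gt2, detector_error_model(p_detect = 1, fp_rate = 0),
                               512, 512, "im")
  m <- match_regions(gt2, perfect$regions)
  expect_equal(precision_recall_f1(m), list(precision = 1, recall = 1, f1 = 1))

  blind <- simulate_detector(gt2, detector_error_model(p_detect = 0, fp_rate = 0),
                             512, 512, "im")
  expect_length(blind$regions, 0L)
})

test_that("the intensity-threshold detector finds blobs through the tiling path", {
  # uniform background: nothing detected
  flat <- matrix(0.2, 512, 512)
  expect_length(intensity_threshold_detector(flat)$regions, 0L)

  # one bright blob well above the patch cutoff is found and overlaps truth
  img <- matrix(0.2, 512, 512)
  img[200:260, 150:240] <- 0.8   # ~5500 px
  det <- intensity_threshold_detector(img, image_id = "im")
  expect_gte(length(det$regions), 1L)
  gt <- region("im", bbox = c(149, 199, 240, 260))
  expect_true(any(vapply(det$regions, function(r) region_overlap(r, gt) > 0,
                         logical(1))))

  # a blob straddling two patch columns still yields one stitched region
  img2 <- matrix(0.2, 512, 512)
  img2[100:160, 100:220] <- 0.8   # spans the x=128 patch boundary
  det2 <- intensity_threshold_detector(img2, image_id = "im")
  expect_length(det2$regions, 1L)
})

test_that("fixture blobs are detectable by the reference intensity detector", {
  fx <- small_fixture(seed = 14, n_bg = 1, n_fol = 2)
  fol <- fx$manifest$image_id[fx$manifest$class_label == "follicular"][1:4]
  for (id in fol) {
    det <- intensity_threshold_detector(fixture_raster(fx, id), image_id = id)
    m <- match_regions(fixture_gt_regions(fx, id), det$regions)
    expect_gte(m$tp, 1L)
  }
})

test_that("paired archetype detectors give the ensemble a precision edge", {
  fx <- small_fixture(seed = 20, n_bg = 3, n_fol = 2)
  pd <- make_paired_detectors(fx, seed = 21)
  # identical model under the same stream equals itself; ensemble of a
  # detector with itself reproduces its foreground
  id1 <- fx$manifest$image_id[1]
  self <- intersect_detections(pd$A[[id1]], pd$A[[id1]], 512, 512)
  expect_equal(rasterize_regions(self$regions, 512, 512),
               rasterize_regions(pd$A[[id1]]$regions, 512, 512))

  ens <- ensemble_detections(pd$A, pd$B, pd$frames)
  for (id in fx$manifest$image_id) {
    # B empty forces the ensemble empty
    if (length(pd$B[[id]]$regions) == 0L)
      expect_length(ens[[id]]$regions, 0L)
    # per-image FP never exceeds either input's
    ma <- match_regions(pd$gt[[id]], pd$A[[id]]$regions)
    mb <- match_regions(pd$gt[[id]], pd$B[[id]]$regions)
    me <- match_regions(pd$gt[[id]], ens[[id]]$regions)
    expect_lte(me$fp, min(ma$fp, mb$fp))
  }
})
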