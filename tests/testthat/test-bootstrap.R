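make_pool <- function(n_patients = 6, images_per_patient = 7, seed = 5,
                      gt_lambda = 1, pred_lambda = 1.2) {
  set.seed(seed)
  n <- n_patients * images_per_patient
  patient_pool(data.frame(
    patient_id = rep(sprintf("p%d", seq_len(n_patients)), each = images_per_patient),
    image_id = sprintf("i%03d", seq_len(n)),
    gt_count = rpois(n, gt_lambda),
    pred_count = rpois(n, pred_lambda),
    stringsAsFactors = FALSE))
}

test_that("patient-group sampling is uniform with replacement and reproducible", {
  single <- patient_pool(data.frame(patient_id = "p1", image_id = "i1",
                                    gt_count = 0, pred_count = 0))
  expect_equal(sample_patient_group(single, 6), rep("p1", 6))

  pool <- make_pool()
  set.seed(1); g1 <- sample_patient_group(pool, 6)
  set.seed(1); g2 <- sample_patient_group(pool, 6)
  expect_identical(g1, g2)

  # per-patient frequency within 3 binomial standard errors of 1/6
  set.seed(2)
  draws <- unlist(replicate(4000, sample_patient_group(pool, 6), simplify = FALSE))
  freq <- table(factor(draws, levels = pool$patient_ids)) / length(draws)
  se <- sqrt((1 / 6) * (5 / 6) / length(draws))
  expect_true(all(abs(freq - 1 / 6) < 3 * se))

  expect_error(sample_patient_group(patient_pool(data.frame(
    patient_id = character(), image_id = character(),
    gt_count = numeric(), pred_count = numeric())[0, ]), 6))
})

test_that("slide counts decompose as sums over the sampled images", {
  # forced case: one image (gt 1, pred 2) sampled 3 times
  single <- patient_pool(data.frame(patient_id = "p1", image_id = "i1",
                                    gt_count = 1, pred_count = 2))
  cfg <- bootstrap_config(images_per_slide = 3)
  set.seed(1)
  sl <- sample_slide(single, "p1", cfg)
  expect_equal(sl$gt_count, 3)
  expect_equal(sl$pred_count, 6)

  expect_error(bootstrap_config(images_per_slide = 0))

  # provenance identity on a real pool
  pool <- make_pool()
  set.seed(3)
  sl <- sample_slide(pool, sample_patient_group(pool, 6), bootstrap_config())
  imgs <- attr(sl, "provenance")
  idx <- match(imgs, pool$images$image_id)
  expect_equal(sl$gt_count, sum(pool$images$gt_count[idx]))
  expect_equal(sl$pred_count, sum(pool$images$pred_count[idx]))
  expect_length(imgs, 41L)
})

test_that("without-replacement sampling requires a large enough pooled set", {
  pool <- make_pool(n_patients = 2, images_per_patient = 3)
  cfg <- bootstrap_config(images_per_slide = 41,
                          image_sampling = "without_replacement")
  expect_error(sample_slide(pool, c("p1", "p2"), cfg), ">= 41")

  cfg_small <- bootstrap_config(images_per_slide = 5,
                                image_sampling = "without_replacement")
  set.seed(1)
  sl <- sample_slide(pool, c("p1", "p2"), cfg_small)
  expect_length(unique(attr(sl, "provenance")), 5L)  # no repeats
})

test_that("the full bootstrap is deterministic under its seed and sized as configured", {
  pool <- make_pool()
  cfg <- bootstrap_config(n_groups = 50, seed = 99)
  b1 <- run_bootstrap(pool, cfg)
  b2 <- run_bootstrap(pool, cfg)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 50L)
  b3 <- run_bootstrap(pool, bootstrap_config(n_groups = 50, seed = 100))
  expect_false(identical(b1$pred_count, b3$pred_count))

  # single-patient pool with unit ground truth: every slide has gt 41
  ones <- patient_pool(data.frame(patient_id = "p1",
                                  image_id = sprintf("i%d", 1:5),
                                  gt_count = 1, pred_count = 2))
  bf <- run_bootstrap(ones, bootstrap_config(n_groups = 20))
  expect_true(all(bf$gt_count == 41L))
  expect_true(all(bf$pred_count == 82L))
})

test_that("bootstrapped slide means match analytic expectations within 3 SE", {
  # single patient: slide gt_count is a sum of 41 uniform draws, so its mean
  # is 41 * pool mean and its variance 41 * pool variance
  pool <- make_pool(n_patients = 1, images_per_patient = 12, seed = 8)
  mu <- mean(pool$images$gt_count)
  v <- mean((pool$images$gt_count - mu)^2)
  b <- run_bootstrap(pool, bootstrap_config(n_groups = 10000, seed = 7))
  se <- sqrt(41 * v / 10000)
  expect_lt(abs(mean(b$gt_count) - 41 * mu), 3 * se)

  # provenance bookkeeping holds over a replay
  bp <- run_bootstrap(pool, bootstrap_config(n_groups = 25, seed = 7),
                      provenance = TRUE)
  prov <- attr(bp, "provenance")
  for (i in seq_len(25)) {
    idx <- match(prov[[i]]$images, pool$images$image_id)
    expect_equal(bp$gt_count[i], sum(pool$images$gt_count[idx]))
  }
})

test_that("hierarchical sampling rebalances toward rare follicular-rich patients", {
  # five barren patients, one follicular-rich: the pooled per-image mean is
  # dominated by barren images, while patient-level resampling upweights the
  # rich patient to 1/6 of draws
  imgs <- data.frame(
    patient_id = c(rep("rich", 2), rep(sprintf("poor%d", 1:5), each = 10)),
    image_id = sprintf("i%02d", 1:52),
    gt_count = c(5, 5, rep(0, 50)),
    pred_count = 0)
  pool <- patient_pool(imgs)
  pooled_mean <- mean(imgs$gt_count)           # flat, patient-blind rate
  b <- run_bootstrap(pool, bootstrap_config(n_groups = 4000, seed = 11))
  hier_mean <- mean(b$gt_count) / 41
  # patient-major draws give the rich patient 1/6 weight but only 2/52 of
  # the flat pool, so the hierarchical per-image rate must exceed the pooled
  # per-image rate
  expect_gt(hier_mean, pooled_mean)
})
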