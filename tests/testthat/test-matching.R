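test_that("one-pixel-overlap matching handles the canonical cases", {
  gt1 <- list(region("i", bbox = c(0, 0, 10, 10)))

  # two predictions on one ground truth: one TP, the surplus is ignored
  m <- match_regions(gt1, list(region("i", bbox = c(2, 2, 4, 4)),
                               region("i", bbox = c(6, 6, 8, 8))))
  expect_equal(unclass(m)[c("tp", "fp", "fn", "ignored_preds")],
               list(tp = 1L, fp = 0L, fn = 0L, ignored_preds = 1L))

  # unmatched ground truth is a false negative
  m <- match_regions(gt1, list())
  expect_equal(m$fn, 1L)
  expect_equal(m$tp, 0L)

  # sharing exactly one pixel suffices for a true positive
  m <- match_regions(gt1, list(region("i", bbox = c(9, 9, 15, 15))))
  expect_equal(m$tp, 1L)

  # predictions without any ground truth are all false positives
  m <- match_regions(list(), list(region("i", bbox = c(0, 0, 2, 2)),
                                  region("i", bbox = c(4, 4, 6, 6)),
                                  region("i", bbox = c(8, 8, 10, 10))))
  expect_equal(m$fp, 3L)
})

test_that("matching equals the brute-force pixel-set oracle on random scenes", {
  set.seed(101)
  for (i in 1:200) {
    gt <- random_regions(sample(0:6, 1), 32, 32)
    pred <- random_regions(sample(0:6, 1), 32, 32)
    got <- match_regions(gt, pred)
    want <- oracle_match(gt, pred)
    expect_equal(got$tp, want$tp)
    expect_equal(got$fp, want$fp)
    expect_equal(got$fn, want$fn)
    expect_equal(got$ignored_preds, want$ignored)
    # bookkeeping identities hold unconditionally
    expect_equal(got$tp + got$fn, length(gt))
    expect_equal(got$tp + got$fp + got$ignored_preds, length(pred))
  }
})

test_that("matching also agrees with the oracle on rle (mask) regions", {
  set.seed(55)
  for (i in 1:30) {
    gt <- regions_from_mask(random_mask(24, 24, 0.15), "im")
    pred <- c(regions_from_mask(random_mask(24, 24, 0.1), "im"),
              random_regions(sample(0:3, 1), 24, 24, "im"))
    got <- match_regions(gt, pred)
    want <- oracle_match(gt, pred)
    expect_equal(got[c("tp", "fp", "fn")],
                 want[c("tp", "fp", "fn")], ignore_attr = TRUE)
  }
})

test_that("adding a prediction never decreases tp nor fp+ignored", {
  set.seed(77)
  for (i in 1:30) {
    gt <- random_regions(sample(1:5, 1), 32, 32)
    pred <- random_regions(sample(1:6, 1), 32, 32)
    base <- match_regions(gt, pred)
    more <- match_regions(gt, c(pred, random_regions(1, 32, 32)))
    expect_gte(more$tp, base$tp)
    expect_gte(more$fp + more$ignored_preds, base$fp + base$ignored_preds)
  }
})

test_that("whole-image IOU applies the degenerate-image exclusion rule", {
  m <- random_mask(10, 10, 0.4)
  m[1, 1] <- TRUE
  expect_equal(image_iou(m, m), 1.0)

  empty <- matrix(FALSE, 10, 10)
  expect_true(is.na(image_iou(empty, empty)))     # excluded image
  expect_equal(image_iou(empty, m), 0.0)          # false-positive-only image
  expect_equal(image_iou(m, empty), 0.0)

  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[2:3, 1:2] <- TRUE
  expect_equal(image_iou(a, b), 2 / 6)

  expect_error(image_iou(matrix(FALSE, 2, 2), matrix(FALSE, 3, 3)), "shape")
})

test_that("precision/recall/F1 follow the count formulas with explicit undefineds", {
  # the fold counted in the study: 16 TP, 21 FN, 3 FP
  prf <- precision_recall_f1(list(tp = 16, fp = 3, fn = 21))
  expect_equal(prf$precision, 16 / 19)
  expect_equal(prf$recall, 16 / 37)
  expect_equal(prf$f1, 2 * (16 / 19) * (16 / 37) / (16 / 19 + 16 / 37))

  perfect <- precision_recall_f1(list(tp = 5, fp = 0, fn = 0))
  expect_equal(unlist(perfect), c(precision = 1, recall = 1, f1 = 1))

  none <- precision_recall_f1(list(tp = 0, fp = 0, fn = 5))
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)
  expect_true(is.na(none$f1))
})

test_that("fold aggregation uses sample sd and drops undefined entries with a count", {
  same <- data.frame(precision = rep(0.5, 7), recall = rep(0.25, 7))
  agg <- aggregate_folds(same)
  expect_equal(agg$sd, c(0, 0))
  expect_equal(agg$n, c(7L, 7L))

  two <- data.frame(iou = c(0.2, 0.4))
  agg2 <- aggregate_folds(two)
  expect_equal(agg2$mean, 0.3)
  expect_equal(agg2$sd, sqrt(0.02), tolerance = 1e-12)

  withna <- data.frame(iou = c(0.2, NA, 0.4, 0.1, 0.3, 0.25, 0.15))
  expect_message(agg3 <- aggregate_folds(withna), "dropped 1")
  expect_equal(agg3$n, 6L)
})

test_that("evaluate_detections sums counts over images and averages IOU over non-excluded ones", {
  gt <- list(a = list(region("a", bbox = c(0, 0, 4, 4))),
             b = list(),
             c = list(region("c", bbox = c(2, 2, 6, 6))))
  dets <- list(a = image_detections("a", list(region("a", bbox = c(0, 0, 4, 4))), "d"),
               b = image_detections("b", list(), "d"),
               c = image_detections("c", list(region("c", bbox = c(10, 10, 12, 12))), "d"))
  frames <- data.frame(image_id = c("a", "b", "c"), width = 16, height = 16)
  res <- evaluate_detections(gt, dets, frames)
  expect_equal(res$counts$tp, 1L)
  expect_equal(res$counts$fp, 1L)
  expect_equal(res$counts$fn, 1L)
  expect_equal(res$n_iou_images, 2L)   # image b is excluded
  expect_equal(res$iou, mean(c(1, 0)))
  expect_equal(res$precision, 0.5)
  expect_equal(res$recall, 0.5)
})
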