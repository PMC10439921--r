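#' Seven-fold cross-validation splits over the manifest's groups
#'
#' The dataset is pre-split into 7 disjoint groups; fold `i` tests on group
#' `i`, validates on group `(i mod 7) + 1`, and trains on the remaining 5
#' groups, so each group serves as the test set exactly once. With the
#' study-structure fixture each fold trains on 205 images and tests on 41.
#'
#' @param manifest manifest data.frame with a `group_id` column spanning
#'   exactly 7 groups.
#' @return list of 7 `fna_fold` objects, each with `fold` (index), `test`,
#'   `validation`, `train` (character vectors of image ids).
#' @export
make_folds <- function(manifest) {
  groups <- sort(unique(manifest$group_id))
  if (length(groups) != 7L)
    stop(sprintf("7-fold protocol requires exactly 7 groups, found %d",
                 length(groups)))
  ids_by_group <- split(manifest$image_id, manifest$group_id)
  lapply(seq_along(groups), function(i) {
    test_g <- groups[i]
    val_g <- groups[(i %% 7L) + 1L]
    train_g <- setdiff(groups, c(test_g, val_g))
    structure(list(fold = i,
                   test = ids_by_group[[test_g]],
                   validation = ids_by_group[[val_g]],
                   train = unlist(ids_by_group[train_g], use.names = FALSE)),
              class = "fna_fold")
  })
}

#' Compare models across folds with paired exact signed-rank tests
#'
#' Per-metric mean and standard deviation per model across the common folds,
#' plus pairwise two-sided exact signed-rank p-values for every model pair
#' ([paired_signed_rank()]). Raw p-values are reported by default; an
#' optional Bonferroni correction over the model pairs is available.
#'
#' @param metrics long-format data.frame with columns `model`, `fold`,
#'   `metric`, `value`.
#' @param bonferroni apply Bonferroni correction across model pairs within
#'   each metric.
#' @return list with `summary` (model x metric means/sds) and `pairs`
#'   (data.frame `metric, model_a, model_b, p_value`); p-values are
#'   symmetric in the model pair.
#' @export
compare_models <- function(metrics, bonferroni = FALSE) {
  req <- c("model", "fold", "metric", "value")
  stopifnot(all(req %in% names(metrics)))
  models <- sort(unique(metrics$model))
  folds <- sort(unique(metrics$fold))
  # every model must cover the same folds for each metric
  for (m in models) for (met in unique(metrics$metric)) {
    f <- metrics$fold[metrics$model == m & metrics$metric == met]
    if (!setequal(f, folds) || anyDuplicated(f))
      stop(sprintf("model %s does not cover all folds for metric %s", m, met))
  }
  summary <- do.call(rbind, lapply(models, function(m) {
    do.call(rbind, lapply(unique(metrics$metric), function(met) {
      v <- metrics$value[metrics$model == m & metrics$metric == met]
      v <- v[order(metrics$fold[metrics$model == m & metrics$metric == met])]
      data.frame(model = m, metric = met, mean = mean(v, na.rm = TRUE),
                 sd = sd(v, na.rm = TRUE), stringsAsFactors = FALSE)
    }))
  }))
  pairs <- list()
  if (length(models) >= 2L) {
    cmb <- utils::combn(models, 2L)
    n_pairs <- ncol(cmb)
    for (met in unique(metrics$metric)) {
      for (k in seq_len(n_pairs)) {
        va <- .fold_values(metrics, cmb[1, k], met, folds)
        vb <- .fold_values(metrics, cmb[2, k], met, folds)
        p <- paired_signed_rank(va, vb)$p.value
        if (bonferroni) p <- min(1, p * n_pairs)
        pairs[[length(pairs) + 1L]] <-
          data.frame(metric = met, model_a = cmb[1, k], model_b = cmb[2, k],
                     p_value = p, stringsAsFactors = FALSE)
      }
    }
  }
  list(summary = summary,
       pairs = if (length(pairs)) do.call(rbind, pairs)
               else data.frame(metric = character(), model_a = character(),
                               model_b = character(), p_value = numeric()))
}

.fold_values <- function(metrics, model, metric, folds) {
  sub <- metrics[metrics$model == model & metrics$metric == metric, ]
  sub$value[match(folds, sub$fold)]
}
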