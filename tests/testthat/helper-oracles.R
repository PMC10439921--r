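# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: pixel sets are enumerated explicitly, components
# come from a plain R flood fill, matching from an all-pairs overlap matrix,
# and the signed-rank p from exhaustive sign enumeration.

# Pixel set of a region as "x,y" strings (0-based).
oracle_region_pixels <- function(r) {
  if (!is.null(r$bbox)) {
    bb <- r$bbox
    grid <- expand.grid(x = seq.int(bb[1], bb[3] - 1),
                        y = seq.int(bb[2], bb[4] - 1))
  } else {
    m <- rle_decode(r$rle)
    idx <- which(m, arr.ind = TRUE)
    grid <- data.frame(x = idx[, 2] - 1, y = idx[, 1] - 1)
  }
  paste(grid$x, grid$y, sep = ",")
}

oracle_mask_pixels <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  paste(idx[, 2] - 1, idx[, 1] - 1, sep = ",")
}

# Recursive-free flood fill on a logical matrix, plain R.
oracle_flood_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 4)
    rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  else
    rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
          c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  next_lab <- 0L
  for (y in seq_len(h)) for (x in seq_len(w)) {
    if (!mask[y, x] || lab[y, x] != 0L) next
    next_lab <- next_lab + 1L
    stack <- list(c(y, x))
    lab[y, x] <- next_lab
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        ny <- p[1] + nb[k, 1]; nx <- p[2] + nb[k, 2]
        if (ny < 1 || ny > h || nx < 1 || nx > w) next
        if (!mask[ny, nx] || lab[ny, nx] != 0L) next
        lab[ny, nx] <- next_lab
        stack[[length(stack) + 1L]] <- c(ny, nx)
      }
    }
  }
  lab
}

# Greedy ground-truth-major matching from an explicit overlap matrix built
# out of enumerated pixel sets.
oracle_match <- function(gt, pred) {
  gt_px <- lapply(gt, oracle_region_pixels)
  pr_px <- lapply(pred, oracle_region_pixels)
  overlap <- matrix(FALSE, length(gt), length(pred))
  if (length(gt) && length(pred))
    for (i in seq_along(gt)) for (j in seq_along(pred))
      overlap[i, j] <- length(intersect(gt_px[[i]], pr_px[[j]])) > 0
  used <- rep(FALSE, length(pred))
  tp <- 0L
  for (i in seq_along(gt)) {
    cand <- which(overlap[i, ] & !used)
    if (length(cand)) { used[cand[1]] <- TRUE; tp <- tp + 1L }
  }
  touches <- if (length(gt)) apply(overlap, 2, any) else rep(FALSE, length(pred))
  list(tp = tp, fp = sum(!touches), fn = length(gt) - tp,
       ignored = sum(touches & !used))
}

# Exhaustive 2^n enumeration of the signed-rank null (two-sided).
oracle_signed_rank <- function(a, b) {
  d <- (a - b)[a != b]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Random small scene of bbox regions inside a frame.
random_regions <- function(n, width, height, image_id = "img", max_side = 10) {
  lapply(seq_len(n), function(i) {
    w <- sample.int(max_side, 1); h <- sample.int(max_side, 1)
    x0 <- sample.int(width - w, 1) - 1
    y0 <- sample.int(height - h, 1) - 1
    region(image_id, bbox = c(x0, y0, x0 + w, y0 + h))
  })
}

random_mask <- function(width, height, p = 0.3) {
  matrix(runif(width * height) < p, nrow = height, ncol = width)
}

# Small desk-scale fixture shared by several suites.
small_fixture <- function(seed = 11L, n_groups = 7L, n_bg = 33L, n_fol = 8L) {
  generate_fixture(fixture_config(
    n_groups = n_groups, n_background_per_group = n_bg,
    n_follicular_per_group = n_fol, width = 512L, height = 512L,
    blob_area_range = c(800, 8000), seed = seed))
}
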