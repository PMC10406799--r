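# Independent brute-force oracles. These deliberately use the most naive
# formulation of each quantity (explicit loops / exhaustive scans) so the
# package's vectorized or indexed implementations are checked against an
# unrelated computational route.

# Pixel-counting Jaccard oracle.
oracle_ji <- function(x, y) {
  inter <- 0L; uni <- 0L
  for (i in seq_along(x)) {
    if (x[i] && y[i]) inter <- inter + 1L
    if (x[i] || y[i]) uni <- uni + 1L
  }
  if (uni == 0L) NA_real_ else inter / uni
}

# All-pairs average Hausdorff oracle: explicit min over every pair.
oracle_hd <- function(X, Y) {
  dxy <- vapply(seq_len(nrow(X)), function(i)
    min(sqrt(colSums((t(Y) - X[i, ])^2))), numeric(1))
  dyx <- vapply(seq_len(nrow(Y)), function(j)
    min(sqrt(colSums((t(X) - Y[j, ])^2))), numeric(1))
  (mean(dxy) + mean(dyx)) / 2
}

# Distance-to-centerline tube rasterizer: for every voxel, the minimum
# distance over all centerline samples.
oracle_rasterize <- function(centerline, radius, shape) {
  mask <- array(FALSE, shape)
  for (z in seq_len(shape[3])) for (x in seq_len(shape[2]))
    for (y in seq_len(shape[1])) {
      d2 <- (centerline[, 1] - y)^2 + (centerline[, 2] - x)^2 +
        (centerline[, 3] - z)^2
      if (min(d2) <= radius^2) mask[y, x, z] <- TRUE
    }
  mask
}

# Exhaustive between-class-variance scan for the Otsu threshold.
oracle_otsu <- function(values, nbins) {
  lv <- 0:(nbins - 1L)
  best <- -Inf; best_t <- NA_integer_
  n <- length(values)
  for (t in 0:(nbins - 2L)) {
    lo <- values <= t
    n0 <- sum(lo)
    if (n0 == 0L || n0 == n) next
    w0 <- n0 / n
    sb <- w0 * (1 - w0) * (mean(values[lo]) - mean(values[!lo]))^2
    if (sb > best + 1e-12) { best <- sb; best_t <- t }
  }
  best_t
}

# BFS flood-fill labeling with 8-connectivity.
oracle_label8 <- function(mask) {
  d <- dim(mask)
  lbl <- matrix(0L, d[1], d[2])
  k <- 0L
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j] || lbl[i, j] > 0L) next
    k <- k + 1L
    queue <- list(c(i, j))
    lbl[i, j] <- k
    while (length(queue) > 0L) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dy in -1:1) for (dx in -1:1) {
        yy <- p[1] + dy; xx <- p[2] + dx
        if (yy >= 1 && yy <= d[1] && xx >= 1 && xx <= d[2] &&
            mask[yy, xx] && lbl[yy, xx] == 0L) {
          lbl[yy, xx] <- k
          queue[[length(queue) + 1L]] <- c(yy, xx)
        }
      }
    }
  }
  lbl
}

# Double-loop weighted total variation of a box with the border-clamp rule.
oracle_wtv <- function(img, y_top, x_left, H, W) {
  d <- dim(img)
  total <- 0
  for (i in (y_top + 1):(y_top + H)) for (j in (x_left + 1):(x_left + W)) {
    dy <- if (i + 1 <= d[1]) img[i + 1, j] - img[i, j] else 0
    dx <- if (j + 1 <= d[2]) img[i, j + 1] - img[i, j] else 0
    total <- total + sqrt(dy^2 + dx^2)
  }
  total / (H * W)
}

# Two-sample permutation test on the difference of means.
oracle_perm_test <- function(a, b, n_perm = 400L) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (r in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}
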