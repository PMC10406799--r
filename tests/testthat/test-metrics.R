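test_that("per-slice Jaccard handles identity, the thin-vessel worked case,
           and the undefined sentinel", {
  m <- random_mask2d(8, 8)
  expect_equal(jaccard_slice(m, m), if (any(m)) 1 else NA_real_)

  truth <- matrix(FALSE, 3, 3); truth[2, 1:2] <- TRUE
  ann <- matrix(FALSE, 3, 3); ann[2, 1] <- TRUE
  expect_equal(jaccard_slice(truth, ann), 0.5)

  empty <- matrix(FALSE, 3, 3)
  expect_identical(jaccard_slice(empty, empty), NA_real_)
  expect_error(jaccard_slice(truth, matrix(FALSE, 2, 2)), "shape")
})

test_that("Jaccard equals the pixel-count oracle and is symmetric", {
  set.seed(12)
  for (rep in 1:50) {
    x <- random_mask2d(8, 8, runif(1, 0.05, 0.6))
    y <- random_mask2d(8, 8, runif(1, 0.05, 0.6))
    expect_equal(jaccard_slice(x, y), oracle_ji(x, y))
    expect_equal(jaccard_slice(x, y), jaccard_slice(y, x))
  }
})

test_that("removing true-positive pixels never increases Jaccard", {
  set.seed(13)
  for (rep in 1:20) {
    x <- random_mask2d(10, 10, 0.4)
    y <- x & random_mask2d(10, 10, 0.9)   # annotation inside truth
    if (!any(y)) next
    ji_full <- jaccard_slice(x, y)
    drop1 <- y
    drop1[which(y)[1]] <- FALSE
    expect_lte(jaccard_slice(x, drop1) %||% 0, ji_full)
  }
})

test_that("stack Jaccard averages defined slices and honours the filter", {
  X <- square_mask(c(12, 12, 6), provenance = "t")
  Y <- square_mask(c(12, 12, 6), offset = c(1L, 0L), provenance = "a")
  # slices 1,3,5 annotated only in X -> keep union defined everywhere
  rep_all <- jaccard_stack(X, Y)
  per <- sapply(1:6, function(s) jaccard_slice(X$data[, , s], Y$data[, , s]))
  expect_equal(rep_all$stack_ji, mean(per, na.rm = TRUE))
  expect_equal(unname(rep_all$per_slice_ji), per)

  rep_f <- jaccard_stack(X, Y, slice_filter = c(2, 5))
  expect_equal(rep_f$stack_ji, mean(per[c(2, 5)]))
  expect_equal(rep_f$n_slices_used, 2)

  expect_equal(jaccard_stack(X, X)$stack_ji, 1)
  empty <- mask_stack(array(FALSE, c(12, 12, 6)), provenance = "e")
  expect_error(jaccard_stack(empty, empty), "undefined")
})

test_that("point extraction conserves counts and applies spacing per axis", {
  arr <- array(FALSE, c(6, 6, 4)); arr[3, 4, 2] <- TRUE
  m <- mask_stack(arr, spacing = c(60, 60, 200), provenance = "p")
  pts <- extract_points(m)
  expect_equal(unclass(pts),
               matrix(c(3, 4, 2), 1,
                      dimnames = list(NULL, c("y", "x", "z"))),
               ignore_attr = "count")
  expect_equal(attr(pts, "count"), 1)

  ph <- small_phantom(seed = 2, shape = c(24, 24, 8))
  expect_equal(attr(extract_points(ph$mask), "count"), sum(ph$mask$data))

  # two voxels one slice apart: anisotropic spacing scales z by 200
  arr2 <- arr; arr2[3, 4, 3] <- TRUE
  m2 <- mask_stack(arr2, spacing = c(60, 60, 200), provenance = "p")
  p_vox <- extract_points(m2, use_spacing = FALSE)
  p_um <- extract_points(m2, use_spacing = TRUE)
  expect_equal(sqrt(sum((p_vox[1, ] - p_vox[2, ])^2)), 1)
  expect_equal(sqrt(sum((p_um[1, ] - p_um[2, ])^2)), 200)

  expect_error(extract_points(mask_stack(array(FALSE, c(4, 4, 2)),
                                         provenance = "e")), "empty")
})

test_that("average Hausdorff: identity, closed form, symmetry, and the
           all-pairs oracle", {
  X <- matrix(c(0, 0, 0), 1)
  Y <- matrix(c(0, 0, 3), 1)
  expect_equal(average_hausdorff(X, X), 0)
  expect_equal(average_hausdorff(X, Y), 3)

  set.seed(14)
  for (rep in 1:25) {
    A <- matrix(runif(3 * sample(2:60, 1), 0, 30), ncol = 3)
    B <- matrix(runif(3 * sample(2:60, 1), 0, 30), ncol = 3)
    expect_equal(average_hausdorff(A, B), oracle_hd(A, B), tolerance = 1e-9)
    expect_equal(average_hausdorff(A, B), average_hausdorff(B, A))
  }
})

test_that("MS-SSIM maps: perfect reconstruction, luminance-only case, size
           guard", {
  ph <- small_phantom(seed = 2, shape = c(48, 48, 8))
  sl <- ph$volume$data[, , 4]
  res <- ms_ssim_map(sl, sl, scales = 2)
  expect_true(all(abs(res$map - 1) < 1e-9))
  expect_equal(res$mean, 1)

  # constant vs constant differing by a DC offset: variance and covariance
  # vanish, the map is the luminance term alone
  a <- matrix(1000, 16, 16); b <- matrix(3000, 16, 16)
  r <- ms_ssim_map(a, b, scales = 1, bit_depth = 16)
  C1 <- (0.01 * 65535)^2
  lum <- (2 * 1000 * 3000 + C1) / (1000^2 + 3000^2 + C1)
  expect_equal(unique(round(as.numeric(r$map), 10)), round(lum, 10))

  expect_error(ms_ssim_map(sl, sl, scales = 4), "too small")
})

test_that("MS-SSIM mean decreases down a PSNR fixture ladder", {
  ph <- small_phantom(seed = 10, shape = c(64, 64, 8))
  ladder <- make_fixture_ladder(ph$volume, c(60, 50, 40))
  means <- sapply(ladder, function(r)
    ms_ssim_map(ph$volume$data[, , 4], r$reconstructed$data[, , 4],
                scales = 2)$mean)
  expect_true(all(diff(means) < 0))
})
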