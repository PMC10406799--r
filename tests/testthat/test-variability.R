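test_that("valid-slice selection applies the agreement threshold exactly", {
  jis <- c(0.9, 0.6, 0.7, 1.0, 0.3, 0.8, 0.0, 0.7, 0.5, 0.9)
  rec <- record_with_jis(jis)
  vs <- valid_slices(rec, t = 0.7)
  expect_identical(vs$slice_indices, which(jis >= 0.7))
  expect_equal(unname(vs$per_slice_ji), jis)

  # t = 0 keeps every slice with a defined index
  expect_identical(valid_slices(rec, 0)$slice_indices, 1:10)

  # identical timepoints: every annotated slice valid at any threshold
  rec_id <- observer_record("A", rec$s_t0, rec$s_t0)
  expect_identical(valid_slices(rec_id, 1)$slice_indices, 1:10)

  expect_error(valid_slices(rec, 1.2), "0, 1")
})

test_that("the threshold sweep is a monotone recount of retained slices", {
  jis <- c(0.9, 0.6, 0.7, 1.0, 0.3, 0.8, 0.0, 0.7, 0.5, 0.9)
  rec <- record_with_jis(jis)
  grid <- seq(0, 1, by = 0.1)
  curve <- threshold_sweep(rec, grid)
  # recount oracle
  manual <- sapply(grid, function(t) 100 * sum(jis >= t) / 10)
  expect_equal(curve$pct_kept, manual)
  expect_true(all(diff(curve$pct_kept) <= 0))

  rec_id <- observer_record("A", rec$s_t0, rec$s_t0)
  expect_true(all(threshold_sweep(rec_id, grid)$pct_kept == 100))
})

test_that("intra-observer variability: identity, exact means, empty-set
           error", {
  jis <- c(0.8, 0.9)
  rec <- record_with_jis(jis)
  res <- iaov(rec, t = 0.7)
  expect_equal(res$ji, 0.85)
  expect_identical(res$validity$slice_indices, 1:2)

  rec_id <- observer_record("A", rec$s_t0, rec$s_t0)
  res_id <- iaov(rec_id, t = 0.9)
  expect_equal(res_id$ji, 1)
  expect_equal(res_id$hd, 0)

  expect_error(iaov(rec, t = 0.95), "t = 0.95")
})

test_that("timepoint merging is the voxel-wise intersection", {
  jis <- c(0.8, 0.9)
  rec <- record_with_jis(jis)
  merged <- merge_timepoints(rec)
  expect_identical(merged$data, rec$s_t0$data & rec$s_t1$data)
  # intersection contract: merged within each input
  expect_true(all(!merged$data | rec$s_t0$data))
  expect_true(all(!merged$data | rec$s_t1$data))

  rec_id <- observer_record("A", rec$s_t0, rec$s_t0)
  expect_identical(merge_timepoints(rec_id)$data, rec$s_t0$data)

  a <- array(FALSE, c(4, 8, 2)); a[2, 1:3, ] <- TRUE
  b <- array(FALSE, c(4, 8, 2)); b[2, 5:7, ] <- TRUE
  rec_dis <- observer_record(
    "D", mask_stack(a, provenance = "D/t0"),
    mask_stack(b, provenance = "D/t1"))
  expect_equal(sum(merge_timepoints(rec_dis)$data), 0)

  set.seed(30)
  x <- array(runif(4 * 8 * 2) < 0.5, c(4, 8, 2))
  y <- array(runif(4 * 8 * 2) < 0.5, c(4, 8, 2))
  rec_r <- observer_record("R", mask_stack(x, provenance = "R/t0"),
                           mask_stack(y, provenance = "R/t1"))
  expect_equal(sum(merge_timepoints(rec_r)$data), sum(x & y))
})

test_that("inter-observer variability on a hand-computable fixture", {
  # observer A: JI per slice {0.9, 0.8, 0.6}; observer B: {1.0, 0.7, 0.9}
  recA <- record_with_jis(c(0.9, 0.8, 0.6), "A")
  recB <- record_with_jis(c(1.0, 0.7, 0.9), "B")
  # V_A at 0.7 = {1, 2}; V_B = {1, 2, 3}; V_AB = {1, 2}
  res <- ieov(recA, recB, t = 0.7)
  expect_identical(res$validity$slice_indices, 1:2)
  # merged masks: A keeps cols 1:9 and 1:8; B keeps 1:10 and 1:7 (row 2)
  # slice 1: |A&B| = 9, |A|B| = 10 -> 0.9 ; slice 2: 7/8
  expect_equal(res$ji, mean(c(9 / 10, 7 / 8)))

  # same observer twice: perfect agreement
  same <- ieov(recA, recA, t = 0.7)
  expect_equal(same$ji, 1)
  expect_equal(same$hd, 0)

  expect_error(ieov(recA, record_with_jis(c(0, 0, 0), "C"), t = 0.7),
               "V_AB")
})

test_that("conjunction of valid sets is contained in each observer's set", {
  ph <- small_phantom(seed = 6, shape = c(32, 32, 8))
  for (sd in 1:5) {
    recA <- observer_record(
      "A", simulate_observer(ph$mask, observer_model(seed = sd), 0),
      simulate_observer(ph$mask, observer_model(seed = sd), 1))
    recB <- observer_record(
      "B", simulate_observer(ph$mask, observer_model(seed = sd + 50), 0, "B"),
      simulate_observer(ph$mask, observer_model(seed = sd + 50), 1, "B"))
    vA <- valid_slices(recA, 0.5)$slice_indices
    vB <- valid_slices(recB, 0.5)$slice_indices
    res <- tryCatch(ieov(recA, recB, t = 0.5), error = function(e) NULL)
    if (is.null(res)) next
    expect_true(all(res$validity$slice_indices %in% vA))
    expect_true(all(res$validity$slice_indices %in% vB))
  }
})

test_that("per-run assertion: IaOV(JI) over V is at least the threshold", {
  jis <- c(0.9, 0.6, 0.7, 1.0, 0.3, 0.8)
  rec <- record_with_jis(jis)
  res <- iaov(rec, t = 0.7)
  expect_gte(res$ji, 0.7)
})

test_that("variability JSON twin serializes both baselines", {
  recA <- record_with_jis(c(0.9, 0.8, 0.6), "A")
  recB <- record_with_jis(c(1.0, 0.7, 0.9), "B")
  ia <- iaov(recA, 0.7)
  ie <- ieov(recA, recB, 0.7)
  path <- withr::local_tempfile(fileext = ".json")
  write_variability_json(ia, ie, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$IaOV$JI, ia$ji)
  expect_equal(back$IeOV$JI, ie$ji)
  expect_equal(back$t, 0.7)
})
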