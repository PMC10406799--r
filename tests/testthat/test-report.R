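test_that("Tukey comparison: power, self-similarity, degenerate input", {
  set.seed(51)
  strong <- list(
    condition_group("hi", pmin(pmax(rnorm(30, 0.9, 0.05), 0), 1)),
    condition_group("lo", pmin(pmax(rnorm(30, 0.5, 0.05), 0), 1)))
  res <- tukey_compare(strong)
  expect_true(res$table$significant[1])

  # two samples from the same values: never significant
  vals <- pmin(pmax(rnorm(30, 0.7, 0.05), 0), 1)
  same <- list(condition_group("a", vals), condition_group("b", vals))
  res2 <- tukey_compare(same)
  expect_false(res2$table$significant[1])
  expect_gt(res2$table$p_adj[1], 0.99)

  degen <- list(condition_group("a", rep(0.5, 10)),
                condition_group("b", rep(0.5, 10)))
  expect_error(tukey_compare(degen), "degenerate")
  expect_error(tukey_compare(strong[1]), "at least 2")
})

test_that("baseline flags identify which groups differ from which baseline", {
  set.seed(52)
  groups <- list(
    condition_group("raw-intra", rnorm(40, 0.85, 0.04)),
    condition_group("raw-inter", rnorm(40, 0.65, 0.04)),
    condition_group("enc-CR10", rnorm(40, 0.84, 0.04)),
    condition_group("enc-CR100", rnorm(40, 0.40, 0.04)))
  res <- tukey_compare(groups)
  fl <- res$flags
  expect_setequal(fl$group, c("enc-CR10", "enc-CR100"))
  expect_false(fl$differs_from_intra[fl$group == "enc-CR10"])
  expect_true(fl$differs_from_intra[fl$group == "enc-CR100"])
  expect_true(fl$differs_from_inter[fl$group == "enc-CR100"])
  expect_match(res$caveat, "independent")
})

test_that("Tukey decisions agree with a permutation oracle", {
  set.seed(53)
  agree <- 0L; total <- 60L
  for (r in seq_len(total)) {
    shift <- sample(c(0, 0, 0.08), 1)   # mix of null and alternative
    a <- rnorm(25, 0.7, 0.05)
    b <- rnorm(25, 0.7 + shift, 0.05)
    tk <- tukey_compare(list(condition_group("a", pmin(pmax(a, 0), 1)),
                             condition_group("b", pmin(pmax(b, 0), 1))))
    perm <- oracle_perm_test(a, b) < 0.05
    if (tk$table$significant[1] == perm) agree <- agree + 1L
  }
  expect_gte(agree / total, 0.95)
})

test_that("the validity decision applies the two-metric baseline rule", {
  inter <- condition_group("raw-inter", c(0.6, 0.65, 0.7), mean_hd = 0.8)

  ok <- condition_group("g1", c(0.7, 0.75), mean_hd = 0.5)
  expect_equal(validity_decision(ok, inter)$decision, "valid")

  # the JI-passes / HD-fails situation: invalid
  hd_fail <- condition_group("g2", c(0.7, 0.75), mean_hd = 1.2)
  d <- validity_decision(hd_fail, inter, tukey_flag = FALSE)
  expect_equal(d$decision, "invalid")
  expect_true(d$ji_pass)
  expect_false(d$hd_pass)
  expect_false(d$tukey_differs_from_inter)

  # boundary: equal to the baseline counts as meeting it, flagged as a tie
  tie <- condition_group("g3", inter$ji_values, mean_hd = 0.8)
  dt <- validity_decision(tie, inter)
  expect_equal(dt$decision, "valid")
  expect_true(dt$tie)

  expect_error(validity_decision(ok, condition_group("x", c(0.5, 0.6))),
               "finite")
})

test_that("rate-distortion curves are monotone and accommodate lossless", {
  ph <- small_phantom(seed = 1)
  ladder <- make_fixture_ladder(ph$volume, c(60, 50, 45))
  curve <- cr_quality_curve(ladder)
  expect_true(all(attr(curve, "monotone")))
  expect_true(all(diff(curve$psnr[curve$encoder == "wavelet"]) <= 0))

  with_ll <- c(ladder, list(encode_lossless(ph$volume)))
  curve2 <- cr_quality_curve(with_ll)
  ll <- curve2[curve2$encoder == "lossless", ]
  expect_true(is.finite(ll$cr) && ll$cr >= 1)
  expect_identical(ll$psnr, Inf)
})

test_that("predictive coding wins on redundant stacks at matched quality", {
  ph <- small_phantom(seed = 8, shape = c(48, 48, 8))
  sl <- ph$volume$data[, , 1]
  vol <- volume_stack(array(rep(sl, 16), c(48, 48, 16)), 16)
  rw <- encode_target_psnr(vol, 55)
  rp <- encode_qp_matched(vol, rw$global_psnr, tol = 1.5)
  curve <- cr_quality_curve(list(rw, rp))
  expect_gte(curve$cr[curve$encoder == "predictive"],
             curve$cr[curve$encoder == "wavelet"])
})

test_that("fewer, larger structures are easier to segment reproducibly", {
  seeds <- 1:8
  ji_few_large <- sapply(seeds, function(sd) {
    ph <- generate_phantom(phantom_config(
      shape = c(48, 48, 12), n_vessels = 2, radius_range = c(3, 4),
      seed = sd))
    om <- observer_model(seed = sd + 100)
    rec <- observer_record("A", simulate_observer(ph$mask, om, 0),
                           simulate_observer(ph$mask, om, 1))
    iaov(rec, t = 0)$ji
  })
  ji_many_small <- sapply(seeds, function(sd) {
    ph <- generate_phantom(phantom_config(
      shape = c(48, 48, 12), n_vessels = 12, radius_range = c(1, 1.5),
      seed = sd))
    om <- observer_model(seed = sd + 100)
    rec <- observer_record("A", simulate_observer(ph$mask, om, 0),
                           simulate_observer(ph$mask, om, 1))
    iaov(rec, t = 0)$ji
  })
  expect_gt(mean(ji_few_large), mean(ji_many_small))
})

test_that("complexity profiles expose per-slice covariates in range", {
  ph <- small_phantom(seed = 4, shape = c(32, 32, 8))
  om <- observer_model(seed = 7)
  rec <- observer_record("A", simulate_observer(ph$mask, om, 0),
                         simulate_observer(ph$mask, om, 1))
  prof <- complexity_profile(rec)
  expect_true(all(prof$per_slice$norm_area >= 0 &
                    prof$per_slice$norm_area <= 1))
  expect_true(all(prof$per_slice$n_annotations >= 0))
  expect_true(nrow(prof$trend_area) >= 1)

  # single-slice record: one scatter point
  arr <- array(FALSE, c(8, 8, 1)); arr[3:4, 3:4, 1] <- TRUE
  rec1 <- observer_record("S", mask_stack(arr, provenance = "S/t0"),
                          mask_stack(arr, provenance = "S/t1"))
  expect_equal(nrow(complexity_profile(rec1)$per_slice), 1)
})

test_that("storage arithmetic: identity and error cases, harmonic identity", {
  plans <- data.frame(modality = c("A", "B"), n_datasets = c(2, 3),
                      raw_size_mb = c(100, 50), chosen_cr = c(10, 5))
  res <- storage_reduction(plans)
  expect_equal(res$per_modality$reduced_mb, c(20, 30))
  # total fold equals the size-weighted harmonic composition of the CRs
  w <- res$per_modality$raw_total_mb / res$total_raw_mb
  expect_equal(res$fold_reduction, 1 / sum(w / plans$chosen_cr))

  one <- storage_reduction(data.frame(modality = "A", n_datasets = 1,
                                      raw_size_mb = 500, chosen_cr = 1))
  expect_equal(one$total_reduced_mb, 500)
  expect_error(storage_reduction(
    data.frame(modality = "A", n_datasets = 1, raw_size_mb = 500,
               chosen_cr = 0.5)), ">= 1")
})

test_that("the orchestrated audit returns a coherent bundle", {
  b <- run_audit(list(phantom = phantom_config(shape = c(48, 48, 16),
                                               seed = 2),
                      targets = c(60, 45)))
  expect_length(b$ladder, 2)
  expect_true(all(sapply(b$decisions, function(d)
    d$decision %in% c("valid", "invalid"))))
  expect_true(all(attr(b$cr_curve, "monotone")))
  expect_identical(b$texture$delta_wtv_pct[1], 0)
  # single-run baselines are stochastic; the IaOV >= IeOV ordering is a
  # statistical property tested over replicate seeds elsewhere
  expect_true(b$iaov$ji >= 0 && b$iaov$ji <= 1)
  expect_true(b$ieov$ji >= 0 && b$ieov$ji <= 1)
  # decisions are pure functions of their summaries: idempotent re-run
  g <- condition_group("g", c(0.8, 0.9), mean_hd = 0.1)
  bl <- condition_group("raw-inter", c(0.6, 0.7), mean_hd = 0.5)
  expect_identical(validity_decision(g, bl), validity_decision(g, bl))
})
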