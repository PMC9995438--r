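test_that("overlap metrics match their definitions on simple masks", {
  a <- array(c(rep(TRUE, 4), rep(FALSE, 5)), c(3, 3, 1))
  b <- array(c(FALSE, FALSE, rep(TRUE, 4), rep(FALSE, 3)), c(3, 3, 1))
  expect_identical(dsc(a, a), 1)
  expect_identical(jaccard(a, a), 1)
  expect_identical(sum(a & b), 2L)
  expect_equal(dsc(a, b), 0.5)        # 2*2 / (4+4)
  expect_equal(jaccard(a, b), 1 / 3)  # 2 / 6
  disjoint <- array(c(rep(FALSE, 4), rep(TRUE, 5)), c(3, 3, 1))
  expect_identical(dsc(a, disjoint), 0)
  expect_identical(jaccard(a, disjoint), 0)
  # empty-mask conventions: both empty agree perfectly, one empty is 0
  none <- array(FALSE, c(3, 3, 1))
  expect_identical(dsc(none, none), 1)
  expect_identical(jaccard(none, none), 1)
  expect_identical(dsc(a, none), 0)
  expect_error(dsc(a, array(TRUE, c(3, 1, 3))), "shapes differ")
})

test_that("Dice/Jaccard identities hold on random mask pairs", {
  set.seed(33)
  for (rep in 1:50) {
    a <- array(runif(18) < runif(1), c(3, 3, 2))
    b <- array(runif(18) < runif(1), c(3, 3, 2))
    d <- dsc(a, b)
    expect_equal(jaccard(a, b), d / (2 - d))
    expect_identical(dsc(b, a), d)        # symmetry
    expect_true(jaccard(a, b) <= d + 1e-12 && d <= 1 && d >= 0)
  }
})

test_that("agreement bands use half-open intervals with 0 and 1 pinned", {
  expect_identical(agreement_category(0), "No Agreement")
  expect_identical(agreement_category(0.1), "Slight agreement")
  expect_identical(agreement_category(0.2), "Fair agreement")
  expect_identical(agreement_category(0.39), "Fair agreement")
  expect_identical(agreement_category(0.4), "Moderate agreement")
  expect_identical(agreement_category(0.5), "Moderate agreement")
  expect_identical(agreement_category(0.6), "Substantial agreement")
  expect_identical(agreement_category(0.8), "Almost perfect agreement")
  expect_identical(agreement_category(0.85), "Almost perfect agreement")
  expect_identical(agreement_category(1), "Almost perfect agreement")
  expect_error(agreement_category(1.2), "0, 1")
  expect_error(agreement_category(-0.1), "0, 1")
})

test_that("region volumes convert voxel counts to milliliters", {
  mask <- array(FALSE, c(10, 10, 10))
  mask[1:10, 1:10, 1:10][seq_len(1000)] <- TRUE
  expect_equal(region_volume_ml(mask, c(1, 1, 1)), 1)
  expect_equal(region_volume_ml(array(FALSE, c(2, 2, 2)), c(1, 1, 1)), 0)
  m708 <- array(FALSE, c(12, 12, 12))
  m708[seq_len(708)] <- TRUE
  expect_equal(region_volume_ml(m708, c(1, 1, 1)), 0.708)
  expect_error(region_volume_ml(mask, c(0, 1, 1)), "positive")
  # additivity over disjoint regions
  a <- array(FALSE, c(4, 4, 4)); a[1:8] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[9:20] <- TRUE
  expect_equal(region_volume_ml(a, c(2, 2, 4)) + region_volume_ml(b, c(2, 2, 4)),
               region_volume_ml(a | b, c(2, 2, 4)))
})

test_that("per-image region metrics compare core with core, penumbra with penumbra", {
  res <- generate_study(zero_noise(small_spec()), "m1")
  gt <- build_lesion_map(res$study)
  rm_same <- region_metrics(gt, gt, "m1")
  expect_identical(rm_same$dsc, c(1, 1))
  expect_identical(rm_same$agreement, rep("Almost perfect agreement", 2))
  expect_equal(rm_same$gt_volume_ml, rm_same$pred_volume_ml)
  # degrade the prediction: drop the core entirely
  pred <- gt
  pred$labels[pred$labels == 3L] <- 2L
  rm2 <- region_metrics(gt, pred, "m1")
  expect_identical(rm2$dsc[rm2$region == "core"], 0)
  expect_lt(rm2$dsc[rm2$region == "penumbra"], 1)
  expect_identical(rm2$pred_volume_ml[rm2$region == "core"], 0)
})

test_that("cohort summaries aggregate metrics and run the paired tests", {
  set.seed(41)
  n <- 12
  vols <- sort(runif(n, 5, 60))
  d <- pmin(0.2 + 0.012 * vols + rnorm(n, 0, 0.02), 0.99)  # DSC grows with volume
  per <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(study_id = sprintf("s%02d", i),
               region = c("core", "penumbra"),
               dsc = d[i], ji = d[i] / (2 - d[i]),
               gt_volume_ml = vols[i], pred_volume_ml = vols[i] * d[i],
               agreement = agreement_category(d[i]))))
  rep <- cohort_summary(per)
  core <- rep$regions$core
  expect_equal(core$dsc_mean, mean(d))
  expect_equal(core$ji_mean, mean(d / (2 - d)))
  # JI = DSC/(2-DSC) < DSC below 1, so the paired test sees JI < DSC
  expect_lt(core$ji_mean, core$dsc_mean)
  expect_gt(core$dsc_vs_ji_t, 0)
  expect_lt(core$dsc_vs_ji_p, 0.05)
  expect_gt(core$dsc_vs_volume$r, 0)  # metrics rise with lesion volume
  # identical DSC and JI lists give t = 0, p = 1
  per0 <- per
  per0$ji <- per0$dsc
  rep0 <- cohort_summary(per0)
  expect_identical(rep0$regions$core$dsc_vs_ji_t, 0)
  expect_identical(rep0$regions$core$dsc_vs_ji_p, 1)
  expect_error(cohort_summary(per[per$study_id %in% c("s01", "s02"), ]),
               "at least 3")
})

test_that("follow-up volume correlation supports artifact exclusion", {
  set.seed(43)
  n <- 10
  followup <- runif(n, 5, 50)
  pred_vol <- followup + rnorm(n, 0, 2)
  flag <- rep(c(FALSE, TRUE), length.out = n)
  pred_vol[flag] <- pred_vol[flag] + runif(sum(flag), 40, 80)  # artifact overcall
  per <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(study_id = sprintf("s%02d", i), region = c("core", "penumbra"),
               dsc = 0.5, ji = 0.5 / 1.5, gt_volume_ml = followup[i],
               pred_volume_ml = pred_vol[i], agreement = "Moderate agreement")))
  rep <- cohort_summary(per, followup_volumes = followup, artifact_flag = flag)
  expect_gt(rep$followup$no_artifact$r, rep$followup$all$r)
  expect_gt(rep$followup$no_artifact$r, 0.9)
  expect_error(cohort_summary(per, followup_volumes = followup[1:3]),
               "one volume per image")
})
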