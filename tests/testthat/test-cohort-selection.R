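test_that("referral prevalence solves the proportion-diagnosed identity", {
  # 24% of referred patients diagnosed under sn 0.54 / sp 0.84 -> 21% true
  p <- referral_prevalence(0.24, 0.54, 0.84)
  expect_equal(p, 0.08 / 0.38, tolerance = 1e-12)
  expect_equal(round(100 * p), 21)
  # forward evaluation closes the identity
  expect_equal(p * 0.54 + (1 - p) * 0.16, 0.24, tolerance = 1e-12)

  expect_equal(referral_prevalence(0.54, 0.54, 0.84), 1)   # all diseased
  expect_equal(referral_prevalence(0.16, 0.54, 0.84), 0)   # none diseased
  expect_error(referral_prevalence(0.10, 0.54, 0.84), "attainable interval")
  expect_error(referral_prevalence(0.24, 0.3, 0.6), "uninformative")
})

test_that("post-MRI prevalence reproduces the published enrichment chain", {
  p_ref <- referral_prevalence(0.24, 0.54, 0.84)
  expect_equal(post_mri_prevalence(p_ref, 0.54, 0.84), 0.127, tolerance = 0.005)
  # excluding 10/20/40% of correctly negative non-AD patients -> 14/15/19%
  enriched <- vapply(c(0.10, 0.20, 0.40), function(f) {
    post_mri_prevalence(p_ref, 0.54, 0.84, f)
  }, numeric(1))
  # published as whole percentages; full precision gives 14.0/15.4/19.6
  expect_true(all(abs(100 * enriched - c(14, 15, 19)) < 1))
  expect_equal(post_mri_prevalence(p_ref, 0.54, 0.84, 1.0), 1.0)
  # strictly increasing in the exclusion fraction and in referral prevalence
  fs <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(vapply(fs, function(f)
    post_mri_prevalence(0.21, 0.54, 0.84, f), numeric(1))) > 0))
  prevs <- seq(0.05, 0.6, by = 0.05)
  expect_true(all(diff(vapply(prevs, function(p)
    post_mri_prevalence(p, 0.54, 0.84, 0.2), numeric(1))) > 0))
})

test_that("memory-impairment subcohort prevalence matches the published 39%", {
  p_ref <- referral_prevalence(0.24, 0.54, 0.84)
  expect_lt(abs(memory_subcohort_prevalence(p_ref, 0.93, 0.68, 0.54, 0.84)
                - 0.39), 0.005)
  expect_error(memory_subcohort_prevalence(0.2, 0.54, 0.84, 0.54, 0.84),
               "empty subcohort")
  # cross-checked by direct confusion-table enumeration: in a population with
  # p = 0.5, count patients positive on memory but negative on the combined
  # criterion, assuming nested positivity (the memory criterion flags a
  # superset of those the stricter criterion flags)
  n <- 10000; p <- 0.5
  diseased <- p * n
  mem_pos_d <- diseased * 1.0; mr_pos_d <- diseased * 0.5
  sub_d <- mem_pos_d - mr_pos_d
  healthy <- (1 - p) * n
  mem_pos_h <- healthy * (1 - 0.5); mr_pos_h <- healthy * (1 - 0.75)
  sub_h <- mem_pos_h - mr_pos_h
  expect_equal(memory_subcohort_prevalence(0.5, 1.0, 0.5, 0.5, 0.75),
               sub_d / (sub_d + sub_h), tolerance = 1e-12)
  expect_equal(sub_d / (sub_d + sub_h), 2 / 3, tolerance = 1e-12)
})

test_that("conditional biomarker accuracy solves the composition identities", {
  bm <- conditional_biomarker_accuracy(0.86, 0.79, 0.54, 0.84)
  expect_equal(bm$sp, 0.941, tolerance = 0.001)
  # printed 0.698 was derived from unrounded inputs; printed inputs give 0.6957
  expect_equal(bm$sn, 0.698, tolerance = 0.005)
  expect_equal(bm$sn, (0.86 - 0.54) / 0.46, tolerance = 1e-12)

  # composing back through the identities reproduces the combined accuracy
  expect_equal(0.54 + (1 - 0.54) * bm$sn, 0.86, tolerance = 1e-12)
  expect_equal(0.84 * bm$sp, 0.79, tolerance = 1e-12)

  ident <- conditional_biomarker_accuracy(0.54, 0.84, 0.54, 0.84)
  expect_equal(ident$sn, 0)
  expect_equal(ident$sp, 1)
  expect_error(conditional_biomarker_accuracy(0.5, 0.79, 0.54, 0.84),
               "combined_sn >= mr_sn")
  expect_error(conditional_biomarker_accuracy(0.86, 0.9, 0.54, 0.84),
               "combined_sp <= mr_sp")
})

test_that("outcome probabilities match the published splits and sum to one", {
  pr <- outcome_probabilities(0.127, 0.698, 0.941)
  expect_equal(100 * pr$p_tp, 8.9, tolerance = 0.05)
  expect_equal(100 * pr$p_fn, 3.8, tolerance = 0.05)
  expect_equal(100 * pr$p_fp, 5.2, tolerance = 0.05)
  expect_equal(100 * pr$p_tn, 82.1, tolerance = 0.05)

  none <- outcome_probabilities(0, 0.7, 0.9)
  expect_equal(unlist(none[c("p_tp", "p_fn", "p_fp", "p_tn")]),
               c(p_tp = 0, p_fn = 0, p_fp = 0.1, p_tn = 0.9))
  all_d <- outcome_probabilities(1, 0.7, 0.9)
  expect_equal(unlist(all_d[c("p_tp", "p_fn", "p_fp", "p_tn")]),
               c(p_tp = 0.7, p_fn = 0.3, p_fp = 0, p_tn = 0))

  grid <- expand.grid(p = seq(0, 1, 0.25), sn = seq(0, 1, 0.25),
                      sp = seq(0, 1, 0.25))
  sums <- mapply(function(p, sn, sp) {
    x <- outcome_probabilities(p, sn, sp)
    x$p_tp + x$p_fn + x$p_fp + x$p_tn
  }, grid$p, grid$sn, grid$sp)
  expect_equal(sums, rep(1, nrow(grid)), tolerance = 1e-12)
  # the disease margin is preserved
  pr2 <- outcome_probabilities(0.3, 0.6, 0.8)
  expect_equal(pr2$p_tp + pr2$p_fn, 0.3, tolerance = 1e-12)
})

test_that("the parameter-set prevalence chain uses full precision", {
  p <- pretest_prevalence(base_ps)
  expect_equal(p, 0.1274238, tolerance = 1e-6)
})
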