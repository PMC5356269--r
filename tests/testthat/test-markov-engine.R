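test_that("hazard-to-probability conversion matches the published rate pairs", {
  # 28,768 per 100,000/yr <-> 25% annual discontinuation
  expect_equal(annual_hazard_to_cycle_prob(28768, 12), 0.25, tolerance = 1e-4)
  # 62,362 <-> 46.4% annual (facility dwellers)
  expect_equal(annual_hazard_to_cycle_prob(62362, 12), 0.464, tolerance = 1e-3)
  expect_equal(annual_hazard_to_cycle_prob(0, 1), 0)
  expect_equal(annual_hazard_to_cycle_prob(27710, 1),
               1 - exp(-0.2771 / 12), tolerance = 1e-12)
  expect_lt(abs(annual_hazard_to_cycle_prob(27710, 1) - 0.02283), 5e-6)
  expect_error(annual_hazard_to_cycle_prob(-5), ">= 0")
})

test_that("other-cause mortality follows the fitted exponential", {
  expect_equal(other_cause_mortality_rate(0, base_ps), 3.53)
  expect_equal(other_cause_mortality_rate(65, base_ps), 3.53 * exp(0.0909 * 65))
  expect_equal(other_cause_mortality_rate(65, base_ps), 1300, tolerance = 2e-3)
  ages <- seq(40, 100, 5)
  expect_true(all(diff(other_cause_mortality_rate(ages, base_ps)) > 0))
})

test_that("death probability composes mortality rate and severity HR", {
  p_sev <- cycle_death_prob(65, "severe", base_ps)
  expect_equal(p_sev,
               1 - exp(-(3.53 * exp(0.0909 * 65) * 9.52 / 1e5) / 12),
               tolerance = 1e-12)
  # non-AD mortality is linked to the mild-AD HR
  expect_equal(cycle_death_prob(65, "nonad", base_ps),
               cycle_death_prob(65, "mild", base_ps))
})

test_that("baseline cost curve caps at the 90+ average", {
  expect_equal(baseline_annual_cost(65, base_ps), 12337, tolerance = 1e-3)
  expect_equal(baseline_annual_cost(95, base_ps), 33870)
  expect_equal(baseline_annual_cost(90, base_ps), 33870)  # curve exceeds cap
  expect_lt(baseline_annual_cost(89.9, base_ps), 33880)
})

test_that("per-state cost and utility follow the published tables", {
  c_mild <- cycle_cost(65, "AD", "mild", "community", FALSE, base_ps)
  expect_equal(c_mild, (baseline_annual_cost(65, base_ps) + 24128) / 12)
  c_sev <- cycle_cost(80, "AD", "severe", "ltcf", TRUE, base_ps)
  expect_equal(c_sev,
               (baseline_annual_cost(80, base_ps) + 9847 + 83950 + 3192) / 12)
  # non-AD is costed as mild AD at the same age and location
  expect_equal(cycle_cost(72, "nonAD", location = "community", ps = base_ps),
               cycle_cost(72, "AD", "mild", "community", ps = base_ps))

  expect_equal(cycle_utility(67, "AD", "moderate", "community", FALSE, base_ps),
               0.82 * 0.54 / 12)
  expect_equal(cycle_utility(67, "AD", "severe", "community", TRUE, base_ps),
               (0.82 * 0.37 + 0.051) / 12)
  # age bands are stepwise constant, extended at both ends
  expect_equal(age_band_weight(c(55, 62, 83, 101), base_ps),
               c(0.83, 0.83, 0.74, 0.74))
})

test_that("conditional transition matrices are row-stochastic with the
           published treated/untreated contrast", {
  v <- model_inputs(base_ps)
  for (group in c("TP", "FN", "FP", "TN")) {
    mod <- csfcea:::build_group_model(v, group, scenario_flags())
    expect_equal(unname(rowSums(mod$cond)), rep(1, nrow(mod$cond)),
                 tolerance = 1e-12)
    expect_true(all(mod$cond >= 0))
    # LTCF -> community transitions are structurally impossible
    ltcf <- grepl("ltcf", mod$states$name)
    expect_true(all(mod$cond[ltcf, !ltcf] == 0))
  }
  mod <- csfcea:::build_group_model(v, "TP", scenario_flags())
  M <- mod$cond
  to_moderate <- grepl("^moderate", colnames(M))
  # marginal monthly progression probabilities; the tiny deficit relative to
  # the single-event closed form comes from competing-risk allocation with
  # the mild-to-severe hazard
  expect_lt(abs(sum(M["mild.community.off", to_moderate]) - 0.02283), 5e-5)
  expect_lt(abs(sum(M["mild.community.on", to_moderate]) -
                  (1 - exp(-0.2771 * 0.5 / 12))), 5e-5)
  expect_lt(abs(sum(M["mild.community.on", to_moderate]) - 0.01148), 5e-5)
})

test_that("cohort occupancy conserves mass every cycle", {
  o <- run_cohort("TP", base_ps, trace = TRUE)
  occ_cols <- setdiff(names(o$trace),
                      c("month", "age", "dead", "cycle_cost", "cycle_qaly",
                        "discount"))
  live <- rowSums(o$trace[, occ_cols])
  expect_true(all(abs(live + o$trace$dead - 1) < 1e-10))
})

test_that("interpreted and compiled engines agree to machine precision", {
  v <- model_inputs(base_ps)
  for (group in c("TP", "FN", "FP", "TN")) {
    mod <- csfcea:::build_group_model(v, group, scenario_flags())
    a <- csfcea:::run_markov_model(mod, v, use_compiled = TRUE)
    b <- csfcea:::run_markov_model(mod, v, use_compiled = FALSE)
    expect_equal(unclass(a)[1:4], unclass(b)[1:4], tolerance = 1e-12)
  }
})

test_that("treatment-free dynamics make the TP and FN groups coincide", {
  ps <- base_ps
  for (id in c("treatment.uptake_donepezil", "treatment.uptake_memantine",
               "treatment.reinit_donepezil", "treatment.reinit_memantine")) {
    ps <- set_param(ps, id, param_value(0, kind = get_param(ps, id)$kind))
  }
  tp <- run_cohort("TP", ps)
  fn <- run_cohort("FN", ps)
  expect_equal(tp$cost, fn$cost, tolerance = 1e-10)
  expect_equal(tp$qalys, fn$qalys, tolerance = 1e-10)
  expect_equal(tp$life_years, fn$life_years, tolerance = 1e-10)
})

test_that("base-case outcome orderings hold", {
  o <- base_outcomes()
  # treatment does not affect mortality in non-AD: FP and TN lifetimes and
  # quality of life coincide exactly; only drug costs differ
  expect_equal(o$FP$life_years, o$TN$life_years, tolerance = 1e-12)
  expect_equal(o$FP$disc_life_years, o$TN$disc_life_years, tolerance = 1e-12)
  expect_equal(o$FP$qalys, o$TN$qalys, tolerance = 1e-12)
  expect_gt(o$FP$cost, o$TN$cost)
  # treatment in AD is beneficial: cheaper, more QALYs, no shorter life
  expect_lt(o$TP$cost, o$FN$cost)
  expect_gt(o$TP$qalys, o$FN$qalys)
  expect_gte(o$TP$life_years, o$FN$life_years)
})

test_that("undiscounted accrual dominates discounted accrual", {
  ps <- base_ps
  ps$settings$discount_rate <- 0
  o0 <- run_cohort("TP", ps)
  o3 <- run_cohort("TP", base_ps)
  expect_gt(o0$qalys, o3$qalys)
  expect_equal(o0$life_years, o0$disc_life_years, tolerance = 1e-12)
})

test_that("lifetime QALYs are non-increasing in start age", {
  qalys <- vapply(c(55, 65, 75), function(a) {
    run_cohort("TP", set_param(base_ps, "cohort.start_age", a))$qalys
  }, numeric(1))
  expect_true(all(diff(qalys) < 0))
})

test_that("QALYs never exceed life-years times the maximum utility weight", {
  for (o in base_outcomes()) {
    expect_lte(o$qalys, o$disc_life_years * 0.83)
    expect_gte(o$cost, 0)
    expect_gte(o$qalys, 0)
  }
})
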