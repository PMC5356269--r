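test_that("fitted distributions preserve the mean and recover the range", {
  up <- distribution_for(param_value(0.45, 0.27, 0.56, "probability"))
  expect_equal(up$family, "beta")
  a <- up$pars[["shape1"]]; b <- up$pars[["shape2"]]
  expect_equal(a / (a + b), 0.45, tolerance = 1e-9)
  # the fit preserves the mean and the 95% interval width; for an
  # asymmetric published range the interval position shifts slightly
  q <- qbeta(c(0.025, 0.975), a, b)
  expect_equal(diff(q), 0.56 - 0.27, tolerance = 1e-6)
  expect_lt(abs(q[1] - 0.27), 0.05)
  expect_lt(abs(q[2] - 0.56), 0.05)

  cost <- distribution_for(param_value(463, 250, 600, "cost"))
  expect_equal(cost$family, "gamma")
  expect_equal(cost$pars[["shape"]] / cost$pars[["rate"]], 463,
               tolerance = 1e-9)
  expect_equal(diff(qgamma(c(0.025, 0.975), cost$pars[["shape"]],
                           rate = cost$pars[["rate"]])), 350,
               tolerance = 0.01)

  hr <- distribution_for(param_value(0.37, 0.20, 0.50, "hazard_ratio"))
  expect_equal(hr$family, "lognormal")
  expect_equal(exp(hr$pars[["meanlog"]] + hr$pars[["sdlog"]]^2 / 2), 0.37,
               tolerance = 1e-9)  # mean-preserving

  pt <- distribution_for(param_value(0.24, kind = "probability"))
  expect_equal(pt$family, "point")
  set.seed(1)
  expect_equal(unique(csfcea:::draw_spec(pt, 50)), 0.24)
})

test_that("very narrow published ranges still fit", {
  # the tightest utility band in the table
  d <- distribution_for(param_value(0.82, 0.820, 0.826, "utility"))
  expect_equal(d$family, "beta")
  w <- diff(qbeta(c(0.025, 0.975), d$pars[["shape1"]], d$pars[["shape2"]]))
  expect_equal(w, 0.006, tolerance = 0.01)
})

test_that("parameter draws are reproducible, valid, and mean-centred", {
  dists <- psa_distributions(base_ps)
  expect_false(any(c("accuracy.combined_sn", "accuracy.combined_sp")
                   %in% names(dists)))
  set.seed(5); s1 <- sample_parameter_set(base_ps, dists)
  set.seed(5); s2 <- sample_parameter_set(base_ps, dists)
  expect_identical(s1, s2)

  set.seed(11)
  draws <- replicate(200, sample_parameter_set(base_ps, dists),
                     simplify = FALSE)
  for (sm in draws[1:25]) expect_length(validate_parameters(sm), 0)
  # severity mix renormalized exactly
  mixsums <- vapply(draws, function(sm) {
    sm$cohort$severity_mild + sm$cohort$severity_moderate +
      sm$cohort$severity_severe
  }, numeric(1))
  expect_equal(mixsums, rep(1, 200), tolerance = 1e-12)
  # linked non-AD fields follow the drawn mild-AD values
  expect_equal(vapply(draws, function(s) s$mortality$hr_nonad, numeric(1)),
               vapply(draws, function(s) s$mortality$hr_mild, numeric(1)))
  # sampled accuracies stay in [0, 1]
  sns <- vapply(draws, function(s) s$accuracy$bm_sn, numeric(1))
  expect_true(all(sns >= 0 & sns <= 1))

  # empirical mean of an unconstrained parameter within 2 SE of its base
  set.seed(21)
  upt <- replicate(4000, csfcea:::draw_spec(dists$`treatment.uptake_donepezil`))
  se <- sd(upt) / sqrt(length(upt))
  expect_lt(abs(mean(upt) - 0.45), 2 * se)
  set.seed(22)
  fac <- replicate(4000, csfcea:::draw_spec(dists$`costs.facility`))
  expect_lt(abs(mean(fac) - 83950), 2 * sd(fac) / sqrt(length(fac)))
})

test_that("microsimulation is reproducible and handles degenerate dynamics", {
  a <- microsimulate_cohort("TN", base_ps, n = 500, seed = 4)
  b <- microsimulate_cohort("TN", base_ps, n = 500, seed = 4)
  expect_identical(unclass(a), unclass(b))

  # no transitions and no mortality: everyone reaches the stopping age
  ps <- base_ps
  ps$mortality$coeff_a <- param_value(0)
  for (id in grep("^rates\\.", param_table(ps)$id, value = TRUE)) {
    ps <- set_param(ps, id, param_value(0, kind = "rate"))
  }
  ms <- microsimulate_cohort("TN", ps, n = 20, seed = 2)
  expect_equal(ms$life_years, 120 - 65, tolerance = 1e-9)
  expect_equal(ms$life_years_se, 0)
  co <- run_cohort("TN", ps)
  expect_equal(co$life_years, 120 - 65, tolerance = 1e-6)
})

test_that("microsimulation agrees with the cohort engine at moderate n", {
  ms <- microsimulate_cohort("FN", base_ps, n = 4000, seed = 17)
  co <- run_cohort("FN", base_ps)
  expect_lt(abs(co$cost - ms$cost), 3 * ms$cost_se)
  expect_lt(abs(co$qalys - ms$qalys), 3 * ms$qalys_se)
  expect_lt(abs(co$life_years - ms$life_years), 3 * ms$life_years_se)
})
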