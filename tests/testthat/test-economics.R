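test_that("strategy aggregation reproduces the published strategy rows from
           the published outcome rows", {
  # do nothing at prevalence 0.127: AD patients follow the untreated
  # trajectory, non-AD the true-negative one
  dn <- csfcea:::strategy_do_nothing(0.127, published)
  expect_lt(abs(dn$cost - 286587), 5)
  expect_lt(abs(dn$qalys - 4.745), 0.001)

  probs <- outcome_probabilities(0.127, 0.698, 0.941)
  bm <- aggregate_strategy(probs, published, test_cost = 463,
                           test_toll = 0.008, tested = TRUE,
                           label = "biomarker")
  expect_lt(abs(bm$cost - 286752), 5)
  expect_lt(abs(bm$qalys - 4.760), 0.001)

  # with no test cost or toll and matching probabilities, tested and
  # untested aggregation coincide
  a <- aggregate_strategy(probs, published, tested = FALSE)
  b <- aggregate_strategy(probs, published, test_cost = 0, test_toll = 0,
                          tested = TRUE)
  expect_equal(a$cost, b$cost)
  expect_equal(a$qalys, b$qalys)

  expect_error(aggregate_strategy(probs, published[c("TP", "FN")]),
               "must contain")
})

test_that("incremental classification follows the sign quadrants", {
  s <- function(cost, qalys) {
    structure(list(cost = cost, qalys = qalys), class = "strategy_result")
  }
  expect_equal(compare_strategies(s(100, 1.01), s(200, 1))$classification,
               "dominant")
  expect_equal(compare_strategies(s(300, 0.99), s(200, 1))$classification,
               "dominated")
  tr <- compare_strategies(s(200165, 1.015), s(200000, 1))
  expect_equal(tr$classification, "tradeoff")
  expect_equal(tr$icer, 165 / 0.015, tolerance = 1e-9)
  same <- compare_strategies(s(100, 1), s(100, 1))
  expect_equal(same$classification, "equivalent")
  expect_equal(same$delta_cost, 0)
  # zero QALY difference classifies by cost sign with undefined ICER
  flat <- compare_strategies(s(90, 1), s(100, 1))
  expect_equal(flat$classification, "dominant")
  expect_true(is.na(flat$icer))
})

test_that("net monetary benefit is consistent with the ICER", {
  dn <- csfcea:::strategy_do_nothing(0.127, published)
  probs <- outcome_probabilities(0.127, 0.698, 0.941)
  bm <- aggregate_strategy(probs, published, test_cost = 463,
                           test_toll = 0.008, tested = TRUE)
  expect_equal(net_monetary_benefit(dn, 0), -dn$cost)
  inc <- compare_strategies(bm, dn)
  at_icer <- net_monetary_benefit(bm, inc$icer) -
    net_monetary_benefit(dn, inc$icer)
  expect_equal(at_icer, 0, tolerance = 1e-6)
  # NMB difference decomposes into the INMB test-comparison formula
  spec <- challenge_region_spec(published, 0.127, 50000,
                                delta_test_cost = 463,
                                delta_test_qaly = 0.008)
  expect_equal(inmb_test_comparison(spec, 0.698, 0.941),
               net_monetary_benefit(bm, 50000) -
                 net_monetary_benefit(dn, 50000),
               tolerance = 1e-6)
})

test_that("INMB formula reproduces the published per-case values and is
           linear in its arguments", {
  spec <- challenge_region_spec(published, 0.127, 50000)
  # equal accuracy: only the test-cost and test-QALY terms remain
  spec463 <- challenge_region_spec(published, 0.127, 50000,
                                   delta_test_cost = 463,
                                   delta_test_qaly = 0.008)
  expect_equal(inmb_test_comparison(spec463, spec463$q1, spec463$q2),
               -463 - 50000 * 0.008)
  # value of preventing one false negative / one false positive (cost terms)
  expect_equal(spec$cost_fn - spec$cost_tp, 9954)
  expect_equal(spec$cost_fp - spec$cost_tn, 11345)

  # linearity by finite differences
  d1 <- inmb_test_comparison(spec, 0.6, 0.9) - inmb_test_comparison(spec, 0.5, 0.9)
  d1b <- inmb_test_comparison(spec, 0.9, 0.9) - inmb_test_comparison(spec, 0.8, 0.9)
  expect_equal(d1, d1b, tolerance = 1e-9)
  d2 <- inmb_test_comparison(spec, 0.5, 0.8) - inmb_test_comparison(spec, 0.5, 0.7)
  d2b <- inmb_test_comparison(spec, 0.5, 1.0) - inmb_test_comparison(spec, 0.5, 0.9)
  expect_equal(d2, d2b, tolerance = 1e-9)
  s1 <- challenge_region_spec(published, 0.127, 60000)
  s2 <- challenge_region_spec(published, 0.127, 70000)
  s3 <- challenge_region_spec(published, 0.127, 80000)
  expect_equal(inmb_test_comparison(s2, 0.7, 0.9) - inmb_test_comparison(s1, 0.7, 0.9),
               inmb_test_comparison(s3, 0.7, 0.9) - inmb_test_comparison(s2, 0.7, 0.9),
               tolerance = 1e-6)
})

test_that("challenge region is anchored, nested in prevalence, and grows
           with the threshold", {
  outcomes <- base_outcomes()
  # with no test cost or toll, the no-test point (0, 1) lies on the boundary
  free <- challenge_region_spec(outcomes, 0.127, 50000)
  expect_equal(inmb_test_comparison(free, 0, 1), 0)
  cr <- challenge_region(free, grid_step = 0.05)
  b <- cr$boundary
  expect_equal(b[["a0"]] + b[["a1"]] * 0 + b[["a2"]] * 1, 0, tolerance = 1e-9)

  v <- model_inputs(base_ps)
  region <- function(p, lambda) {
    spec <- challenge_region_spec(outcomes, p, lambda,
                                  delta_test_cost = v$costs$test_cost,
                                  delta_test_qaly = v$utilities$lp_toll)
    challenge_region(spec, grid_step = 0.05)$grid$admissible
  }
  regions <- lapply(c(0.075, 0.127, 0.15, 0.30), region, lambda = 50000)
  for (i in 2:4) {
    expect_true(all(regions[[i]][regions[[i - 1]]]))          # nesting
    expect_gt(sum(regions[[i]]), sum(regions[[i - 1]]))       # strict growth
  }
  # when both outcome INMB terms are positive, raising the threshold can
  # only enlarge the region
  s50 <- challenge_region_spec(outcomes, 0.127, 50000,
                               delta_test_cost = v$costs$test_cost,
                               delta_test_qaly = v$utilities$lp_toll)
  s100 <- challenge_region_spec(outcomes, 0.127, 100000,
                                delta_test_cost = v$costs$test_cost,
                                delta_test_qaly = v$utilities$lp_toll)
  b50 <- challenge_region(s50, 0.05)$boundary
  expect_gt(b50[["a1"]], 0)
  expect_gt(b50[["a2"]], 0)
  r50 <- challenge_region(s50, 0.05)$grid$admissible
  r100 <- challenge_region(s100, 0.05)$grid$admissible
  expect_true(all(r100[r50]))
})

test_that("the full pipeline ties its pieces together consistently", {
  res <- base_cea()
  # totals equal the probability-weighted outcome values plus test cost/toll
  p <- unlist(res$probs[c("p_tp", "p_fn", "p_fp", "p_tn")])
  manual_cost <- sum(p * vapply(res$outcomes[c("TP", "FN", "FP", "TN")],
                                `[[`, numeric(1), "cost")) +
    res$inputs$costs$test_cost
  expect_equal(res$biomarker$cost, manual_cost, tolerance = 1e-9)
  expect_equal(res$incremental$delta_cost,
               res$biomarker$cost - res$do_nothing$cost)
  tab <- render_table2(res)
  expect_equal(sum(tab$probability, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_equal(tab$cost[tab$row == "do_nothing"], res$do_nothing$cost)
  # CSV round-trip preserves values
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  render_table2(res, path = f)
  back <- read.csv(f)
  expect_equal(back$cost, tab$cost, tolerance = 1e-9)
})
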