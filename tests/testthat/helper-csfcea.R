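# Shared fixtures.

base_ps <- default_parameters()

# Published per-outcome lifetime values (discounted cost, discounted
# life-years, discounted QALYs) used as *inputs* for the aggregation-identity
# and net-benefit tests, and as comparison values for model reproduction.
published <- list(
  TP = list(cost = 298632, life_years = 6.781, disc_life_years = 6.781, qalys = 2.916),
  FN = list(cost = 308586, life_years = 6.555, disc_life_years = 6.555, qalys = 2.660),
  FP = list(cost = 294732, life_years = 9.157, disc_life_years = 9.157, qalys = 5.048),
  TN = list(cost = 283387, life_years = 9.157, disc_life_years = 9.157, qalys = 5.048)
)

# run the four outcome groups once per session and reuse across tests
base_outcomes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- lapply(stats::setNames(nm = c("TP", "FN", "FP", "TN")),
                       run_cohort, ps = base_ps)
    }
    cache
  }
})

base_cea <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_cea(base_ps, outcomes = base_outcomes())
    cache
  }
})

expect_rel <- function(actual, target, tol) {
  expect_lt(abs(actual - target) / abs(target), tol)
}
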