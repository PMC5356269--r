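# Strategy aggregation, incremental cost-effectiveness, net monetary benefit,
# and the challenge-region computation for hypothetical test characteristics.

#' Aggregate per-outcome lifetime values into a strategy result
#'
#' Probability-weights the four diagnostic-outcome lifetime values; a tested
#' strategy additionally pays the test cost and the one-time QALY toll of the
#' test (both applied to every tested patient, undiscounted, at time zero).
#'
#' @param probs an [outcome_probabilities()] object (sums to 1).
#' @param outcomes named list with `TP`, `FN`, `FP`, `TN`
#'   [run_cohort()] results.
#' @param test_cost,test_toll per-patient cost (US$) and QALY toll of testing;
#'   ignored when `tested = FALSE`.
#' @param tested whether the strategy performs the test.
#' @param label strategy label.
#' @return an object of class `strategy_result` with `cost`, `qalys`,
#'   `life_years`, `disc_life_years`, and the per-outcome breakdown.
#' @export
aggregate_strategy <- function(probs, outcomes, test_cost = 0, test_toll = 0,
                               tested = FALSE, label = "strategy") {
  need <- c("TP", "FN", "FP", "TN")
  if (!all(need %in% names(outcomes))) {
    stop("outcomes must contain TP, FN, FP, TN entries", call. = FALSE)
  }
  p <- c(probs$p_tp, probs$p_fn, probs$p_fp, probs$p_tn)
  if (abs(sum(p) - 1) > 1e-9) {
    stop("outcome probabilities must sum to 1", call. = FALSE)
  }
  pull <- function(field) vapply(outcomes[need], `[[`, numeric(1), field)
  res <- list(
    label = label,
    cost = sum(p * pull("cost")) + if (tested) test_cost else 0,
    qalys = sum(p * pull("qalys")) - if (tested) test_toll else 0,
    life_years = sum(p * pull("life_years")),
    disc_life_years = sum(p * pull("disc_life_years")),
    probs = probs,
    outcomes = outcomes,
    tested = tested
  )
  class(res) <- "strategy_result"
  res
}

# the do-nothing strategy: no test, so every AD patient follows the untreated
# (false-negative) trajectory and every non-AD patient the true-negative one.
strategy_do_nothing <- function(prevalence, outcomes) {
  probs <- structure(list(p_tp = 0, p_fn = prevalence, p_fp = 0,
                          p_tn = 1 - prevalence), class = "outcome_probs")
  aggregate_strategy(probs, outcomes, tested = FALSE, label = "do_nothing")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s: cost $%s, QALYs %.3f\n", x$label,
              format(round(x$cost), big.mark = ","), x$qalys))
  invisible(x)
}

#' Incremental comparison of two strategies
#'
#' Classifies the comparison by the signs of the incremental cost and QALYs
#' (`dominant` when the new strategy saves money and gains QALYs, `dominated`
#' for the reverse) and computes the ICER only in the trade-off quadrants.
#'
#' @param new,ref `strategy_result` objects (new is compared against ref).
#' @return an object of class `incremental_result` with `delta_cost`,
#'   `delta_qalys`, `classification`, `icer`.
#' @export
compare_strategies <- function(new, ref) {
  dc <- new$cost - ref$cost
  dq <- new$qalys - ref$qalys
  if (dc == 0 && dq == 0) {
    cls <- "equivalent"; icer <- NA_real_
  } else if (dq == 0) {
    cls <- if (dc < 0) "dominant" else "dominated"; icer <- NA_real_
  } else if (dc <= 0 && dq > 0) {
    cls <- "dominant"; icer <- NA_real_
  } else if (dc >= 0 && dq < 0) {
    cls <- "dominated"; icer <- NA_real_
  } else {
    cls <- "tradeoff"; icer <- dc / dq
  }
  structure(list(delta_cost = dc, delta_qalys = dq,
                 classification = cls, icer = icer),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("<incremental_result> %+.0f US$, %+.4f QALYs: %s",
              x$delta_cost, x$delta_qalys, x$classification))
  if (!is.na(x$icer)) cat(sprintf(" (ICER $%s/QALY)",
                                  format(round(x$icer), big.mark = ",")))
  cat("\n")
  invisible(x)
}

#' Net monetary benefit of a strategy
#'
#' @param s a `strategy_result`.
#' @param lambda willingness-to-pay threshold (US$/QALY).
#' @return `lambda * qalys - cost`, in US$.
#' @export
net_monetary_benefit <- function(s, lambda) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  lambda * s$qalys - s$cost
}

#' Full cost-effectiveness analysis of biomarker testing vs doing nothing
#'
#' End-to-end base-case (or scenario) analysis: derives the pretest prevalence
#' from the cohort-selection chain (unless supplied), forms the
#' diagnostic-outcome probabilities from the conditional biomarker accuracy,
#' runs the lifetime cohort model for each outcome group, aggregates both
#' strategies, and compares them.
#'
#' @param ps parameter set.
#' @param flags structural [scenario_flags()].
#' @param prevalence pretest prevalence override (default: computed by
#'   [pretest_prevalence()]).
#' @param outcomes optional pre-computed list of the four [run_cohort()]
#'   results (reused, e.g., when sweeping prevalence).
#' @return an object of class `cea_result`: `prevalence`, `probs`, `outcomes`,
#'   `do_nothing` and `biomarker` strategy results, and `incremental`.
#' @examples
#' \donttest{
#' res <- run_cea(default_parameters())
#' res$incremental
#' }
#' @export
run_cea <- function(ps, flags = scenario_flags(), prevalence = NULL,
                    outcomes = NULL) {
  v <- model_inputs(ps)
  p <- prevalence %||% pretest_prevalence(v)
  probs <- outcome_probabilities(p, v$accuracy$bm_sn, v$accuracy$bm_sp)
  if (is.null(outcomes)) {
    outcomes <- lapply(setNames(nm = c("TP", "FN", "FP", "TN")),
                       run_cohort, ps = v, flags = flags)
  }
  s0 <- strategy_do_nothing(p, outcomes)
  s1 <- aggregate_strategy(probs, outcomes,
                           test_cost = v$costs$test_cost,
                           test_toll = v$utilities$lp_toll,
                           tested = TRUE, label = "biomarker")
  structure(list(
    prevalence = p, probs = probs, outcomes = outcomes,
    do_nothing = s0, biomarker = s1,
    incremental = compare_strategies(s1, s0),
    inputs = v, flags = flags
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Cost-effectiveness at pretest prevalence %.1f%%\n",
              100 * x$prevalence))
  for (s in list(x$do_nothing, x$biomarker)) {
    cat(sprintf("  %-11s cost $%s, QALYs %.3f\n", s$label,
                format(round(s$cost), big.mark = ","), s$qalys))
  }
  print(x$incremental)
  invisible(x)
}

#' Specification for comparing hypothetical test characteristics
#'
#' Bundles everything the incremental-net-monetary-benefit comparison of two
#' tests needs: the prevalence, the willingness-to-pay threshold, the
#' comparator's sensitivity/specificity, the per-outcome lifetime values, and
#' the differences in test cost and short-term test QALYs. The default
#' comparator is "no test" (`q1 = 0`, `q2 = 1`: nobody is diagnosed).
#'
#' @param outcomes named list of the four [run_cohort()] results.
#' @param prevalence pretest prevalence of disease.
#' @param lambda willingness-to-pay (US$/QALY).
#' @param q1,q2 comparator sensitivity and specificity.
#' @param delta_test_cost,delta_test_qaly differences (new minus comparator)
#'   in test cost and in the short-term quality-of-life effect of testing.
#' @return an object of class `challenge_spec`.
#' @export
challenge_region_spec <- function(outcomes, prevalence, lambda,
                                  q1 = 0, q2 = 1,
                                  delta_test_cost = 0, delta_test_qaly = 0) {
  check_fraction(prevalence, "prevalence")
  check_fraction(q1, "q1"); check_fraction(q2, "q2")
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  g <- function(o, f) outcomes[[o]][[f]]
  structure(list(
    prevalence = prevalence, lambda = lambda, q1 = q1, q2 = q2,
    qaly_tp = g("TP", "qalys"), qaly_fn = g("FN", "qalys"),
    qaly_fp = g("FP", "qalys"), qaly_tn = g("TN", "qalys"),
    cost_tp = g("TP", "cost"), cost_fn = g("FN", "cost"),
    cost_fp = g("FP", "cost"), cost_tn = g("TN", "cost"),
    delta_test_cost = delta_test_cost, delta_test_qaly = delta_test_qaly
  ), class = "challenge_spec")
}

#' Incremental net monetary benefit of a new test over a comparator
#'
#' Three-term decomposition of the INMB of replacing a test with sensitivity
#' `q1` and specificity `q2` by one with `r1`, `r2`: the value of prevented
#' false negatives, the value of prevented false positives, and the change in
#' test cost and short-term test QALYs:
#' \deqn{p(r_1-q_1)[\lambda(Q_{TP}-Q_{FN}) - (C_{TP}-C_{FN})] +
#'       (1-p)(r_2-q_2)[\lambda(Q_{TN}-Q_{FP}) - (C_{TN}-C_{FP})] -
#'       \Delta C_{test} - \lambda \Delta Q_{test}}
#'
#' @param spec a [challenge_region_spec()].
#' @param r1,r2 sensitivity and specificity of the new test (vectorized).
#' @return INMB in US$.
#' @export
inmb_test_comparison <- function(spec, r1, r2) {
  stopifnot(inherits(spec, "challenge_spec"))
  if (any(r1 < 0 | r1 > 1 | r2 < 0 | r2 > 1)) {
    stop("r1 and r2 must lie in [0, 1]", call. = FALSE)
  }
  p <- spec$prevalence; l <- spec$lambda
  val_fn <- l * (spec$qaly_tp - spec$qaly_fn) - (spec$cost_tp - spec$cost_fn)
  val_fp <- l * (spec$qaly_tn - spec$qaly_fp) - (spec$cost_tn - spec$cost_fp)
  p * (r1 - spec$q1) * val_fn + (1 - p) * (r2 - spec$q2) * val_fp -
    spec$delta_test_cost - l * spec$delta_test_qaly
}

#' Challenge region of admissible test characteristics
#'
#' Evaluates [inmb_test_comparison()] over a sensitivity-specificity grid and
#' returns the set of `(r1, r2)` pairs with positive INMB against the
#' comparator, together with the analytic INMB = 0 boundary (linear in `r1`
#' and `r2`): `a1 * r1 + a2 * r2 + a0 = 0`.
#'
#' @param spec a [challenge_region_spec()].
#' @param grid_step grid spacing in `(0, 0.1]`.
#' @return an object of class `challenge_region`: `grid` (data.frame with
#'   `r1`, `r2`, `inmb`, `admissible`), `boundary` (coefficients `a0`, `a1`,
#'   `a2`), and `boundary_r2(r1)`, the boundary specificity as a function of
#'   sensitivity.
#' @export
challenge_region <- function(spec, grid_step = 0.01) {
  stopifnot(inherits(spec, "challenge_spec"))
  if (grid_step <= 0 || grid_step > 0.1) {
    stop("grid_step must be in (0, 0.1]", call. = FALSE)
  }
  p <- spec$prevalence; l <- spec$lambda
  a1 <- p * (l * (spec$qaly_tp - spec$qaly_fn) - (spec$cost_tp - spec$cost_fn))
  a2 <- (1 - p) * (l * (spec$qaly_tn - spec$qaly_fp) - (spec$cost_tn - spec$cost_fp))
  a0 <- -a1 * spec$q1 - a2 * spec$q2 - spec$delta_test_cost -
    l * spec$delta_test_qaly
  s <- seq(0, 1, by = grid_step)
  grid <- expand.grid(r1 = s, r2 = s, KEEP.OUT.ATTRS = FALSE)
  grid$inmb <- a0 + a1 * grid$r1 + a2 * grid$r2
  grid$admissible <- grid$inmb > 0
  structure(list(
    grid = grid,
    boundary = c(a0 = a0, a1 = a1, a2 = a2),
    boundary_r2 = function(r1) (-a0 - a1 * r1) / a2,
    spec = spec
  ), class = "challenge_region")
}

#' @export
print.challenge_region <- function(x, ...) {
  cat(sprintf(
    "<challenge_region> p %.3f, lambda $%s: %.1f%% of the grid admissible\n",
    x$spec$prevalence, format(x$spec$lambda, big.mark = ","),
    100 * mean(x$grid$admissible)))
  invisible(x)
}
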