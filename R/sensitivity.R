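# Deterministic one-way and two-way sensitivity analysis, prevalence-threshold
# search, structural scenarios, and the probabilistic sensitivity analysis
# (PSA) with cost-effectiveness acceptability curves.

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full analysis with each selected parameter at its published low
#' and high value (all else at base case) and records the incremental result.
#' Rows are ordered by the width of the ICER range (tornado order); dominance
#' is reported as a classification rather than forced into an ICER number.
#'
#' @param ps parameter set.
#' @param param_ids dotted parameter ids to vary (default: every parameter
#'   with a published range).
#' @param flags structural [scenario_flags()].
#' @return a data.frame with one row per parameter: low/high input values, the
#'   incremental cost, QALYs and ICER (or classification) at each, and the
#'   base-case ICER.
#' @export
one_way_dsa <- function(ps, param_ids = NULL, flags = scenario_flags()) {
  stopifnot(inherits(ps, "cea_parameters"))
  tab <- param_table(ps)
  if (is.null(param_ids)) {
    param_ids <- tab$id[tab$has_range]
  } else {
    unknown <- setdiff(param_ids, tab$id)
    if (length(unknown)) stop("unknown parameter id(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
  }
  base_inc <- run_cea(ps, flags)$incremental
  rows <- lapply(param_ids, function(id) {
    p <- get_param(ps, id)
    at <- function(value) run_cea(set_param(ps, id, value), flags)$incremental
    lo <- at(p$low); hi <- at(p$high)
    data.frame(id = id, low = p$low, high = p$high,
               icer_low = lo$icer, class_low = lo$classification,
               icer_high = hi$icer, class_high = hi$classification,
               delta_cost_low = lo$delta_cost, delta_cost_high = hi$delta_cost,
               icer_base = base_inc$icer, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  span <- function(lo, hi, b) {
    v <- c(lo, hi); v[is.na(v)] <- b  # dominance: treat as at-base for ordering
    abs(diff(range(c(v, b))))
  }
  out[order(-mapply(span, out$icer_low, out$icer_high, out$icer_base)), ,
      drop = FALSE]
}

classify_incremental <- function(inc, lambda_low = 50000, lambda_high = 1e5) {
  dc <- inc$delta_cost; dq <- inc$delta_qalys
  if (inc$classification == "dominant") return("cost_saving")
  if (inc$classification %in% c("dominated", "equivalent")) {
    return(if (inc$classification == "dominated") "dominated" else "icer_le_50k")
  }
  if (dc < 0 && dq < 0) {
    # cheaper and worse: judge by net benefit at the lower threshold
    return(if (lambda_low * dq - dc > 0) "cost_saving" else "dominated")
  }
  if (inc$icer <= lambda_low) "icer_le_50k"
  else if (inc$icer <= lambda_high) "icer_50_100k"
  else "icer_gt_100k"
}

#' Two-way deterministic sensitivity analysis
#'
#' Evaluates the incremental comparison over a grid of two inputs and
#' classifies each cell (`cost_saving`, `icer_le_50k`, `icer_50_100k`,
#' `icer_gt_100k`, `dominated`). An axis is a list with `id` (a dotted
#' parameter id or the special `"pretest_prevalence"`) and `values`.
#'
#' @param ps parameter set.
#' @param axis1,axis2 axis definitions, e.g.
#'   `list(id = "cohort.start_age", values = c(55, 65, 75))`.
#' @param flags structural [scenario_flags()].
#' @return a data.frame with columns `x`, `y`, `delta_cost`, `delta_qalys`,
#'   `icer`, `class`.
#' @export
two_way_dsa <- function(ps, axis1, axis2, flags = scenario_flags()) {
  stopifnot(inherits(ps, "cea_parameters"),
            is.list(axis1), is.list(axis2),
            !is.null(axis1$id), !is.null(axis2$id))
  cells <- expand.grid(x = axis1$values, y = axis2$values,
                       KEEP.OUT.ATTRS = FALSE)
  apply_axis <- function(ps, id, value) {
    if (identical(id, "pretest_prevalence")) list(ps = ps, prevalence = value)
    else list(ps = set_param(ps, id, value), prevalence = NULL)
  }
  res <- lapply(seq_len(nrow(cells)), function(i) {
    a <- apply_axis(ps, axis1$id, cells$x[i])
    b <- apply_axis(a$ps, axis2$id, cells$y[i])
    prev <- b$prevalence %||% a$prevalence
    inc <- run_cea(b$ps, flags, prevalence = prev)$incremental
    data.frame(x = cells$x[i], y = cells$y[i],
               delta_cost = inc$delta_cost, delta_qalys = inc$delta_qalys,
               icer = inc$icer, class = classify_incremental(inc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# incremental comparison at an arbitrary prevalence, reusing the four
# lifetime outcomes (which do not depend on prevalence)
incremental_at_prevalence <- function(p, v, outcomes) {
  probs <- outcome_probabilities(p, v$accuracy$bm_sn, v$accuracy$bm_sp)
  s0 <- strategy_do_nothing(p, outcomes)
  s1 <- aggregate_strategy(probs, outcomes, test_cost = v$costs$test_cost,
                           test_toll = v$utilities$lp_toll, tested = TRUE,
                           label = "biomarker")
  compare_strategies(s1, s0)
}

#' Prevalence at which the ICER equals a willingness-to-pay threshold
#'
#' The ICER of biomarker testing versus doing nothing is strictly decreasing
#' in the pretest prevalence (verified on a grid before searching); this finds
#' the prevalence at which it crosses `lambda` by bisection of the incremental
#' net monetary benefit, which has the same root.
#'
#' @param lambda willingness-to-pay (US$/QALY), `> 0`.
#' @param ps parameter set.
#' @param flags structural [scenario_flags()].
#' @param bracket prevalence search interval.
#' @param tol absolute tolerance on the prevalence.
#' @return the threshold prevalence. If the INMB does not change sign inside
#'   the bracket, returns the nearer bracket end with attribute
#'   `boundary = TRUE` and a warning describing the boundary behaviour.
#' @export
prevalence_threshold <- function(lambda, ps, flags = scenario_flags(),
                                 bracket = c(0.005, 0.6), tol = 1e-4) {
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  v <- model_inputs(ps)
  outcomes <- lapply(setNames(nm = c("TP", "FN", "FP", "TN")),
                     run_cohort, ps = v, flags = flags)
  grid <- seq(max(bracket[1], 0.02), min(bracket[2], 0.5), length.out = 9)
  icers <- vapply(grid, function(p) {
    inc <- incremental_at_prevalence(p, v, outcomes)
    if (is.na(inc$icer)) -Inf else inc$icer  # dominant: below any threshold
  }, numeric(1))
  if (any(diff(icers[is.finite(icers)]) >= 0)) {
    warning("ICER is not strictly decreasing in prevalence over the bracket")
  }
  h <- function(p) {
    inc <- incremental_at_prevalence(p, v, outcomes)
    lambda * inc$delta_qalys - inc$delta_cost
  }
  h_lo <- h(bracket[1]); h_hi <- h(bracket[2])
  if (h_lo * h_hi > 0) {
    boundary <- if (h_lo > 0) bracket[1] else bracket[2]
    warning(sprintf(
      "INMB at lambda = %g does not change sign in [%g, %g]; %s everywhere",
      lambda, bracket[1], bracket[2],
      if (h_lo > 0) "cost-effective" else "not cost-effective"))
    return(structure(boundary, boundary = TRUE))
  }
  uniroot(h, bracket, tol = tol)$root
}

#' Prevalence above which biomarker testing is cost-saving
#'
#' Root of the incremental cost in the pretest prevalence: above this
#' prevalence the biomarker strategy both saves money and gains QALYs
#' (dominant) in the deterministic analysis.
#'
#' @inheritParams prevalence_threshold
#' @return the prevalence at which the incremental cost is zero.
#' @export
cost_saving_threshold <- function(ps, flags = scenario_flags(),
                                  bracket = c(0.005, 0.6), tol = 1e-4) {
  v <- model_inputs(ps)
  outcomes <- lapply(setNames(nm = c("TP", "FN", "FP", "TN")),
                     run_cohort, ps = v, flags = flags)
  g <- function(p) incremental_at_prevalence(p, v, outcomes)$delta_cost
  uniroot(g, bracket, tol = tol)$root
}

#' Run a structural scenario
#'
#' Full pipeline under a structural variant of the model.
#'
#' @param flags [scenario_flags()].
#' @param ps parameter set.
#' @return the `incremental_result` of biomarker testing vs doing nothing.
#' @export
run_scenario <- function(flags, ps) {
  run_cea(ps, flags)$incremental
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets from the published uncertainty distributions (see
#' [psa_distributions()]), re-runs the deterministic pipeline for each draw
#' (the pretest prevalence is re-derived from each draw's diagnostic-accuracy
#' values), and accumulates the cost-effectiveness plane, the quadrant shares,
#' the cost-effectiveness acceptability curve (CEAC) at each willingness-to-pay
#' threshold, and empirical 95% intervals. Fully reproducible from `seed`.
#'
#' @param ps parameter set.
#' @param n number of draws.
#' @param seed integer seed.
#' @param lambdas willingness-to-pay thresholds for the CEAC.
#' @param flags structural [scenario_flags()].
#' @param prevalence optional fixed pretest prevalence (default: re-derived
#'   per draw).
#' @return an object of class `psa_result`: `draws` (data.frame with
#'   per-draw strategy costs/QALYs and increments), `quadrants`, `ceac`,
#'   `intervals`, `n`, `seed`, `n_redraws`.
#' @export
run_psa <- function(ps, n = NULL, seed = 1L,
                    lambdas = NULL, flags = scenario_flags(),
                    prevalence = NULL) {
  stopifnot(inherits(ps, "cea_parameters"))
  n <- n %||% ps$settings$psa_draws
  lambdas <- lambdas %||% ps$settings$wtp
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  dists <- psa_distributions(ps)
  set.seed(seed)
  cols <- c("cost_dn", "qaly_dn", "cost_bm", "qaly_bm",
            "delta_cost", "delta_qalys", "prevalence")
  draws <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  redraws <- 0L
  for (k in seq_len(n)) {
    sm <- sample_parameter_set(ps, dists = dists)
    redraws <- redraws + attr(sm, "n_redraws")
    res <- run_cea(sm, flags, prevalence = prevalence)
    draws[k, ] <- c(res$do_nothing$cost, res$do_nothing$qalys,
                    res$biomarker$cost, res$biomarker$qalys,
                    res$incremental$delta_cost, res$incremental$delta_qalys,
                    res$prevalence)
  }
  draws <- as.data.frame(draws)
  dc <- draws$delta_cost; dq <- draws$delta_qalys
  quadrants <- c(cheaper_better = mean(dc < 0 & dq > 0),
                 costlier_better = mean(dc >= 0 & dq > 0),
                 cheaper_worse = mean(dc < 0 & dq <= 0),
                 costlier_worse = mean(dc >= 0 & dq <= 0))
  ceac <- data.frame(
    lambda = lambdas,
    p_cost_effective = vapply(lambdas, function(l) mean(l * dq - dc > 0),
                              numeric(1)))
  qs <- function(x) quantile(x, c(0.025, 0.975), names = FALSE)
  intervals <- rbind(cost_dn = qs(draws$cost_dn), qaly_dn = qs(draws$qaly_dn),
                     cost_bm = qs(draws$cost_bm), qaly_bm = qs(draws$qaly_bm),
                     delta_cost = qs(dc), delta_qalys = qs(dq))
  colnames(intervals) <- c("lo2.5", "hi97.5")
  structure(list(draws = draws, quadrants = quadrants, ceac = ceac,
                 intervals = intervals, n = n, seed = seed,
                 n_redraws = redraws),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (seed %d, %d constrained redraws)\n",
              x$n, x$seed, x$n_redraws))
  q <- x$quadrants
  cat(sprintf("  cheaper & better %.1f%%, costlier & worse %.1f%%\n",
              100 * q[["cheaper_better"]], 100 * q[["costlier_worse"]]))
  for (i in seq_len(nrow(x$ceac))) {
    cat(sprintf("  CEAC($%s) = %.1f%%\n",
                format(x$ceac$lambda[i], big.mark = ","),
                100 * x$ceac$p_cost_effective[i]))
  }
  invisible(x)
}
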