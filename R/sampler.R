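# Synthetic-input machinery: uncertainty distributions for the PSA, parameter
# draws with the invariants enforced, and an individual-level microsimulation
# that serves as a brute-force oracle for the cohort engine.
#
# Distribution families follow standard health-economics practice:
# probabilities and utilities are beta, costs and rates gamma, hazard ratios
# lognormal, and bounded structural quantities (start age) uniform. The
# published (low, high) range is interpreted as an approximate 95% interval,
# not as hard bounds.

#' Uncertainty distribution for one parameter
#'
#' Fits the family implied by the parameter's kind so that the distribution
#' mean equals the base-case value and the 2.5/97.5 percentile spread matches
#' the published (low, high) range: beta and gamma match the mean exactly and
#' the interval width by a one-dimensional search; lognormal takes its sdlog
#' from the range ratio and shifts meanlog to preserve the mean. A degenerate
#' range yields a point mass.
#'
#' @param pv a [param_value()].
#' @return an object of class `distribution_spec`: `family`, `pars`, and the
#'   originating values.
#' @export
distribution_for <- function(pv) {
  stopifnot(is_param_value(pv))
  out <- list(base = pv$base, low = pv$low, high = pv$high, kind = pv$kind)
  if (pv$low >= pv$high) {
    out$family <- "point"
    out$pars <- c(value = pv$base)
    class(out) <- "distribution_spec"
    return(out)
  }
  width <- pv$high - pv$low
  if (pv$kind %in% c("probability", "utility")) {
    mu <- pv$base
    if (mu <= 0 || mu >= 1) {
      # ranges around a boundary base value (e.g. a zero base): fall back to
      # a uniform draw over the published range
      out$family <- "uniform"
      out$pars <- c(min = pv$low, max = pv$high)
    } else {
      f <- function(logk) {
        k <- exp(logk)
        diff(qbeta(c(0.025, 0.975), mu * k, (1 - mu) * k)) - width
      }
      k <- exp(uniroot(f, c(log(2), log(1e9)), extendInt = "yes")$root)
      out$family <- "beta"
      out$pars <- c(shape1 = mu * k, shape2 = (1 - mu) * k)
    }
  } else if (pv$kind %in% c("cost", "rate")) {
    mu <- pv$base
    if (mu <= 0) {
      out$family <- "uniform"
      out$pars <- c(min = pv$low, max = pv$high)
    } else {
      f <- function(logk) {
        k <- exp(logk)
        diff(qgamma(c(0.025, 0.975), shape = k, rate = k / mu)) - width
      }
      k <- exp(uniroot(f, c(log(0.5), log(1e9)), extendInt = "yes")$root)
      out$family <- "gamma"
      out$pars <- c(shape = k, rate = k / mu)
    }
  } else if (pv$kind == "hazard_ratio") {
    sdlog <- (log(pv$high) - log(pv$low)) / (2 * qnorm(0.975))
    out$family <- "lognormal"
    out$pars <- c(meanlog = log(pv$base) - sdlog^2 / 2, sdlog = sdlog)
  } else {
    out$family <- "uniform"
    out$pars <- c(min = pv$low, max = pv$high)
  }
  class(out) <- "distribution_spec"
  out
}

draw_spec <- function(spec, n = 1L) {
  p <- spec$pars
  switch(spec$family,
         point = rep(p[["value"]], n),
         beta = rbeta(n, p[["shape1"]], p[["shape2"]]),
         gamma = rgamma(n, shape = p[["shape"]], rate = p[["rate"]]),
         lognormal = rlnorm(n, p[["meanlog"]], p[["sdlog"]]),
         uniform = runif(n, p[["min"]], p[["max"]]),
         stop("unknown family: ", spec$family, call. = FALSE))
}

#' PSA distributions for every uncertain parameter
#'
#' Builds the [distribution_for()] specification for every parameter with a
#' published range, in the stable [param_table()] order. The combined-criterion
#' test accuracy is excluded: its uncertainty enters through the conditional
#' biomarker accuracy, which carries its own published range.
#'
#' @param ps parameter set.
#' @return named list of `distribution_spec` objects, keyed by parameter id.
#' @export
psa_distributions <- function(ps) {
  tab <- param_table(ps)
  ids <- setdiff(tab$id[tab$has_range], PSA_EXCLUDE)
  setNames(lapply(ids, function(id) distribution_for(get_param(ps, id))), ids)
}

#' Draw one parameter set for the PSA
#'
#' Independent draws for every parameter with a range, in stable order, from
#' the caller's random stream. Draws that violate a hard model invariant are
#' redrawn (ordering of the mortality hazard ratios; treatment-benefit
#' direction of the donepezil HRs; an MRI specificity incompatible with the
#' observed proportion diagnosed); the initial severity mix is renormalized to
#' sum to 1. Linked non-AD parameters follow their drawn mild-AD counterparts.
#'
#' @param ps parameter set (provides base values, ranges, and links).
#' @param dists optional pre-built [psa_distributions()] (rebuilt otherwise).
#' @param max_tries redraw limit per constraint group.
#' @return a realized `cea_inputs` object; attribute `n_redraws` counts
#'   constraint-violating draws that were rejected.
#' @export
sample_parameter_set <- function(ps, dists = NULL, max_tries = 1000L) {
  stopifnot(inherits(ps, "cea_parameters"))
  dists <- dists %||% psa_distributions(ps)
  redraws <- 0L
  take <- function(id) {
    if (id %in% names(dists)) draw_spec(dists[[id]]) else get_param(ps, id)$base
  }
  draw_until <- function(ids, ok) {
    for (i in seq_len(max_tries)) {
      vals <- vapply(ids, take, numeric(1))
      if (ok(vals)) return(vals)
      redraws <<- redraws + 1L
    }
    stop("could not satisfy constraints for: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  drawn <- setNames(numeric(0), character(0))
  put <- function(vals) drawn[names(vals)] <<- vals

  # stable parameter order with constraint groups drawn jointly
  put(vapply(c("cohort.start_age", "cohort.severity_mild",
               "cohort.severity_moderate", "cohort.severity_severe"),
             take, numeric(1)))
  put(draw_until(c("accuracy.mr_sn", "accuracy.mr_sp"), function(x) {
    x[1] + x[2] > 1 && (1 - x[2]) < ps$cohort$proportion_diagnosed$base &&
      x[1] > ps$cohort$proportion_diagnosed$base
  }))
  put(draw_until(c("accuracy.bm_sn", "accuracy.bm_sp"),
                 function(x) x[1] + x[2] > 1))
  put(draw_until(c("mortality.hr_mild", "mortality.hr_moderate",
                   "mortality.hr_severe"),
                 function(x) x[3] > x[2] && x[2] > x[1] && x[1] > 1))
  rate_ids <- grep("^rates\\.", names(dists), value = TRUE)
  put(vapply(rate_ids, take, numeric(1)))
  put(draw_until("treatment.hr_mild_to_moderate", function(x) x < 1))
  put(draw_until("treatment.hr_moderate_to_mild", function(x) x > 1))
  put(draw_until(c("costs.inc_community_mild", "costs.inc_community_moderate",
                   "costs.inc_community_severe"),
                 function(x) x[3] > x[2] && x[2] > x[1]))
  put(draw_until(c("utilities.community_mild", "utilities.community_moderate",
                   "utilities.community_severe"),
                 function(x) x[1] > x[2] && x[2] > x[3]))
  rest <- setdiff(names(dists), names(drawn))
  put(vapply(rest, take, numeric(1)))

  # renormalize the initial severity mix
  mix_ids <- paste0("cohort.severity_", c("mild", "moderate", "severe"))
  drawn[mix_ids] <- drawn[mix_ids] / sum(drawn[mix_ids])

  out <- ps
  for (id in names(drawn)) out <- set_param(out, id, drawn[[id]])
  v <- model_inputs(out)
  attr(v, "n_redraws") <- redraws
  v
}

#' Individual-level microsimulation of one diagnostic-outcome group
#'
#' Simulates `n` individuals month by month through the same event rules as
#' the cohort engine — death first; conditional on survival one severity
#' event, one location event, and one treatment event per cycle, with the
#' memantine-uptake coupling on entry into severe disease — but by sampling
#' each individual's path rather than propagating expected occupancy. The
#' event probabilities are recomputed here directly from the hazards, so the
#' function is an independent brute-force oracle for [run_cohort()]: its mean
#' discounted cost, QALYs and life-years converge to the cohort values as `n`
#' grows, with Monte-Carlo standard errors reported.
#'
#' @param group `"TP"`, `"FN"`, `"FP"`, or `"TN"`.
#' @param ps parameter set.
#' @param n number of simulated individuals.
#' @param seed integer seed.
#' @param flags structural [scenario_flags()].
#' @return an object of class `microsim_outcome`: means and standard errors
#'   of discounted cost, discounted QALYs, (undiscounted) life-years, and
#'   discounted life-years.
#' @export
microsimulate_cohort <- function(group = c("TP", "FN", "FP", "TN"), ps,
                                 n = 10000L, seed = 1L,
                                 flags = scenario_flags()) {
  group <- match.arg(group)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  v <- model_inputs(ps)
  set.seed(seed)
  st <- v$settings
  cyc <- st$cycle_months
  cyc_frac <- cyc / 12
  n_cycles <- max(1L, ceiling((st$max_age - v$cohort$start_age) * 12 / cyc))
  tr <- v$treatment
  f_fp <- flags$fp_benefit_fraction %||% tr$fp_benefit_fraction
  ad_like <- group %in% c("TP", "FN") ||
    flags$nonad_history == "progressive_like_AD"
  treated <- switch(group, TP = TRUE, FP = TRUE,
                    FN = flags$fn_correction_on_progression, TN = FALSE)
  benefit <- switch(group, TP = 1, FN = 1, FP = f_fp, TN = 0)
  cp <- function(rate) annual_hazard_to_cycle_prob(rate, cyc)

  # state arrays; sev = 0 codes stable non-AD
  if (ad_like) {
    if (group %in% c("TP", "FN")) {
      mix <- c(v$cohort$severity_mild, v$cohort$severity_moderate,
               v$cohort$severity_severe)
      sev <- sample.int(3L, n, replace = TRUE, prob = mix)
      up <- if (group == "TP") {
        ifelse(sev == 3L, tr$uptake_memantine, tr$uptake_donepezil)
      } else 0
    } else {
      sev <- rep(1L, n)
      up <- if (group == "FP") tr$uptake_donepezil else 0
    }
    tx <- as.integer(runif(n) < up)
  } else {
    sev <- rep(0L, n)
    tx <- as.integer(runif(n) < if (group == "FP") tr$uptake_donepezil else 0)
  }
  loc <- rep(1L, n)
  alive <- rep(TRUE, n)

  sevlab <- if (flags$nonad_history == "stable_moderate") "moderate" else "nonad"
  hr_mort <- function(s) {
    out <- numeric(length(s))
    out[s == 0L] <- if (sevlab == "moderate") v$mortality$hr_moderate else
      v$mortality$hr_nonad
    out[s == 1L] <- v$mortality$hr_mild
    out[s == 2L] <- v$mortality$hr_moderate
    out[s == 3L] <- v$mortality$hr_severe
    out
  }
  eff <- list(
    m2mod = scale_hr(tr$hr_mild_to_moderate, benefit),
    mod2m = scale_hr(tr$hr_moderate_to_mild, benefit),
    mod2sev = scale_hr(if (flags$donepezil_affects_moderate_to_severe)
      tr$hr_mild_to_moderate else 1, benefit),
    ltcf_don = scale_hr(tr$hr_ltcf, benefit),
    ltcf_mem = scale_hr(tr$hr_ltcf_memantine, benefit)
  )
  # annual state costs and utility weights, indexed by sev 0..3 and location
  inc_comm <- c(v$costs[[paste0("inc_community_", sevlab)]],
                v$costs$inc_community_mild, v$costs$inc_community_moderate,
                v$costs$inc_community_severe)
  inc_ltcf <- c(v$costs[[paste0("inc_ltcf_", sevlab)]],
                v$costs$inc_ltcf_mild, v$costs$inc_ltcf_moderate,
                v$costs$inc_ltcf_severe) + v$costs$facility
  u_comm <- c(v$utilities[[paste0("community_", sevlab)]],
              v$utilities$community_mild, v$utilities$community_moderate,
              v$utilities$community_severe)
  u_ltcf <- c(v$utilities[[paste0("ltcf_", sevlab)]],
              v$utilities$ltcf_mild, v$utilities$ltcf_moderate,
              v$utilities$ltcf_severe)
  drug_cost <- function(s) ifelse(s == 3L, v$costs$memantine, v$costs$donepezil)
  ltcf_rate_of <- function(s) {
    out <- numeric(length(s))
    out[s == 0L] <- if (sevlab == "moderate") v$rates$ltcf_moderate else
      v$rates$ltcf_nonad
    out[s == 1L] <- v$rates$ltcf_mild
    out[s == 2L] <- v$rates$ltcf_moderate
    out[s == 3L] <- v$rates$ltcf_severe
    out
  }

  cost <- qaly <- ly <- dly <- numeric(n)
  for (m in seq_len(n_cycles)) {
    idx <- which(alive)
    if (!length(idx)) break
    age <- v$cohort$start_age + (m - 1L) * cyc_frac
    dsc <- (1 + st$discount_rate)^(-(m - 1L) * cyc_frac)
    mort <- v$mortality$coeff_a * exp(v$mortality$coeff_b * age)
    s <- sev[idx]; l <- loc[idx]; t <- tx[idx]

    # accrual in the start-of-cycle state
    base_c <- if (isTRUE(st$accrue_baseline)) {
      bc <- v$costs$baseline_a * exp(v$costs$baseline_b * age)
      if (age >= 90) min(bc, v$costs$baseline_cap) else bc
    } else 0
    c_m <- base_c + ifelse(l == 1L, inc_comm[s + 1L], inc_ltcf[s + 1L]) +
      t * drug_cost(s)
    aw <- age_weight_vec(age, v)
    q_m <- aw * ifelse(l == 1L, u_comm[s + 1L], u_ltcf[s + 1L]) +
      t * (s == 3L) * tr$memantine_utility * benefit
    cost[idx] <- cost[idx] + c_m * cyc_frac * dsc
    qaly[idx] <- qaly[idx] + q_m * cyc_frac * dsc
    ly[idx] <- ly[idx] + cyc_frac
    dly[idx] <- dly[idx] + cyc_frac * dsc

    # death
    pd <- cp(mort * hr_mort(s))
    dies <- runif(length(idx)) < pd
    if (any(dies)) {
      if (isTRUE(st$accrue_death_cost)) {
        dc <- if (age < 90) v$costs$death_under90 else v$costs$death_over90
        cost[idx[dies]] <- cost[idx[dies]] + dc * dsc
      }
      alive[idx[dies]] <- FALSE
      idx <- idx[!dies]
      if (!length(idx)) next
      s <- sev[idx]; l <- loc[idx]; t <- tx[idx]
    }

    # severity event (AD-like groups), competing-hazard allocation
    new_s <- s
    if (ad_like) {
      h1 <- h2 <- h3 <- numeric(length(idx))
      m1 <- s == 1L; m2 <- s == 2L; m3 <- s == 3L
      h2[m1] <- v$rates$mild_to_moderate * ifelse(t[m1] == 1L, eff$m2mod, 1)
      h3[m1] <- v$rates$mild_to_severe
      h1[m2] <- v$rates$moderate_to_mild * ifelse(t[m2] == 1L, eff$mod2m, 1)
      h3[m2] <- v$rates$moderate_to_severe * ifelse(t[m2] == 1L, eff$mod2sev, 1)
      h1[m3] <- v$rates$severe_to_mild
      h2[m3] <- v$rates$severe_to_moderate
      H <- h1 + h2 + h3
      p_any <- cp(H)
      u <- runif(length(idx)) * ifelse(H > 0, 1, Inf)
      # thresholds within the moved mass, ordered mild < moderate < severe
      q1 <- p_any * h1 / pmax(H, 1); q2 <- q1 + p_any * h2 / pmax(H, 1)
      q3 <- q2 + p_any * h3 / pmax(H, 1)
      new_s[u < q1] <- 1L
      new_s[u >= q1 & u < q2] <- 2L
      new_s[u >= q2 & u < q3] <- 3L
    }

    # location event (from the start-of-cycle severity and treatment)
    new_l <- l
    in_comm <- l == 1L
    if (any(in_comm)) {
      lr <- ltcf_rate_of(s[in_comm]) *
        ifelse(t[in_comm] == 1L,
               ifelse(s[in_comm] == 3L, eff$ltcf_mem, eff$ltcf_don), 1)
      mv <- runif(sum(in_comm)) < cp(lr)
      new_l[in_comm][mv] <- 2L
    }

    # treatment event; entering severe disease re-draws uptake, and
    # re-diagnosed false negatives start treatment on reaching moderate
    new_t <- t
    if (treated || any(t == 1L)) {
      on <- t == 1L
      if (any(on)) {
        dr <- ifelse(s[on] == 3L, tr$disc_memantine,
                     ifelse(l[on] == 1L, tr$disc_donepezil_community,
                            tr$disc_donepezil_ltcf))
        stop_tx <- runif(sum(on)) < cp(dr)
        new_t[on][stop_tx] <- 0L
      }
      off <- !on
      if (any(off) && treated) {
        rr <- ifelse(s[off] == 3L, tr$reinit_memantine, tr$reinit_donepezil)
        if (group == "FN") rr[s[off] == 1L] <- 0
        start_tx <- runif(sum(off)) < cp(rr)
        new_t[off][start_tx] <- 1L
      }
    }
    entering_sev <- ad_like & new_s == 3L & s != 3L
    if (any(entering_sev)) {
      memup <- if (treated) tr$uptake_memantine else 0
      new_t[entering_sev] <- as.integer(runif(sum(entering_sev)) < memup)
    }
    if (group == "FN" && treated) {
      corr <- new_s == 2L & s == 1L & t == 0L
      if (any(corr)) {
        new_t[corr] <- as.integer(runif(sum(corr)) < tr$uptake_donepezil)
      }
    }

    sev[idx] <- new_s; loc[idx] <- new_l; tx[idx] <- new_t
  }

  se <- function(x) sd(x) / sqrt(n)
  structure(list(
    group = group, n = n, seed = seed,
    cost = mean(cost), cost_se = se(cost),
    qalys = mean(qaly), qalys_se = se(qaly),
    life_years = mean(ly), life_years_se = se(ly),
    disc_life_years = mean(dly), disc_life_years_se = se(dly)
  ), class = "microsim_outcome")
}

#' @export
print.microsim_outcome <- function(x, ...) {
  cat(sprintf(
    "<microsim_outcome> %s, n = %d: cost $%s (se %.0f), QALYs %.3f (se %.4f), LYs %.3f\n",
    x$group, x$n, format(round(x$cost), big.mark = ","), x$cost_se,
    x$qalys, x$qalys_se, x$life_years))
  invisible(x)
}
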