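# Monthly-cycle Markov cohort engine.
#
# AD patients occupy 12 live states (severity {mild, moderate, severe} x
# location {community, LTCF} x treatment {off, on}) plus death; non-AD
# patients occupy 4 live states (location x treatment) plus death. Within a
# cycle, death is applied first; conditional on survival, severity change,
# location change, and treatment-status change are composed as independent
# single events per category, each converted from its annual hazard. The
# conditional (survival) transition matrix is age-invariant, so each cycle is
# one vector-matrix product plus an age-specific death step.

#' Convert an annual hazard to a per-cycle transition probability
#'
#' @param rate_per_100k instantaneous annual hazard per 100,000 person-years.
#' @param cycle_months cycle length in months.
#' @return `1 - exp(-(rate/100000) * cycle_months/12)`.
#' @examples
#' annual_hazard_to_cycle_prob(28768, 12)  # 0.25: annual discontinuation
#' annual_hazard_to_cycle_prob(27710, 1)   # ~0.0228: monthly progression
#' @export
annual_hazard_to_cycle_prob <- function(rate_per_100k, cycle_months = 1) {
  if (any(rate_per_100k < 0)) stop("hazard must be >= 0", call. = FALSE)
  1 - exp(-(rate_per_100k / 1e5) * cycle_months / 12)
}

#' Other-cause mortality hazard
#'
#' Exponential (Gompertz-type) fit of the age-specific mortality rate due to
#' causes other than AD, on the per-100,000 person-year scale.
#'
#' @param age age in years (vectorized).
#' @param ps parameter set (for the fitted coefficients).
#' @return annual deaths per 100,000.
#' @export
other_cause_mortality_rate <- function(age, ps = default_parameters()) {
  if (any(age < 0)) stop("age must be >= 0", call. = FALSE)
  v <- model_inputs(ps)
  v$mortality$coeff_a * exp(v$mortality$coeff_b * age)
}

#' Per-cycle probability of death
#'
#' Other-cause mortality multiplied by the severity-specific mortality hazard
#' ratio (non-AD patients use the linked non-AD HR), converted to a per-cycle
#' probability. Treatment status does not affect mortality.
#'
#' @param age age in years.
#' @param severity `"mild"`, `"moderate"`, `"severe"`, or `"nonad"`.
#' @param ps parameter set.
#' @param cycle_months cycle length in months.
#' @return probability of death within one cycle.
#' @export
cycle_death_prob <- function(age, severity = c("mild", "moderate", "severe", "nonad"),
                             ps = default_parameters(), cycle_months = 1) {
  severity <- match.arg(severity)
  v <- model_inputs(ps)
  hr <- switch(severity, mild = v$mortality$hr_mild,
               moderate = v$mortality$hr_moderate,
               severe = v$mortality$hr_severe, nonad = v$mortality$hr_nonad)
  annual_hazard_to_cycle_prob(other_cause_mortality_rate(age, v) * hr, cycle_months)
}

#' Age-specific baseline annual health-care cost
#'
#' Exponential fit to health-care costs unrelated to AD, capped at the average
#' annual cost for patients aged 90 years and older.
#'
#' @param age age in years (vectorized).
#' @param ps parameter set.
#' @return annual cost in US$.
#' @examples
#' baseline_annual_cost(65)  # ~12,337
#' baseline_annual_cost(95)  # capped at 33,870
#' @export
baseline_annual_cost <- function(age, ps = default_parameters()) {
  if (any(age < 0)) stop("age must be >= 0", call. = FALSE)
  v <- model_inputs(ps)
  raw <- v$costs$baseline_a * exp(v$costs$baseline_b * age)
  ifelse(age >= 90, pmin(raw, v$costs$baseline_cap), raw)
}

#' Age-band utility weight
#'
#' Stepwise-constant age-specific utility. Ages at or above 80 use the ">79"
#' weight indefinitely; ages below 60 use the 60-64 weight.
#'
#' @param age age in years (vectorized).
#' @param ps parameter set.
#' @return utility weight in `[0, 1]`.
#' @export
age_band_weight <- function(age, ps = default_parameters()) {
  v <- model_inputs(ps)
  u <- v$utilities
  w <- c(u$age_60_64, u$age_65_69, u$age_70_74, u$age_75_79, u$age_gt79)
  idx <- findInterval(age, c(-Inf, 65, 70, 75, 80))
  w[idx]
}

#' Per-cycle cost of occupying a health state
#'
#' Baseline age-specific cost plus the severity/location incremental cost,
#' the facility cost for LTCF residents, and medication cost while on
#' treatment (donepezil in mild/moderate AD and falsely diagnosed non-AD;
#' memantine in severe AD), divided over the cycles of a year. Death accrues
#' nothing.
#'
#' @param age age in years.
#' @param group `"AD"` or `"nonAD"`.
#' @param severity `"mild"`, `"moderate"`, or `"severe"` (ignored for nonAD).
#' @param location `"community"` or `"ltcf"`.
#' @param on_treatment logical.
#' @param ps parameter set.
#' @return cost in US$ per cycle.
#' @export
cycle_cost <- function(age, group = c("AD", "nonAD"),
                       severity = c("mild", "moderate", "severe"),
                       location = c("community", "ltcf"),
                       on_treatment = FALSE, ps = default_parameters()) {
  group <- match.arg(group); location <- match.arg(location)
  v <- model_inputs(ps)
  key <- if (group == "nonAD") "nonad" else match.arg(severity)
  inc <- if (location == "community") {
    v$costs[[paste0("inc_community_", key)]]
  } else {
    v$costs[[paste0("inc_ltcf_", key)]] + v$costs$facility
  }
  drug <- 0
  if (on_treatment) {
    drug <- if (group == "AD" && key == "severe") v$costs$memantine else v$costs$donepezil
  }
  (baseline_annual_cost(age, v) + inc + drug) * v$settings$cycle_months / 12
}

#' Per-cycle utility of occupying a health state
#'
#' Age-band weight multiplied by the state-specific weight, plus the
#' annualized memantine utility increment for severe AD on treatment, divided
#' over the cycles of a year.
#'
#' @inheritParams cycle_cost
#' @return QALYs per cycle.
#' @export
cycle_utility <- function(age, group = c("AD", "nonAD"),
                          severity = c("mild", "moderate", "severe"),
                          location = c("community", "ltcf"),
                          on_treatment = FALSE, ps = default_parameters()) {
  group <- match.arg(group); location <- match.arg(location)
  v <- model_inputs(ps)
  key <- if (group == "nonAD") "nonad" else match.arg(severity)
  w <- v$utilities[[paste0(
    if (location == "community") "community_" else "ltcf_", key)]]
  extra <- if (group == "AD" && key == "severe" && on_treatment) {
    v$treatment$memantine_utility
  } else 0
  (age_band_weight(age, v) * w + extra) * v$settings$cycle_months / 12
}

#' Structural scenario flags
#'
#' Switches for the structural sensitivity analyses: the natural history
#' assumed for non-AD patients, whether false-negative patients are
#' re-diagnosed (and offered treatment) when their disease progresses, the
#' fraction of the treatment benefit received by falsely diagnosed non-AD
#' patients, and whether donepezil also slows the moderate-to-severe
#' transition.
#'
#' @param nonad_history `"stable_mild"` (base case), `"stable_moderate"`, or
#'   `"progressive_like_AD"`.
#' @param fn_correction_on_progression if `TRUE`, false negatives begin
#'   treatment (at the usual uptake probabilities) on transition to moderate
#'   or severe disease.
#' @param fp_benefit_fraction fraction of the treatment effect (on hazards,
#'   and on the memantine utility increment where applicable) received by
#'   false-positive patients; `NULL` uses the parameter set's value (0 in the
#'   base case).
#' @param donepezil_affects_moderate_to_severe if `TRUE`, the
#'   mild-to-moderate treatment HR is also applied to the moderate-to-severe
#'   transition.
#' @return an object of class `scenario_flags`.
#' @export
scenario_flags <- function(nonad_history = c("stable_mild", "stable_moderate",
                                             "progressive_like_AD"),
                           fn_correction_on_progression = FALSE,
                           fp_benefit_fraction = NULL,
                           donepezil_affects_moderate_to_severe = FALSE) {
  nonad_history <- match.arg(nonad_history)
  if (!is.null(fp_benefit_fraction)) {
    check_fraction(fp_benefit_fraction, "fp_benefit_fraction")
  }
  structure(list(
    nonad_history = nonad_history,
    fn_correction_on_progression = isTRUE(fn_correction_on_progression),
    fp_benefit_fraction = fp_benefit_fraction,
    donepezil_affects_moderate_to_severe = isTRUE(donepezil_affects_moderate_to_severe)
  ), class = "scenario_flags")
}

# scale a treatment hazard ratio toward the null by the benefit fraction f:
# f = 1 gives the full effect, f = 0 gives none.
scale_hr <- function(hr, f) 1 + f * (hr - 1)

# ---- state spaces --------------------------------------------------------

SEV_LEVELS <- c("mild", "moderate", "severe")

ad_state_table <- function() {
  st <- expand.grid(tx = 0:1, loc = 1:2, sev = 1:3,
                    KEEP.OUT.ATTRS = FALSE)[, c("sev", "loc", "tx")]
  st$name <- paste(SEV_LEVELS[st$sev],
                   c("community", "ltcf")[st$loc],
                   c("off", "on")[st$tx + 1L], sep = ".")
  st
}

nonad_state_table <- function() {
  st <- expand.grid(tx = 0:1, loc = 1:2, KEEP.OUT.ATTRS = FALSE)[, c("loc", "tx")]
  st$name <- paste("nonad", c("community", "ltcf")[st$loc],
                   c("off", "on")[st$tx + 1L], sep = ".")
  st
}

# conditional-on-survival monthly transition matrix over the 12 AD states.
# cfg: eff (treatment HRs, already scaled for partial benefit), mem_uptake,
# reinit_don/reinit_mem, reinit_mild_zero, corr_uptake_moderate (uptake applied
# on the mild->moderate transition for re-diagnosed false negatives, or NULL).
ad_conditional_matrix <- function(v, cfg) {
  st <- ad_state_table()
  n <- nrow(st)
  cyc <- v$settings$cycle_months
  r <- v$rates; tr <- v$treatment
  M <- matrix(0, n, n, dimnames = list(st$name, st$name))
  for (i in seq_len(n)) {
    sev <- st$sev[i]; loc <- st$loc[i]; tx <- st$tx[i]
    # severity event: competing hazards to the other two severities
    h <- c(0, 0, 0)
    if (sev == 1L) {
      h[2] <- r$mild_to_moderate * if (tx) cfg$eff$hr_m2mod else 1
      h[3] <- r$mild_to_severe
    } else if (sev == 2L) {
      h[1] <- r$moderate_to_mild * if (tx) cfg$eff$hr_mod2m else 1
      h[3] <- r$moderate_to_severe * if (tx) cfg$eff$hr_mod2sev else 1
    } else {
      h[1] <- r$severe_to_mild
      h[2] <- r$severe_to_moderate
    }
    H <- sum(h)
    p_sev <- c(0, 0, 0)
    if (H > 0) p_sev <- annual_hazard_to_cycle_prob(H, cyc) * h / H
    p_sev[sev] <- 1 - sum(p_sev)
    # location event
    p_move <- 0
    if (loc == 1L) {
      lr <- c(r$ltcf_mild, r$ltcf_moderate, r$ltcf_severe)[sev]
      if (tx) lr <- lr * (if (sev == 3L) cfg$eff$hr_ltcf_mem else cfg$eff$hr_ltcf_don)
      p_move <- annual_hazard_to_cycle_prob(lr, cyc)
    }
    p_loc <- if (loc == 1L) c(1 - p_move, p_move) else c(0, 1)
    # treatment event (current drug: donepezil in mild/moderate, memantine in severe)
    if (tx) {
      dr <- if (sev == 3L) tr$disc_memantine else
        if (loc == 1L) tr$disc_donepezil_community else tr$disc_donepezil_ltcf
      p_off <- annual_hazard_to_cycle_prob(dr, cyc)
      p_tx <- c(p_off, 1 - p_off)
    } else {
      rr <- if (sev == 3L) cfg$reinit_mem else cfg$reinit_don
      if (sev == 1L && isTRUE(cfg$reinit_mild_zero)) rr <- 0
      p_on <- annual_hazard_to_cycle_prob(rr, cyc)
      p_tx <- c(1 - p_on, p_on)
    }
    for (s2 in 1:3) {
      if (p_sev[s2] == 0) next
      # entering severe: donepezil stops and memantine uptake applies;
      # re-diagnosed false negatives start donepezil on reaching moderate
      p_t2 <- p_tx
      if (s2 == 3L && sev != 3L) {
        p_t2 <- c(1 - cfg$mem_uptake, cfg$mem_uptake)
      } else if (s2 == 2L && sev == 1L && tx == 0L &&
                 !is.null(cfg$corr_uptake_moderate)) {
        p_t2 <- c(1 - cfg$corr_uptake_moderate, cfg$corr_uptake_moderate)
      }
      for (l2 in loc:2) {
        pl <- p_loc[l2]
        if (pl == 0) next
        for (t2 in 0:1) {
          j <- (s2 - 1L) * 4L + (l2 - 1L) * 2L + t2 + 1L
          M[i, j] <- M[i, j] + p_sev[s2] * pl * p_t2[t2 + 1L]
        }
      }
    }
  }
  M
}

# conditional monthly transition matrix over the 4 non-AD states.
# cfg: ltcf_rate, hr_ltcf_eff (benefit-scaled HR while on treatment), reinit.
nonad_conditional_matrix <- function(v, cfg) {
  st <- nonad_state_table()
  cyc <- v$settings$cycle_months
  tr <- v$treatment
  M <- matrix(0, 4, 4, dimnames = list(st$name, st$name))
  for (i in 1:4) {
    loc <- st$loc[i]; tx <- st$tx[i]
    p_move <- 0
    if (loc == 1L) {
      lr <- cfg$ltcf_rate * if (tx) cfg$hr_ltcf_eff else 1
      p_move <- annual_hazard_to_cycle_prob(lr, cyc)
    }
    p_loc <- if (loc == 1L) c(1 - p_move, p_move) else c(0, 1)
    if (tx) {
      dr <- if (loc == 1L) tr$disc_donepezil_community else tr$disc_donepezil_ltcf
      p_off <- annual_hazard_to_cycle_prob(dr, cyc)
      p_tx <- c(p_off, 1 - p_off)
    } else {
      p_on <- annual_hazard_to_cycle_prob(cfg$reinit, cyc)
      p_tx <- c(1 - p_on, p_on)
    }
    for (l2 in loc:2) {
      for (t2 in 0:1) {
        j <- (l2 - 1L) * 2L + t2 + 1L
        M[i, j] <- M[i, j] + p_loc[l2] * p_tx[t2 + 1L]
      }
    }
  }
  M
}

# ---- per-group model assembly -------------------------------------------

build_group_model <- function(v, group, flags) {
  tr <- v$treatment
  f_fp <- flags$fp_benefit_fraction %||% tr$fp_benefit_fraction
  ad_like <- group %in% c("TP", "FN") ||
    flags$nonad_history == "progressive_like_AD"
  if (ad_like) {
    st <- ad_state_table()
    treated <- switch(group, TP = TRUE, FP = TRUE, FN = flags$fn_correction_on_progression,
                      TN = FALSE)
    benefit <- switch(group, TP = 1, FN = 1, FP = f_fp, TN = 0)
    hr_mod2sev <- if (flags$donepezil_affects_moderate_to_severe) {
      tr$hr_mild_to_moderate
    } else 1
    cfg <- list(
      eff = list(
        hr_m2mod   = scale_hr(tr$hr_mild_to_moderate, benefit),
        hr_mod2m   = scale_hr(tr$hr_moderate_to_mild, benefit),
        hr_mod2sev = scale_hr(hr_mod2sev, benefit),
        hr_ltcf_don = scale_hr(tr$hr_ltcf, benefit),
        hr_ltcf_mem = scale_hr(tr$hr_ltcf_memantine, benefit)
      ),
      mem_uptake = if (treated) tr$uptake_memantine else 0,
      reinit_don = if (treated) tr$reinit_donepezil else 0,
      reinit_mem = if (treated) tr$reinit_memantine else 0,
      reinit_mild_zero = group == "FN",
      corr_uptake_moderate = if (group == "FN" && treated) tr$uptake_donepezil
    )
    cond <- ad_conditional_matrix(v, cfg)
    hr <- c(v$mortality$hr_mild, v$mortality$hr_moderate,
            v$mortality$hr_severe)[st$sev]
    inc <- ifelse(st$loc == 1L,
      c(v$costs$inc_community_mild, v$costs$inc_community_moderate,
        v$costs$inc_community_severe)[st$sev],
      c(v$costs$inc_ltcf_mild, v$costs$inc_ltcf_moderate,
        v$costs$inc_ltcf_severe)[st$sev] + v$costs$facility)
    inc <- inc + st$tx * ifelse(st$sev == 3L, v$costs$memantine, v$costs$donepezil)
    uw <- ifelse(st$loc == 1L,
      c(v$utilities$community_mild, v$utilities$community_moderate,
        v$utilities$community_severe)[st$sev],
      c(v$utilities$ltcf_mild, v$utilities$ltcf_moderate,
        v$utilities$ltcf_severe)[st$sev])
    benefit_u <- switch(group, TP = 1, FN = 1, FP = f_fp, TN = 0)
    uplus <- ifelse(st$sev == 3L & st$tx == 1L,
                    tr$memantine_utility * benefit_u, 0)
    init <- numeric(12)
    if (group %in% c("TP", "FN")) {
      mix <- c(v$cohort$severity_mild, v$cohort$severity_moderate,
               v$cohort$severity_severe)
      up <- if (group == "TP") c(tr$uptake_donepezil, tr$uptake_donepezil,
                                 tr$uptake_memantine) else c(0, 0, 0)
      for (s in 1:3) {
        init[(s - 1L) * 4L + 1L] <- mix[s] * (1 - up[s])  # community, off
        init[(s - 1L) * 4L + 2L] <- mix[s] * up[s]        # community, on
      }
    } else {
      # non-AD cohort under the progressive scenario: mild impairment at entry
      up <- if (group == "FP") tr$uptake_donepezil else 0
      init[1L] <- 1 - up
      init[2L] <- up
    }
  } else {
    st <- nonad_state_table()
    sevlab <- if (flags$nonad_history == "stable_moderate") "moderate" else "nonad"
    cfg <- list(
      ltcf_rate = if (sevlab == "moderate") v$rates$ltcf_moderate else v$rates$ltcf_nonad,
      hr_ltcf_eff = if (group == "FP") scale_hr(tr$hr_ltcf, f_fp) else 1,
      reinit = if (group == "FP") tr$reinit_donepezil else 0
    )
    cond <- nonad_conditional_matrix(v, cfg)
    hr <- rep(if (sevlab == "moderate") v$mortality$hr_moderate else
      v$mortality$hr_nonad, 4)
    inc <- ifelse(st$loc == 1L,
                  v$costs[[paste0("inc_community_", sevlab)]],
                  v$costs[[paste0("inc_ltcf_", sevlab)]] + v$costs$facility)
    inc <- inc + st$tx * v$costs$donepezil
    uw <- ifelse(st$loc == 1L,
                 v$utilities[[paste0("community_", sevlab)]],
                 v$utilities[[paste0("ltcf_", sevlab)]])
    uplus <- numeric(4)
    up <- if (group == "FP") tr$uptake_donepezil else 0
    init <- c(1 - up, up, 0, 0)
  }
  list(states = st, init = init, cond = cond, hr = hr,
       inc = inc, uw = uw, uplus = uplus)
}

# ---- cohort engine -------------------------------------------------------

#' Lifetime outcomes of one diagnostic-outcome group
#'
#' Runs the monthly Markov cohort model for one diagnostic-outcome group and
#' returns discounted lifetime cost, discounted QALYs, and life-years. AD
#' groups (TP, FN) start community-dwelling with the initial severity mix;
#' true positives start treatment with the uptake probabilities, false
#' negatives are never treated in the base case. Non-AD groups (FP, TN) start
#' community-dwelling with stable mild cognitive impairment; false positives
#' carry treatment costs (with efficacy scaled by the false-positive benefit
#' fraction, 0 in the base case).
#'
#' Accrual convention: costs and utilities accrue for the full cycle in the
#' start-of-cycle state; there is no half-cycle correction (second-order at
#' 1-month cycles). Discounting uses the per-cycle factor
#' `(1 + rate)^(-(month - 1)/12)`.
#'
#' Which cost components accrue over the lifetime is controlled by
#' `settings$accrue_baseline` and `settings$accrue_death_cost`. The analysis
#' default accrues the severity/location incremental care costs, the LTCF
#' facility cost, and medication, and excludes the age-baseline and
#' year-of-death costs; see the methods vignette for why this is the accrual
#' under which the published per-outcome results are internally consistent.
#' When `accrue_death_cost` is on, the one-time age-dependent cost of dying is
#' added in the cycle of death.
#'
#' @param group `"TP"`, `"FN"`, `"FP"`, or `"TN"`.
#' @param ps parameter set (`cea_parameters` or realized `cea_inputs`).
#' @param flags structural [scenario_flags()].
#' @param trace if `TRUE`, attach the per-cycle trace (month, age, state
#'   occupancy, cycle cost, cycle QALYs, discount factor).
#' @return an object of class `lifetime_outcome` with elements `cost`,
#'   `qalys`, `life_years` (undiscounted), `disc_life_years`, and optionally
#'   `trace`.
#' @export
run_cohort <- function(group = c("TP", "FN", "FP", "TN"), ps,
                       flags = scenario_flags(), trace = FALSE) {
  group <- match.arg(group)
  v <- model_inputs(ps)
  mod <- build_group_model(v, group, flags)
  run_markov_model(mod, v, trace = trace)
}

# use_compiled selects the C++ accumulation kernel; the interpreted loop below
# is the reference implementation (also used whenever a trace is requested) and
# the two are asserted equal in the test suite.
run_markov_model <- function(mod, v, trace = FALSE, use_compiled = !trace) {
  st <- v$settings
  start_age <- v$cohort$start_age
  n_cycles <- max(1L, ceiling((st$max_age - start_age) * 12 / st$cycle_months))
  ages <- start_age + (seq_len(n_cycles) - 1L) * st$cycle_months / 12
  disc <- (1 + st$discount_rate)^(-(seq_len(n_cycles) - 1L) * st$cycle_months / 12)
  mort <- v$mortality$coeff_a * exp(v$mortality$coeff_b * ages)  # per 100k/yr
  base_cost <- if (isTRUE(st$accrue_baseline)) baseline_cost_vec(ages, v) else
    numeric(n_cycles)
  agew <- age_weight_vec(ages, v)
  death_cost <- if (isTRUE(st$accrue_death_cost)) {
    ifelse(ages < 90, v$costs$death_under90, v$costs$death_over90)
  } else numeric(n_cycles)
  cyc_frac <- st$cycle_months / 12

  occ <- mod$init
  cond <- mod$cond
  hrv <- mod$hr
  inc <- mod$inc
  uw <- mod$uw
  uplus <- mod$uplus

  if (use_compiled && !trace) {
    acc <- markov_accumulate(occ, cond, hrv, mort, inc, uw, uplus,
                             base_cost, agew, death_cost, disc, cyc_frac)
    return(structure(list(cost = acc[1], qalys = acc[2], life_years = acc[3],
                          disc_life_years = acc[4]),
                     class = "lifetime_outcome"))
  }

  cost <- qaly <- ly <- dly <- 0
  tr_rows <- if (trace) vector("list", n_cycles) else NULL

  for (m in seq_len(n_cycles)) {
    live <- sum(occ)
    if (live < 1e-9) break
    pd <- 1 - exp(-(mort[m] * hrv / 1e5) * cyc_frac)
    c_m <- (live * base_cost[m] + sum(occ * inc)) * cyc_frac
    q_m <- (agew[m] * sum(occ * uw) + sum(occ * uplus)) * cyc_frac
    deaths <- occ * pd
    d_m <- sum(deaths)
    cost <- cost + (c_m + d_m * death_cost[m]) * disc[m]
    qaly <- qaly + q_m * disc[m]
    ly <- ly + live * cyc_frac
    dly <- dly + live * cyc_frac * disc[m]
    if (trace) {
      tr_rows[[m]] <- c(month = m, age = ages[m], occ,
                        dead = 1 - live, cycle_cost = c_m,
                        cycle_qaly = q_m, discount = disc[m])
    }
    occ <- drop((occ - deaths) %*% cond)
    if (any(occ < -1e-12) || abs(sum(occ) - (live - d_m)) > 1e-8) {
      stop("internal error: occupancy mass not conserved", call. = FALSE)
    }
  }

  out <- list(cost = cost, qalys = qaly, life_years = ly,
              disc_life_years = dly)
  if (trace) {
    tr <- as.data.frame(do.call(rbind, tr_rows[!vapply(tr_rows, is.null, TRUE)]))
    names(tr) <- c("month", "age", mod$states$name, "dead",
                   "cycle_cost", "cycle_qaly", "discount")
    out$trace <- tr
  }
  class(out) <- "lifetime_outcome"
  out
}

baseline_cost_vec <- function(ages, v) {
  raw <- v$costs$baseline_a * exp(v$costs$baseline_b * ages)
  ifelse(ages >= 90, pmin(raw, v$costs$baseline_cap), raw)
}

age_weight_vec <- function(ages, v) {
  u <- v$utilities
  w <- c(u$age_60_64, u$age_65_69, u$age_70_74, u$age_75_79, u$age_gt79)
  w[findInterval(ages, c(-Inf, 65, 70, 75, 80))]
}

#' @export
print.lifetime_outcome <- function(x, ...) {
  cat(sprintf(
    "<lifetime_outcome> cost $%s, QALYs %.3f, LYs %.3f (discounted %.3f)\n",
    format(round(x$cost), big.mark = ","), x$qalys, x$life_years,
    x$disc_life_years))
  invisible(x)
}
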