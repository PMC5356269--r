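# Model inputs: every base-case value, its deterministic sensitivity range, and
# the analysis settings. Values are 2013 US dollars; rates are instantaneous
# annual hazards on the per-100,000 person-year scale used by the source tables.

#' Create a single model parameter with an uncertainty range
#'
#' A `param_value` carries a base-case value, the low/high values used in
#' deterministic sensitivity analysis (interpreted as an approximate 95%
#' interval when sampling), and a kind tag that controls validation rules and
#' the distribution family used in probabilistic sensitivity analysis.
#'
#' @param base base-case value.
#' @param low,high deterministic sensitivity range; default to `base`
#'   (a degenerate range, excluded from sampling).
#' @param kind one of `"probability"`, `"rate"` (annual hazard per 100,000),
#'   `"hazard_ratio"`, `"cost"` (US$), `"utility"`, `"years"`, `"coefficient"`.
#' @return an object of class `param_value`.
#' @export
param_value <- function(base, low = base, high = base,
                        kind = c("probability", "rate", "hazard_ratio",
                                 "cost", "utility", "years", "coefficient")) {
  kind <- match.arg(kind)
  if (!is.numeric(base) || !is.numeric(low) || !is.numeric(high)) {
    stop("param_value components must be numeric", call. = FALSE)
  }
  structure(list(base = base, low = low, high = high, kind = kind),
            class = "param_value")
}

#' @export
print.param_value <- function(x, ...) {
  cat(sprintf("<param_value %s> base %g [%g, %g]\n", x$kind, x$base, x$low, x$high))
  invisible(x)
}

is_param_value <- function(x) inherits(x, "param_value")

#' Packaged base-case parameter set
#'
#' Returns the full model parameter set: the tested-cohort description,
#' diagnostic test accuracy, mortality, AD natural-history transition hazards,
#' treatment uptake/adherence/efficacy, costs, utilities, and analysis
#' settings. Each uncertain quantity is a [param_value()] with its
#' deterministic sensitivity range.
#'
#' Non-AD dementia (stable mild cognitive impairment in the base case) borrows
#' every parameter it needs from mild AD — costs, utilities, the hazard of
#' long-term-care placement, and the mortality hazard ratio — unless an
#' explicit override is supplied (fields `*_nonad`, `NULL` means "linked to
#' mild"). The conditional accuracy of biomarker analysis given a negative
#' MRI criterion is pre-computed from the combined-criterion and MRI-only
#' accuracies (see [conditional_biomarker_accuracy()]).
#'
#' @return an object of class `cea_parameters`.
#' @seealso [load_parameters()], [validate_parameters()], [model_inputs()]
#' @export
default_parameters <- function() {
  pv <- param_value
  ps <- list(
    cohort = list(
      start_age              = pv(65, 55, 75, "years"),
      severity_mild          = pv(0.70, 0.540, 0.783, "probability"),
      severity_moderate      = pv(0.28, 0.185, 0.427, "probability"),
      severity_severe        = pv(0.02, 0.017, 0.033, "probability"),
      proportion_diagnosed   = pv(0.24, kind = "probability"),
      fraction_nonad_excluded = pv(0, kind = "probability")
    ),
    accuracy = list(
      mr_sn       = pv(0.54, 0.46, 0.62, "probability"),
      mr_sp       = pv(0.84, 0.79, 0.89, "probability"),
      combined_sn = pv(0.86, 0.80, 0.92, "probability"),
      combined_sp = pv(0.79, 0.74, 0.84, "probability"),
      memory_sn   = pv(0.93, kind = "probability"),
      memory_sp   = pv(0.68, kind = "probability"),
      # conditional accuracy of CSF biomarkers given no MTL atrophy on MRI,
      # solved from the combined and MRI-only accuracies
      bm_sn = pv((0.86 - 0.54) / (1 - 0.54), 0.54, 0.86, "probability"),
      bm_sp = pv(0.79 / 0.84, 0.89, 0.98, "probability")
    ),
    mortality = list(
      coeff_a     = pv(3.53, kind = "coefficient"),   # per 100,000/yr at age 0
      coeff_b     = pv(0.0909, kind = "coefficient"), # per year of age
      hr_mild     = pv(2.92, 2.34, 3.52, "hazard_ratio"),
      hr_moderate = pv(3.85, 2.94, 5.05, "hazard_ratio"),
      hr_severe   = pv(9.52, 6.60, 13.4, "hazard_ratio"),
      hr_nonad    = NULL  # linked to hr_mild unless overridden
    ),
    rates = list( # annual hazards per 100,000, untreated
      mild_to_moderate     = pv(27710, 24939, 30481, "rate"),
      mild_to_severe       = pv(1385, 1247, 1524, "rate"),
      moderate_to_mild     = pv(4478, 4030, 4925, "rate"),
      moderate_to_severe   = pv(31829, 28647, 35012, "rate"),
      severe_to_mild       = pv(385, 347, 424, "rate"),
      severe_to_moderate   = pv(5332, 4799, 5865, "rate"),
      ltcf_mild            = pv(2110, 500, 4000, "rate"),
      ltcf_moderate        = pv(6957, 1500, 8000, "rate"),
      ltcf_severe          = pv(11747, 2500, 15000, "rate"),
      ltcf_nonad           = NULL  # linked to ltcf_mild unless overridden
    ),
    treatment = list(
      uptake_donepezil         = pv(0.45, 0.27, 0.56, "probability"),
      uptake_memantine         = pv(0.36, 0.22, 0.45, "probability"),
      disc_donepezil_community = pv(28768, 10536, 35667, "rate"),
      disc_donepezil_ltcf      = pv(62362, 51083, 69315, "rate"),
      disc_memantine           = pv(30111, 12783, 44629, "rate"),
      reinit_donepezil         = pv(33142, 23105, 40132, "rate"),
      reinit_memantine         = pv(22314, 17834, 25541, "rate"),
      hr_mild_to_moderate      = pv(0.50, 0.253, 0.989, "hazard_ratio"),
      hr_moderate_to_mild      = pv(2.36, 0.802, 6.95, "hazard_ratio"),
      hr_ltcf                  = pv(0.37, 0.20, 0.50, "hazard_ratio"),
      hr_ltcf_memantine        = pv(0.37, 0.20, 0.50, "hazard_ratio"),
      memantine_utility        = pv(0.051, 0, 0.10, "utility"),
      fp_benefit_fraction      = pv(0, 0, 1, "probability")
    ),
    costs = list( # 2013 US$
      baseline_a    = pv(893, kind = "coefficient"),
      baseline_b    = pv(0.0404, kind = "coefficient"),
      baseline_cap  = pv(33870, kind = "cost"),  # applies from age 90
      inc_community_mild     = pv(24128, 17369, 30369, "cost"),
      inc_community_moderate = pv(33845, 25000, 40000, "cost"),
      inc_community_severe   = pv(60160, 50000, 69000, "cost"),
      inc_community_nonad    = NULL,  # linked to mild
      inc_ltcf_mild          = pv(9872, 7000, 12000, "cost"),
      inc_ltcf_moderate      = pv(9872, 7000, 12000, "cost"),
      inc_ltcf_severe        = pv(9847, 7000, 12000, "cost"),
      inc_ltcf_nonad         = NULL,  # linked to mild
      facility               = pv(83950, 70000, 95000, "cost"),
      donepezil              = pv(2473, 2000, 4288, "cost"),
      memantine              = pv(3192, 2500, 5957, "cost"),
      death_under90          = pv(35158, 32000, 39500, "cost"),
      death_over90           = pv(25455, 22000, 28000, "cost"),
      test_cost              = pv(463, 250, 600, "cost")
    ),
    utilities = list(
      age_60_64 = pv(0.83, 0.822, 0.835, "utility"),
      age_65_69 = pv(0.82, 0.820, 0.826, "utility"),
      age_70_74 = pv(0.81, 0.803, 0.818, "utility"),
      age_75_79 = pv(0.79, 0.786, 0.794, "utility"),
      age_gt79  = pv(0.74, 0.730, 0.742, "utility"),
      community_mild     = pv(0.68, 0.52, 0.80, "utility"),
      community_moderate = pv(0.54, 0.30, 0.70, "utility"),
      community_severe   = pv(0.37, 0.25, 0.50, "utility"),
      community_nonad    = NULL,  # linked to mild
      ltcf_mild          = pv(0.71, 0.55, 0.80, "utility"),
      ltcf_moderate      = pv(0.48, 0.30, 0.60, "utility"),
      ltcf_severe        = pv(0.31, 0.20, 0.45, "utility"),
      ltcf_nonad         = NULL,  # linked to mild
      lp_toll = pv(0.008, 0, 0.02, "utility")  # one-time QALY toll of the test
    ),
    settings = list(
      discount_rate = 0.03,
      cycle_months  = 1,
      wtp           = c(50000, 100000),
      psa_draws     = 10000,
      max_age       = 120,
      # lifetime accrual of the age-baseline and year-of-death costs; the
      # published per-outcome results are reproduced only with both off
      # (see the methods vignette), so that is the analysis default
      accrue_baseline   = FALSE,
      accrue_death_cost = FALSE
    )
  )
  class(ps) <- "cea_parameters"
  ps
}

# parameters never varied in the PSA even though a range is present: the
# combined-criterion accuracy is represented in sampling by the conditional
# biomarker accuracy (bm_sn, bm_sp), which the source table lists with its own
# range; sampling both would double-count test-accuracy uncertainty.
PSA_EXCLUDE <- c("accuracy.combined_sn", "accuracy.combined_sp")

#' Flat table of model parameters
#'
#' Walks the parameter set in a stable order and returns one row per
#' [param_value()]: its dotted identifier (`group.name`), base value, range and
#' kind. The ordering is the contract used by the sampler so that adding a
#' parameter at the end does not scramble earlier draws.
#'
#' @param ps a `cea_parameters` object.
#' @return a data.frame with columns `id`, `base`, `low`, `high`, `kind`,
#'   `has_range`.
#' @export
param_table <- function(ps) {
  stopifnot(inherits(ps, "cea_parameters"))
  rows <- list()
  for (g in setdiff(names(ps), "settings")) {
    for (nm in names(ps[[g]])) {
      x <- ps[[g]][[nm]]
      if (is_param_value(x)) {
        rows[[length(rows) + 1L]] <- data.frame(
          id = paste(g, nm, sep = "."), base = x$base, low = x$low,
          high = x$high, kind = x$kind, has_range = x$low < x$high,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Get or set a parameter by dotted identifier
#'
#' @param ps a `cea_parameters` object.
#' @param id dotted identifier, e.g. `"treatment.uptake_donepezil"`.
#' @param value replacement: a single number (replaces the base value, keeping
#'   the range) or a full [param_value()].
#' @return `get_param()` returns the `param_value`; `set_param()` the modified
#'   parameter set.
#' @export
get_param <- function(ps, id) {
  path <- strsplit(id, ".", fixed = TRUE)[[1]]
  if (length(path) != 2L || is.null(ps[[path[1]]]) || !path[2] %in% names(ps[[path[1]]])) {
    stop("unknown parameter id: ", id, call. = FALSE)
  }
  ps[[path[1]]][[path[2]]]
}

#' @rdname get_param
#' @export
set_param <- function(ps, id, value) {
  path <- strsplit(id, ".", fixed = TRUE)[[1]]
  cur <- get_param(ps, id)
  if (is_param_value(value)) {
    ps[[path[1]]][[path[2]]] <- value
  } else if (is.numeric(value) && length(value) == 1L) {
    if (is_param_value(cur)) {
      cur$base <- value
      ps[[path[1]]][[path[2]]] <- cur
    } else {
      ps[[path[1]]][[path[2]]] <- param_value(value)
    }
  } else {
    stop("value must be a number or a param_value", call. = FALSE)
  }
  ps
}

#' Validate a parameter set
#'
#' Checks every type invariant and returns a character vector of violation
#' descriptions (empty when the set is valid). Violations are returned, not
#' raised, so callers can decide whether a draw should be rejected or a load
#' refused.
#'
#' @param ps a `cea_parameters` object, or a realized `cea_inputs` object
#'   (e.g. a PSA draw), in which case the range checks are vacuous but all
#'   structural invariants are still verified.
#' @return character vector of violations; `character(0)` if valid.
#' @export
validate_parameters <- function(ps) {
  if (inherits(ps, "cea_inputs")) ps <- inputs_as_parameters(ps)
  v <- character(0)
  add <- function(msg) v[[length(v) + 1L]] <<- msg
  tab <- param_table(ps)
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (!(r$low <= r$base && r$base <= r$high)) {
      add(sprintf("%s: range violated (low %g <= base %g <= high %g fails)",
                  r$id, r$low, r$base, r$high))
    }
    if (r$kind %in% c("probability", "utility") &&
        (r$low < 0 || r$high > 1)) {
      add(sprintf("%s: %s %g outside [0, 1]", r$id, r$kind, r$base))
    }
    if (r$kind %in% c("rate", "cost") && r$low < 0) {
      add(sprintf("%s: %s must be >= 0 (low is %g)", r$id, r$kind, r$low))
    }
  }
  mix <- ps$cohort$severity_mild$base + ps$cohort$severity_moderate$base +
    ps$cohort$severity_severe$base
  if (abs(mix - 1) > 1e-9) {
    add(sprintf("cohort severity mix sums to %g, not 1", mix))
  }
  mt <- ps$mortality
  if (!(mt$hr_severe$base > mt$hr_moderate$base &&
        mt$hr_moderate$base > mt$hr_mild$base && mt$hr_mild$base > 1)) {
    add("mortality HRs must satisfy severe > moderate > mild > 1")
  }
  if (ps$treatment$hr_mild_to_moderate$base >= 1) {
    add(sprintf(
      "treatment.hr_mild_to_moderate is %g; treatment must slow progression (HR < 1)",
      ps$treatment$hr_mild_to_moderate$base))
  }
  if (ps$treatment$hr_moderate_to_mild$base <= 1) {
    add(sprintf(
      "treatment.hr_moderate_to_mild is %g; treatment must favour regression (HR > 1)",
      ps$treatment$hr_moderate_to_mild$base))
  }
  cc <- ps$costs
  if (!(cc$inc_community_severe$base > cc$inc_community_moderate$base &&
        cc$inc_community_moderate$base > cc$inc_community_mild$base)) {
    add("community incremental costs must increase with severity")
  }
  uu <- ps$utilities
  if (!(uu$community_mild$base > uu$community_moderate$base &&
        uu$community_moderate$base > uu$community_severe$base)) {
    add("community utility weights must decrease with severity")
  }
  ac <- ps$accuracy
  if (!is.null(ac$combined_sn) && ac$combined_sn$base < ac$mr_sn$base) {
    add("combined-criterion sensitivity must be >= MRI-only sensitivity")
  }
  if (!is.null(ac$combined_sp) && ac$combined_sp$base > ac$mr_sp$base) {
    add("combined-criterion specificity must be <= MRI-only specificity")
  }
  st <- ps$settings
  if (st$discount_rate < 0) add("settings: discount rate must be >= 0")
  if (st$psa_draws < 1) add("settings: psa_draws must be >= 1")
  v
}

#' Load a parameter set from a configuration document
#'
#' Reads a YAML or JSON document of overrides on top of the packaged defaults
#' (see [default_parameters()]). An override may be a bare number (replacing
#' the base value and keeping the published range) or a mapping with any of
#' `base`, `low`, `high`. Settings (`discount_rate`, `wtp`, `psa_draws`,
#' `max_age`, `cycle_months`) are replaced verbatim. The loaded set is
#' validated; any violation is a load error naming the offending field.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` document, or `NULL` for the
#'   packaged defaults.
#' @param overrides a nested list of overrides applied after `path`.
#' @return a validated `cea_parameters` object.
#' @examples
#' ps <- load_parameters(overrides = list(cohort = list(start_age = 75)))
#' ps$cohort$start_age$base
#' @export
load_parameters <- function(path = NULL, overrides = NULL) {
  ps <- default_parameters()
  doc <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such configuration file: ", path, call. = FALSE)
    ext <- tolower(tools::file_ext(path))
    doc <- switch(ext,
      "json" = jsonlite::read_json(path, simplifyVector = TRUE),
      "yaml" = ,
      "yml"  = yaml::read_yaml(path),
      stop("unsupported configuration format: .", ext, call. = FALSE))
    if (is.null(doc)) doc <- list()
  }
  if (!is.null(overrides)) doc <- modifyList(doc, overrides)
  ps <- apply_overrides(ps, doc)
  bad <- validate_parameters(ps)
  if (length(bad)) {
    stop("invalid parameter document:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  ps
}

apply_overrides <- function(ps, doc) {
  for (g in names(doc)) {
    if (!g %in% names(ps)) stop("unknown parameter group: ", g, call. = FALSE)
    if (g == "settings") {
      for (nm in names(doc$settings)) {
        if (!nm %in% names(ps$settings)) {
          stop("unknown setting: ", nm, call. = FALSE)
        }
        val <- doc$settings[[nm]]
        ps$settings[[nm]] <- if (is.numeric(val)) as.numeric(val) else val
      }
      next
    }
    for (nm in names(doc[[g]])) {
      if (!nm %in% names(ps[[g]])) {
        stop("unknown parameter: ", g, ".", nm, call. = FALSE)
      }
      ov <- doc[[g]][[nm]]
      cur <- ps[[g]][[nm]]
      if (is.numeric(ov) && length(ov) == 1L) {
        ps[[g]][[nm]] <- if (is_param_value(cur)) {
          modifyList(cur, list(base = as.numeric(ov)))
        } else {
          param_value(as.numeric(ov))
        }
      } else if (is.list(ov)) {
        if (!all(names(ov) %in% c("base", "low", "high", "kind"))) {
          stop("override for ", g, ".", nm,
               " may only set base/low/high/kind", call. = FALSE)
        }
        ov[names(ov) != "kind"] <- lapply(ov[names(ov) != "kind"], as.numeric)
        base <- if (is_param_value(cur)) cur else param_value(NA_real_)
        ps[[g]][[nm]] <- structure(modifyList(unclass(base), ov),
                                   class = "param_value")
      } else {
        stop("override for ", g, ".", nm,
             " must be a number or a base/low/high mapping", call. = FALSE)
      }
    }
  }
  class(ps) <- "cea_parameters"
  ps
}

#' Serialize a parameter set
#'
#' Writes the parameter set to JSON (full double precision; round-trips
#' bit-for-bit through [load_parameters()] applied to the written file) or
#' YAML by file extension.
#'
#' @param ps a `cea_parameters` object.
#' @param path output path ending in `.json`, `.yaml`, or `.yml`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(ps, path) {
  stopifnot(inherits(ps, "cea_parameters"))
  doc <- lapply(unclass(ps), function(grp) {
    grp <- grp[!vapply(grp, is.null, logical(1))]  # linked fields stay implicit
    lapply(grp, function(x) if (is_param_value(x)) unclass(x) else x)
  })
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path, precision = 15)
  } else {
    stop("unsupported configuration format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Realize a parameter set into plain model inputs
#'
#' Collapses every [param_value()] to a single number (its base value) and
#' resolves the linked non-AD fields (mortality HR, long-term-care entry
#' hazard, costs, and utilities default to their mild-AD counterparts).
#' The result is the plain numeric structure consumed by the Markov engine;
#' [sample_parameter_set()] produces objects of the same shape.
#'
#' @param ps a `cea_parameters` object (or an already-realized `cea_inputs`
#'   object, returned unchanged).
#' @return an object of class `cea_inputs`: the same nesting with bare numbers.
#' @export
model_inputs <- function(ps) {
  if (inherits(ps, "cea_inputs")) return(ps)
  stopifnot(inherits(ps, "cea_parameters"))
  v <- lapply(unclass(ps), function(grp) {
    lapply(grp, function(x) if (is_param_value(x)) x$base else x)
  })
  v$settings <- ps$settings
  resolve_links(v)
}

# lift a realized draw back into param_value form (point ranges, kinds taken
# from the packaged defaults) so the structural validators can run on it
inputs_as_parameters <- function(v) {
  ref <- default_parameters()
  for (g in setdiff(names(ref), "settings")) {
    for (nm in names(ref[[g]])) {
      val <- v[[g]][[nm]]
      if (is.null(val)) next
      kind <- if (is_param_value(ref[[g]][[nm]])) ref[[g]][[nm]]$kind else "coefficient"
      ref[[g]][[nm]] <- param_value(val, kind = kind)
    }
  }
  # PSA draws vary the conditional biomarker accuracy directly, so the
  # combined-criterion identities no longer bind them
  ref$accuracy$combined_sn <- NULL
  ref$accuracy$combined_sp <- NULL
  ref$settings <- v$settings
  ref
}

resolve_links <- function(v) {
  v$mortality$hr_nonad      <- v$mortality$hr_nonad      %||% v$mortality$hr_mild
  v$rates$ltcf_nonad        <- v$rates$ltcf_nonad        %||% v$rates$ltcf_mild
  v$costs$inc_community_nonad <- v$costs$inc_community_nonad %||% v$costs$inc_community_mild
  v$costs$inc_ltcf_nonad    <- v$costs$inc_ltcf_nonad    %||% v$costs$inc_ltcf_mild
  v$utilities$community_nonad <- v$utilities$community_nonad %||% v$utilities$community_mild
  v$utilities$ltcf_nonad    <- v$utilities$ltcf_nonad    %||% v$utilities$ltcf_mild
  class(v) <- "cea_inputs"
  v
}

#' @export
print.cea_parameters <- function(x, ...) {
  tab <- param_table(x)
  cat(sprintf("<cea_parameters> %d parameters (%d with sensitivity ranges)\n",
              nrow(tab), sum(tab$has_range)))
  cat(sprintf("  start age %g, discount rate %.1f%%, WTP %s, %d PSA draws\n",
              x$cohort$start_age$base, 100 * x$settings$discount_rate,
              paste0("$", format(x$settings$wtp, big.mark = ","), collapse = "/"),
              x$settings$psa_draws))
  invisible(x)
}
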