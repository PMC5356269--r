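# Diagnostic-accuracy algebra for the tested cohort: how referral prevalence,
# MRI triage, and patient selection determine the pretest probability of AD in
# the patients who are actually offered CSF biomarker analysis, and how test
# accuracy splits that cohort into TP/FN/FP/TN groups.

#' True prevalence in the referral population from the proportion diagnosed
#'
#' Solves `proportion_diagnosed = p * sn + (1 - p) * (1 - sp)` for the true
#' prevalence `p`: the fraction of referred patients carrying the disease given
#' the fraction actually diagnosed by an imperfect test.
#'
#' @param proportion_diagnosed fraction of the referral population diagnosed.
#' @param sn,sp sensitivity and specificity of the diagnostic criterion.
#' @return the prevalence `p` in `[0, 1]`.
#' @examples
#' referral_prevalence(0.24, 0.54, 0.84)  # ~0.21
#' @export
referral_prevalence <- function(proportion_diagnosed, sn, sp) {
  check_fraction(sn, "sn"); check_fraction(sp, "sp")
  if (sn + sp <= 1) {
    stop("uninformative test: sn + sp must exceed 1", call. = FALSE)
  }
  fpr <- 1 - sp
  if (proportion_diagnosed < fpr - 1e-12 || proportion_diagnosed > sn + 1e-12) {
    stop(sprintf(
      "proportion diagnosed (%g) outside the attainable interval [%g, %g]",
      proportion_diagnosed, fpr, sn), call. = FALSE)
  }
  p <- (proportion_diagnosed - fpr) / (sn - fpr)
  min(max(p, 0), 1)
}

#' Pretest prevalence after clinical assessment and MRI
#'
#' Prevalence of disease among referred patients who remain without a
#' diagnosis after the MRI-based criterion: disease cases missed by the
#' criterion over all patients left undiagnosed, optionally after removing a
#' fraction of the correctly negative non-diseased patients to an alternative
#' definitive diagnosis (which enriches the remaining cohort):
#' `p(1-sn) / [p(1-sn) + (1-p) sp (1-excluded)]`.
#'
#' @param referral_p prevalence in the referral population.
#' @param sn,sp sensitivity/specificity of the clinical + MRI criterion.
#' @param fraction_nonad_excluded fraction of true-negative non-diseased
#'   patients removed from the biomarker-candidate cohort by an alternative
#'   diagnosis (0 in the base case).
#' @return pretest prevalence in the biomarker-candidate cohort.
#' @examples
#' p <- referral_prevalence(0.24, 0.54, 0.84)
#' post_mri_prevalence(p, 0.54, 0.84)        # ~0.127
#' post_mri_prevalence(p, 0.54, 0.84, 0.20)  # ~0.15
#' @export
post_mri_prevalence <- function(referral_p, sn, sp, fraction_nonad_excluded = 0) {
  check_fraction(referral_p, "referral_p"); check_fraction(sn, "sn")
  check_fraction(sp, "sp")
  check_fraction(fraction_nonad_excluded, "fraction_nonad_excluded")
  num <- referral_p * (1 - sn)
  den <- num + (1 - referral_p) * sp * (1 - fraction_nonad_excluded)
  if (den <= 0) stop("empty residual cohort (denominator is 0)", call. = FALSE)
  num / den
}

#' Prevalence in the memory-impairment subcohort
#'
#' Prevalence of disease among patients who are positive on memory impairment
#' alone but negative on the combined clinical + MRI criterion — the cohort
#' that would actually be offered biomarker testing if patients without memory
#' impairment were excluded first.
#'
#' @param referral_p prevalence in the referral population.
#' @param mem_sn,mem_sp accuracy of memory impairment alone.
#' @param mr_sn,mr_sp accuracy of the combined clinical + MRI criterion.
#' @return prevalence in the subcohort.
#' @examples
#' p <- referral_prevalence(0.24, 0.54, 0.84)
#' memory_subcohort_prevalence(p, 0.93, 0.68, 0.54, 0.84)  # ~0.39
#' @export
memory_subcohort_prevalence <- function(referral_p, mem_sn, mem_sp, mr_sn, mr_sp) {
  for (x in c(referral_p, mem_sn, mem_sp, mr_sn, mr_sp)) check_fraction(x, "input")
  if (mem_sn < mr_sn || (1 - mem_sp) < (1 - mr_sp)) {
    stop("memory impairment must be at least as sensitive and no more specific ",
         "than the combined criterion", call. = FALSE)
  }
  num <- referral_p * (mem_sn - mr_sn)
  den <- num + (1 - referral_p) * ((1 - mem_sp) - (1 - mr_sp))
  if (den <= 0) stop("empty subcohort: the two criteria coincide", call. = FALSE)
  num / den
}

#' Conditional biomarker accuracy given a negative MRI criterion
#'
#' Solves the composition identities
#' `sn_combined = sn_mr + (1 - sn_mr) * sn_bm` and
#' `sp_combined = sp_mr * sp_bm`
#' for the accuracy of biomarker analysis performed only in patients negative
#' on the MRI criterion, given the published accuracy of the combined
#' (MRI and/or biomarker) criterion and of the MRI criterion alone.
#'
#' @param combined_sn,combined_sp accuracy of the combined criterion.
#' @param mr_sn,mr_sp accuracy of the MRI criterion alone.
#' @return a list with elements `sn` and `sp`.
#' @examples
#' conditional_biomarker_accuracy(0.86, 0.79, 0.54, 0.84)  # sn ~0.696, sp ~0.941
#' @export
conditional_biomarker_accuracy <- function(combined_sn, combined_sp, mr_sn, mr_sp) {
  for (x in c(combined_sn, combined_sp, mr_sn, mr_sp)) check_fraction(x, "input")
  if (combined_sn < mr_sn) {
    stop("identity sn_combined = sn_mr + (1 - sn_mr) * sn_bm requires ",
         "combined_sn >= mr_sn", call. = FALSE)
  }
  if (mr_sp <= 0) stop("identity sp_combined = sp_mr * sp_bm requires mr_sp > 0",
                       call. = FALSE)
  if (combined_sp > mr_sp) {
    stop("identity sp_combined = sp_mr * sp_bm requires combined_sp <= mr_sp",
         call. = FALSE)
  }
  sn <- if (mr_sn >= 1) 0 else (combined_sn - mr_sn) / (1 - mr_sn)
  sp <- combined_sp / mr_sp
  list(sn = sn, sp = sp)
}

#' Diagnostic-outcome probabilities
#'
#' Splits a tested cohort into the four diagnostic-outcome groups from its
#' disease prevalence and the test's sensitivity and specificity.
#'
#' @param prevalence pretest prevalence of disease in the tested cohort.
#' @param sn,sp test sensitivity and specificity.
#' @return an object of class `outcome_probs`: a list with `p_tp`, `p_fn`,
#'   `p_fp`, `p_tn` (summing to 1).
#' @examples
#' outcome_probabilities(0.127, 0.698, 0.941)
#' @export
outcome_probabilities <- function(prevalence, sn, sp) {
  check_fraction(prevalence, "prevalence")
  check_fraction(sn, "sn"); check_fraction(sp, "sp")
  structure(list(
    p_tp = prevalence * sn,
    p_fn = prevalence * (1 - sn),
    p_fp = (1 - prevalence) * (1 - sp),
    p_tn = (1 - prevalence) * sp
  ), class = "outcome_probs")
}

#' @export
print.outcome_probs <- function(x, ...) {
  cat(sprintf("TP %5.1f%%  FN %5.1f%%  FP %5.1f%%  TN %5.1f%%\n",
              100 * x$p_tp, 100 * x$p_fn, 100 * x$p_fp, 100 * x$p_tn))
  invisible(x)
}

#' Pretest prevalence implied by a parameter set
#'
#' Runs the full cohort-selection chain at the values stored in a parameter
#' set: referral prevalence from the proportion diagnosed, then post-MRI
#' pretest prevalence allowing for exclusion of non-diseased patients with an
#' alternative diagnosis.
#'
#' @param ps a `cea_parameters` or `cea_inputs` object.
#' @return pretest prevalence of AD in the biomarker-candidate cohort.
#' @export
pretest_prevalence <- function(ps) {
  v <- model_inputs(ps)
  p_ref <- referral_prevalence(v$cohort$proportion_diagnosed,
                               v$accuracy$mr_sn, v$accuracy$mr_sp)
  post_mri_prevalence(p_ref, v$accuracy$mr_sn, v$accuracy$mr_sp,
                      v$cohort$fraction_nonad_excluded)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(name, " must be a single number in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
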