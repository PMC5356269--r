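# csfcea

Lifetime cost-effectiveness of cerebrospinal fluid (CSF) biomarker testing in
patients with suspected Alzheimer's disease (AD) who remain undiagnosed after
clinical assessment and MR neuroimaging.

Clinical assessment plus medial-temporal-lobe atrophy on MRI misses roughly
half of AD cases in referral populations. CSF biomarkers (amyloid-β42, total
tau, phospho-tau) can re-examine the undiagnosed patients, at a cost of $463
and a one-time 0.008-QALY lumbar-puncture toll per patient. Whether that is
worth doing depends critically on the pretest prevalence of AD in the tested
cohort: a true positive reaches symptomatic treatment earlier (cheaper, more
QALYs), while a false positive pays for years of useless medication.

`csfcea` implements the full decision model:

* **Cohort-selection algebra** — referral prevalence from the proportion
  diagnosed (`referral_prevalence`), post-MRI pretest prevalence
  (`post_mri_prevalence`, base case 12.7%), enrichment by alternative
  diagnoses or memory-impairment selection, and the conditional accuracy of
  biomarkers given a negative MRI criterion
  (`conditional_biomarker_accuracy`, sn 0.696 / sp 0.941 solved from
  sn<sub>c</sub> = sn<sub>mr</sub> + (1 − sn<sub>mr</sub>)·sn<sub>bm</sub>
  and sp<sub>c</sub> = sp<sub>mr</sub>·sp<sub>bm</sub>).
* **A monthly-cycle Markov cohort model** (`run_cohort`) over 12 AD states
  (severity × residence × treatment) or 4 non-AD states plus death, with
  Gompertz-type other-cause mortality times severity hazard ratios,
  treatment uptake/discontinuation/reinitiation, facility placement, and 3%
  annual discounting, for each diagnostic outcome group (TP/FN/FP/TN).
* **Economics** — strategy aggregation, ICER with dominance classification,
  net monetary benefit, and the challenge region of test characteristics
  with positive incremental net monetary benefit versus no testing
  (`challenge_region`).
* **Sensitivity analysis** — one-way and two-way deterministic analysis,
  prevalence-threshold search, structural scenarios, and a 10,000-draw
  probabilistic sensitivity analysis with CEACs (`run_psa`).
* **A microsimulation oracle** (`microsimulate_cohort`) that validates the
  cohort engine by brute force.

## Worked example

```r
library(csfcea)

ps <- default_parameters()       # packaged base-case inputs
res <- run_cea(ps)               # full base-case analysis
render_table2(res)
```

```
Lifetime discounted costs and benefits by diagnostic outcome
  true_positive   $   313,151  LYs  6.788  QALYs  3.023  (  8.9%)
  false_negative  $   324,697  LYs  6.561  QALYs  2.766  (  3.9%)
  false_positive  $   313,497  LYs  9.155  QALYs  5.041  (  5.2%)
  true_negative   $   302,152  LYs  9.155  QALYs  5.041  ( 82.1%)
By diagnostic strategy
  do_nothing      $   305,025  QALYs  4.751
  biomarker       $   305,054  QALYs  4.766
  incremental     $        29  QALYs +0.015  [ICER $1,944/QALY]
```

Reading the table: an accurately diagnosed AD patient (true positive) costs
about $11,500 *less* over a lifetime than an undiagnosed one (false
negative) — treatment delays both disease progression and facility
placement — and gains 0.26 QALYs. A false positive costs $11,345 more than a
true negative, purely in medication. Weighted by the 12.7% pretest
prevalence and the test accuracy, biomarker testing adds $29 and 0.015
QALYs per tested patient: cost-effective at any conventional threshold.

The result is driven by prevalence:

```r
prevalence_threshold(50000, ps)   # 0.087: above ~8.7% testing is below $50k/QALY
cost_saving_threshold(ps)         # 0.131: above ~13.1% testing saves money outright
run_psa(ps, n = 10000, seed = 42) # quadrant shares, CEACs, 95% intervals
```

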