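Package: csfcea
Title: Cost-Effectiveness of CSF Biomarker Testing in Suspected Alzheimer's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A monthly-cycle Markov cohort model of the lifetime costs and
    quality-adjusted life-years of cerebrospinal fluid (CSF) biomarker testing
    in patients referred with suspected Alzheimer's disease (AD) who remain
    undiagnosed after clinical assessment and neuroimaging. Implements the
    diagnostic-accuracy algebra linking referral prevalence, post-MRI pretest
    prevalence, and conditional biomarker accuracy; lifetime cohort simulation
    for true-positive, false-negative, false-positive, and true-negative
    diagnostic outcomes; incremental cost-effectiveness and net-monetary-benefit
    analysis including the Phelps-Mushlin challenge region; deterministic,
    structural, and probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves; and an individual-level microsimulation oracle for
    validating the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
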