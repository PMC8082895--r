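Package: prepcea
Title: Cost-Effectiveness of Intra-Procedural Bowel-Prep Rescue in Screening Colonoscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Lifetime Markov cohort model comparing standard-of-care screening
    colonoscopy with an intra-procedural colon-cleansing device strategy for
    patients who present with inadequate bowel preparation. Provides the cohort
    state-transition engine with discounted cost and QALY accrual, colonoscopy
    episode costing under Medicare and private-payer reimbursement, incremental
    cost-effectiveness statistics (ICER, incremental net benefit, dominance),
    one-way and threshold sensitivity analysis by bisection, Monte-Carlo
    probabilistic sensitivity analysis with running-mean ICER convergence
    monitoring, logistic-regression propensity scoring with greedy caliper
    matching, and a patient-level microsimulation twin of the cohort engine
    used as an independent validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
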