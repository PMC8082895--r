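# prepcea

Lifetime cost-effectiveness modelling of intra-procedural bowel-prep
rescue in screening colonoscopy.

About 25% of screening colonoscopies are performed on an inadequately
prepped colon, where adenoma miss rates reach 42–48% and the recommended
repeat exam often never happens. An intra-procedural cleansing device,
deployed during the exam in that inadequately prepped quarter of patients
at an additional $750 per procedure, salvages ~95% of those exams.
`prepcea` asks whether paying for the device saves money and health over
the remaining lifetime of an average-risk 60-year-old screening cohort,
under Medicare and private reimbursement.

The package is aimed at health-economics analysts: it provides a complete,
scriptable Markov cohort engine plus the surrounding apparatus of a
cost-utility analysis, with a patient-level microsimulation twin used as
an independent validation oracle.

## The model in brief

A time-inhomogeneous nine-state Markov chain (states: compliant screening,
lapsed post-colonoscopy, never-screened, adenoma surveillance, early CRC,
advanced CRC, remission, CRC death, other death) with a 1-year cycle over
a 24-year horizon. Screening colonoscopy occurs every 10 years with 60%
per-opportunity compliance; the within-stage episode tree covers prep
adequacy (25% inadequate under standard of care vs a 5% residual among
device-assisted exams), repeat exams after prep failure, adenoma detection
and polypectomy with routing to 3-yearly surveillance, complications, and
lapse from the programme. Adenoma carriage is tracked as a mean-field
carrier fraction within each state; carriers progress to cancer, with the
canonical screening stage shift: progression inside the programme is
diagnosed early, progression outside it presents as advanced disease.

Lifetime discounted (3%/year) costs and QALYs per arm feed the standard
incremental statistics

- ICER = ΔC / ΔE,
- incremental net benefit INB(λ) = λ·ΔE − ΔC,

plus dominance classification, one-way sensitivity sweeps, bisection
threshold analysis, and Monte-Carlo probabilistic sensitivity analysis
with the 0.1% running-mean-ICER stopping rule.

Headline published inputs (compliance, prep rates, device price and
salvage rate, discounting, the 1.63–2.48 private multiplier range, life
expectancies) ship as defaults; supplementary-level inputs are documented
placeholder values with a small calibrated set — see the methods vignette
(`vignettes/model-methods.Rmd`) for the calibration and its caveats.

## Worked example

```r
library(prepcea)

params <- default_parameters("medicare")
soc <- run_arm(params, "soc")
dev <- run_arm(params, "purevu")
soc
#> <arm_result> soc/medicare: $6929 / 15.16 QALYs ($457/QALY)
#>   cumulative incidence: early CRC 6.83%, advanced CRC 13.12%
dev
#> <arm_result> purevu/medicare: $6047 / 15.19 QALYs ($398/QALY)
#>   cumulative incidence: early CRC 5.72%, advanced CRC 12.93%

compare_arms(dev, soc)
#> <icer_result> dCost $-882.17, dQALY 0.0309
#>   ICER $-28560/QALY; intervention_dominates
```

The device arm costs $882 less per patient over the cohort's remaining
lifetime and yields slightly more QALYs, so it dominates: no willingness-
to-pay judgement is needed. The `$457/QALY` and `$398/QALY` parentheticals
are the per-arm average cost/QALY ratios used in the reporting tables,
distinct from the ICER. The early-CRC incidence difference (6.83% vs
5.72%, a 1.1-point gap) is what carries most of the saving: missed
adenomas in poorly prepped, unrepeated exams progress to costly disease.

Threshold analysis locates the device price at which standard of care
becomes the cheaper option:

```r
find_threshold(default_parameters("private"), "cost_purevu_device",
               c(0, 5000), tol = 1, payer = "private")
#> <threshold_result> cost_purevu_device = 1753.23 (private; bracket [1752.93, 1753.54], tol 1)
```

Probabilistic sensitivity analysis, one-way sweeps, the propensity-score
tooling and the microsimulation oracle follow the same pattern; see
`?run_psa`, `?one_way_sweep`, `?fit_logistic`, `?simulate_patients`, and
the report drivers `?report_base_case` and friends (a thin command-line
wrapper lives in `inst/cli/prepcea.R`).

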