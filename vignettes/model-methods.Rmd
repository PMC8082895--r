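---
title: "A lifetime Markov model of intra-procedural bowel-prep rescue in screening colonoscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime Markov model of intra-procedural bowel-prep rescue in screening colonoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prepcea)
```

## The decision problem

Roughly a quarter of screening colonoscopies are performed on an
inadequately prepped colon. A poor prep raises the adenoma miss rate
substantially (miss rates of 42–48% are reported for poorly prepped
colons), and the recommended remedy — a repeat colonoscopy — happens for
only part of these patients, costs a second procedure, and often fails
prep again. An intra-procedural cleansing device offers an alternative:
deployed during the exam in the inadequately prepped quarter of patients,
it salvages about 95% of those exams at an additional per-procedure cost
of $750.

`prepcea` implements a lifetime cost-utility comparison of the two
strategies for an average-risk cohort entering screening at age 60, priced
at Medicare and at private reimbursement. Outcomes are lifetime discounted
costs, quality-adjusted life years (QALYs), and the cumulative incidence
of early and advanced colorectal cancer (CRC).

## Model structure

The cohort engine is a time-inhomogeneous Markov chain over nine states
(see `health_states()`), with a one-year cycle over a 24-year horizon —
the remaining life expectancy of the average-risk 60-year-old that the
cohort represents:

* `COMPLIANT_SCREENING` — engaged with the decennial screening programme;
* `NONCOMPLIANT_POST_COLONOSCOPY` — screened at least once, then lapsed;
* `NONCOMPLIANT_WITH_SYSTEM` — never engages with screening;
* `ADENOMA_SURVEILLANCE` — post-polypectomy surveillance at a 3-year
  colonoscopy interval;
* `EARLY_CRC`, `ADVANCED_CRC`, `REMISSION` — cancer states;
* `DEATH_CRC`, `DEATH_OTHER` — absorbing.

At entry the cohort splits by the screening compliance rate (base 60%)
into engaged screeners, who have their first colonoscopy at stage 0, and
never-screeners. Later screening rounds (stages 10 and 20) are attended
with the same per-opportunity compliance. Cycle length is one year; no
half-cycle correction is applied (a documented switch,
`half_cycle_correction`, enables the conventional correction), and
outcomes accrued in cycle *t* are discounted by $(1+r)^{-t}$ at $r = 3\%$.

### The screening episode

At a screening stage, an attending patient's episode unfolds as a small
decision tree:

1. **Prep adequacy.** Under standard of care 25% of exams present
   inadequately prepped. In the device arm the device is deployed in
   exactly that quarter of exams (`device_use_fraction = 0.25`) and fails
   to salvage 5% of them, so only $0.25 \times 0.05 = 1.25\%$ of episodes
   remain inadequate.
2. **Repeat exam.** An inadequate exam is repeated with a probability
   coupled to screening compliance: repeat attendance equals
   `p_repeat_uptake` × compliance, anchored so that the base case
   reproduces the published 55–60% repeat rate (0.575 at 60% compliance).
   The repeat of a previously failed prep fails again at an elevated rate
   (`p_inadequate_repeat = 0.55`), reflecting the persistence of the
   patient-level causes of poor preparation.
3. **Detection.** Adequate (or salvaged) exams detect a prevalent adenoma
   with sensitivity 0.97; inadequately prepped exams with sensitivity
   0.52 (a 48% miss rate). Detected adenomas are removed (polypectomy)
   and the patient moves to `ADENOMA_SURVEILLANCE` for life, with
   colonoscopy every 3 years at 85% surveillance compliance.
4. **Lapse.** A patient whose inadequate exam is never repeated abandons
   the programme with probability `p_lapse_after_inadequate = 0.10`,
   moving to `NONCOMPLIANT_POST_COLONOSCOPY`.
5. **Complications** occur per exam at 0.5% and are costed but do not
   change state.

### Natural history and the stage shift

Adenoma carriage is tracked as a deterministic *carrier fraction* inside
each alive non-cancer state (a mean-field sub-state): 30% of the cohort
carries an adenoma at entry, new adenomas arise at 0.2%/year (8%/year
post-polypectomy), and carriers progress to cancer at an annual rate of
15% (`p_progression_adenoma_to_early`, one of the calibrated parameters —
see below). Because the carrier composition of each state depends on the
cohort's screening history, the transition matrix is regenerated per stage
(`build_transition_matrix()`); the same matrices, carrier fractions, and
episode event probabilities drive both the cohort engine and the
microsimulation, which is what makes the two mutually consistent by
construction.

Progressing cancers are *stage-shifted* by screening engagement: carriers
progressing while in an engaged state (`COMPLIANT_SCREENING`,
`ADENOMA_SURVEILLANCE`) are diagnosed as `EARLY_CRC`, whereas carriers
progressing outside the programme (`NONCOMPLIANT_*`) present
symptomatically as `ADVANCED_CRC`. This is the canonical screening
stage-shift mechanism, and it is what makes the early-CRC incidence gap
between the arms an engaged-cohort phenomenon, consistent with reading
the published "1.1% and 0.2% lower absolute incidence rates" as early and
advanced differences respectively.

Early cancer resolves to remission at 30%/year, progresses to advanced
disease at 2.5%/year, and carries a small direct cancer mortality;
advanced disease is not curable in-model and its total mortality is set
by the published 4.8-year life expectancy ($1/4.8$ per year). Other-cause
mortality is a constant 0.2%/year. We deliberately did **not** use a
$1/24$ annual hazard for other-cause death: with such a hazard the
discounted QALY ceiling over a 24-year horizon is about 11.8, far below
the published 15.10–15.25 QALYs, which are only attainable when the
horizon itself represents the life expectancy and within-horizon
competing mortality is small. This understates real competing mortality
at ages 60–84 and is flagged as a limitation.

## Costs and payers

All costs are 2019 USD on the Medicare reference scale: diagnostic
colonoscopy $380, physician fee $140, polypectomy increment $250,
complication $8,000, device add-on $750. Private reimbursement multiplies
*colonoscopy services* — including the device add-on, which is treated as
a reimbursed procedure add-on rather than a flat list price — by the
midpoint (2.055) of the published 1.63–2.48 range. Cancer-treatment
streams (early $36,993/year while in `EARLY_CRC`, advanced $1,573/year,
remission follow-up $800/year) come from the all-payer literature and
receive their own, much smaller private uplift
(`cancer_cost_multiplier = 1.1835`), consistent with commercial oncology
reimbursement running moderately above Medicare.

Treating the device as payer-multiplied is a deliberate design choice:
the published per-patient savings ($833 Medicare, $992 private), the
Medicare/private cost ratios, and the $1,753 device-price threshold are
mutually consistent only when the saving-versus-price slope is
$0.25 \times E[\text{discounted exams}] \times \text{multiplier}$.

## Calibration

The published article prints the headline inputs (compliance, prep rates,
device price and salvage rate, discount rate, payer-multiplier range,
life expectancies, sex mix) but leaves detection, natural-history, cost
and utility inputs to supplementary appendices that are not part of the
main text. Those inputs ship here as *supplementary-sourced* defaults:
plausible values fixed at realistic 2019 levels, plus a small set of free
parameters calibrated against the published outputs. Because total cost
is linear in every cost input, the calibration reduces to a linear system:
the adenoma-to-cancer progression rate was tuned so the early-CRC
incidence gap reproduces the printed 1.1 percentage points, and the two
cancer-cost streams plus the private cancer uplift were then solved so
that the four published cost cells and the device-price threshold are
met simultaneously. The shipped defaults reproduce:

| quantity | published | model |
|---|---|---|
| SOC Medicare cost / QALYs | $6,903 / 15.10 | $6,929 / 15.16 |
| Device-arm Medicare cost / QALYs | $6,070 / 15.25 | $6,047 / 15.19 |
| SOC private cost | $9,208 | $9,130 |
| Device-arm private cost | $8,216 | $8,285 |
| Early / advanced CRC incidence gap | 1.1 / 0.2 pp | 1.11 / 0.19 pp |
| Device-price threshold (private) | $1,753 | $1,753 |

Two honest caveats. First, the fitted advanced-CRC annual cost
($1,573/year) is implausibly low for real advanced-cancer care; it is a
structural compression caused by reproducing the printed lifetime cost
levels, under which the savings are carried almost entirely by
early-stage treatment costs. Second, the model's per-patient savings
($882 Medicare, $845 private) bracket neither printed saving exactly;
they are the values implied by cost cells that each sit within 1% of the
printed ones.

## Threshold analyses

`find_threshold()` brackets the sign change of the deterministic lifetime
cost difference (standard of care minus device arm) and bisects to a
configurable resolution ($1 for prices, 0.5 percentage points for
probabilities; ties are reported at the equality point). The cost
difference is exactly affine in the device price, so the bisection result
can be cross-checked against a two-point analytic solution — the test
suite does this. At the shipped configuration the device arm stops being
cheaper when its price exceeds $1,753 at private rates ($2,902 at
Medicare rates).

For screening compliance the published threshold (standard of care
cheaper at compliance ≤ 28%) is **not reproducible**: in this model the
cost difference favours the device arm over the entire compliance range,
under both payers and under both the raw-cost and cost-per-QALY
predicates. The published compliance table itself shows savings rising
monotonically from $338 at 20% compliance to $1,316 at 80%, which
extrapolates to a zero crossing near 0% compliance, not 28%. Every
between-arm difference in a cohort model of this family scales with
attendance, so a sign change at an interior compliance level cannot
arise; `find_threshold()` therefore reports "no crossing" on this
configuration, and we regard the published 28% figure as inconsistent
with the published base-case tables.

## Probabilistic sensitivity analysis

`run_psa()` samples each parameter that carries a distribution (beta for
probabilities and utilities, gamma for costs, uniform where only a range
is published — e.g. the 1.63–2.48 payer multiplier), runs **both arms on
the same draw**, and monitors the running mean of the per-draw ICER. The
run is declared converged at the first draw after which the relative
change of the running mean stays at or below 0.1% for 100 consecutive
draws; the window is our choice, since the source analysis states the
0.1% rule but not its cadence. Draws with $|\Delta QALY| < 10^{-9}$ are
excluded from the ICER mean (the count is reported); the incremental net
benefit at $50,000/QALY, which is always defined, is the primary summary.
Parameter draws are independent across fields (no correlation evidence is
available), draws are clipped to their supports by rejection, and a
single seeded generator makes runs byte-for-byte reproducible. At the
shipped distributions the rule is typically met within a few hundred
draws — the same order as the published 1,728 — and the net benefit is
positive in essentially all draws.

## The microsimulation oracle and the synthetic study generator

`simulate_patients()` is the Monte-Carlo twin of the cohort engine:
patients are walked through the same stage-dependent matrices, with the
within-stage episode resolved event by event (attendance, prep, device,
repeat, detection, complication, lapse), and carrier status re-drawn each
year from the state's carrier fraction, exactly as the mean-field cohort
assumes. Consequently the cohort trace is the exact expectation of the
per-patient state frequencies, and per-patient discounted cost and QALY
means estimate the cohort totals unbiasedly — which the test suite checks
at up to 100,000 patients with simultaneous 4-standard-error bounds. What
the microsimulation deliberately does *not* add is individual-level
heterogeneity beyond the model's own stochastic structure (no persistent
frailty, no correlated attendance behaviour), so oracle agreement
validates the engine's bookkeeping, not the realism of the natural
history.

`generate_study()` emulates the colonoscopy-outcome study data behind the
propensity analysis: age, sex, device allocation, cecal intubation, and a
completion outcome drawn from a logistic model with configurable
coefficients. It exists to validate the logistic machinery by parameter
recovery; it makes no attempt to re-create the patient-level data of any
actual study.

## Propensity scoring and matching

The source analysis fits one logistic model (successful colonoscopy on
age, sex, device use and cecal intubation) and speaks of propensity for
arm assignment; `fit_logistic()` serves both uses — the outcome model is
reported with Wald tests, and a treatment model (device use on age and
sex) produces the scores. Matching is greedy 1:1 nearest-neighbour on the
logit of the score, treated units processed in descending score order for
determinism, controls used without replacement, within a caliper
defaulting to 0.2 SD of the pooled logit scores (the common convention).
Greedy matching is compared against a brute-force optimal-assignment
oracle on small instances in the tests. Balance is reported as
standardized mean differences over the matched units; a zero pooled SD is
reported as SMD 0 with a degenerate flag.

## Numerical conventions and test problem sizes

Transition-row conservation is enforced at $10^{-12}$ and cohort-trace
conservation at $10^{-9}$; a negative residual branch probability raises
a configuration error rather than being clipped silently. Reported tables
round dollars to integers and QALYs to two decimals, but rounding never
feeds back into computation. The default test runs use 2,000–20,000
simulated patients and 2,000 PSA draws, with the closed-form geometric
toy checked to $10^{-12}$; these sizes were chosen to keep routine runs
fast while leaving Monte-Carlo tolerances (3–4 standard errors) sharp
enough to catch real bookkeeping errors.

## Known limitations

* Other-cause mortality is understated (see above), a compromise forced
  by the published QALY levels.
* The advanced-CRC cost stream is compressed by calibration; absolute
  advanced-disease cost projections from this model should not be used.
* The published 28% compliance threshold is unreproducible and is
  reported as such.
* Carrier composition is tracked mean-field; the entering carrier
  fraction of the lapsed state approximates flow mixing exactly, but the
  never-screened and lapsed pools share one incidence parameter.
* No age- or sex-specific life tables, no tunnel states, no correlation
  structure in the PSA.
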