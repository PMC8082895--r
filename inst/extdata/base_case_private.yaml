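p_compliance_screening: 0.6
p_inadequate_prep_soc: 0.25
p_inadequate_prep_purevu: 0.05
p_repeat_after_inadequate: 0.575
p_repeat_uptake: 0.958333333333333
p_inadequate_repeat: 0.55
p_lapse_after_inadequate: 0.1
p_surveillance_compliance: 0.85
screening_interval_years: 10
surveillance_interval_years: 3
sens_adequate: 0.97
spec_adequate: 1.0
sens_inadequate: 0.52
p_complication: 0.005
p_adenoma_prevalence: 0.3
p_adenoma_incidence: 0.002
p_adenoma_recurrence: 0.05
p_progression_adenoma_to_early: 0.15
p_progression_early_to_advanced: 0.025
p_remission_early: 0.3
p_death_early_crc: 0.004
p_death_other: 0.002
life_expectancy_no_crc: 24.0
life_expectancy_early_crc: 23.0
life_expectancy_advanced_crc: 4.8
cost_colonoscopy_dx: 380.0
cost_physician: 140.0
cost_colonoscopy_polypectomy: 250.0
cost_complication: 8000.0
cost_early_crc_annual: 36993.0
cost_advanced_crc_annual: 1573.0
cost_remission_annual: 800.0
cost_purevu_device: 750.0
payer: private
payer_multiplier: 2.055
cancer_cost_multiplier: 1.1835
utility_by_state:
  COMPLIANT_SCREENING: 0.96
  NONCOMPLIANT_POST_COLONOSCOPY: 0.96
  NONCOMPLIANT_WITH_SYSTEM: 0.96
  ADENOMA_SURVEILLANCE: 0.96
  EARLY_CRC: 0.74
  ADVANCED_CRC: 0.5
  REMISSION: 0.88
  DEATH_CRC: 0.0
  DEATH_OTHER: 0.0
discount_rate: 0.03
start_age: 60.0
sex_mix: 0.54
horizon_years: 24
half_cycle_correction: no
device_payer_multiplied: yes
psa_distributions:
  p_compliance_screening:
    kind: beta
    params:
      shape1: 36.0
      shape2: 24.0
    support:
    - 0.0
    - 1.0
  p_inadequate_prep_soc:
    kind: beta
    params:
      shape1: 25.0
      shape2: 75.0
    support:
    - 0.0
    - 1.0
  p_inadequate_prep_purevu:
    kind: beta
    params:
      shape1: 5.0
      shape2: 95.0
    support:
    - 0.0
    - 1.0
  p_repeat_after_inadequate:
    kind: uniform
    params:
      min: 0.55
      max: 0.6
    support:
    - 0.0
    - 1.0
  sens_inadequate:
    kind: uniform
    params:
      min: 0.52
      max: 0.58
    support:
    - 0.0
    - 1.0
  sens_adequate:
    kind: beta
    params:
      shape1: 97.0
      shape2: 3.000000000000003
    support:
    - 0.0
    - 1.0
  p_complication:
    kind: beta
    params:
      shape1: 10.0
      shape2: 1990.0
    support:
    - 0.0
    - 1.0
  p_adenoma_prevalence:
    kind: uniform
    params:
      min: 0.2
      max: 0.3
    support:
    - 0.0
    - 1.0
  p_progression_adenoma_to_early:
    kind: beta
    params:
      shape1: 60.0
      shape2: 340.0
    support:
    - 0.0
    - 1.0
  p_progression_early_to_advanced:
    kind: beta
    params:
      shape1: 5.0
      shape2: 195.0
    support:
    - 0.0
    - 1.0
  cost_colonoscopy_dx:
    kind: gamma
    params:
      shape: 44.444444444444443
      scale: 8.550000000000001
    support:
    - 0.0
    - .inf
  cost_physician:
    kind: gamma
    params:
      shape: 44.444444444444443
      scale: 3.15
    support:
    - 0.0
    - .inf
  cost_complication:
    kind: gamma
    params:
      shape: 44.444444444444443
      scale: 180.0
    support:
    - 0.0
    - .inf
  cost_early_crc_annual:
    kind: gamma
    params:
      shape: 44.444444444444443
      scale: 832.342500000000086
    support:
    - 0.0
    - .inf
  cost_advanced_crc_annual:
    kind: gamma
    params:
      shape: 44.444444444444443
      scale: 35.392499999999998
    support:
    - 0.0
    - .inf
  payer_multiplier:
    kind: uniform
    params:
      min: 1.63
      max: 2.48
    support:
    - 1.0
    - .inf
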