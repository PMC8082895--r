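test_that("discount factors follow the end-of-cycle convention", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0, 17), 1)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03)
  expect_equal(discount_factor(0.03, 0:3), (1 / 1.03)^(0:3))
  expect_error(discount_factor(0.03, -1), "non-negative")
  expect_error(discount_factor(-0.01, 1), "non-negative")
})

test_that("two-state geometric toy matches the closed form to 1e-12", {
  p <- toy_two_state_params()
  tr <- run_cohort(p, make_strategy("soc", "medicare", p))
  expect_equal(sum(tr$discounted_qaly), sum(0.9^(0:23)), tolerance = 1e-12)
  expect_equal(sum(tr$discounted_cost), 0)
  # occupancy of the alive state decays geometrically
  expect_equal(tr$occupancy[, "COMPLIANT_SCREENING"], 0.9^(0:23),
               tolerance = 1e-12)
})

test_that("a cohort started in an absorbing state accrues nothing", {
  p <- default_parameters()
  init <- stats::setNames(numeric(9), health_states())
  init["DEATH_OTHER"] <- 1
  tr <- run_cohort(p, make_strategy("soc", "medicare", p),
                   initial_occupancy = init)
  expect_equal(sum(tr$cycle_cost), 0)
  expect_equal(sum(tr$cycle_qaly), 0)
  expect_true(all(tr$occupancy[, "DEATH_OTHER"] == 1))
})

test_that("conservation and absorbing monotonicity hold for random valid parameters", {
  set.seed(421)
  for (k in 1:12) {
    p <- random_valid_params()
    for (arm in c("soc", "purevu")) {
      s <- make_strategy(arm, "medicare", p)
      tr <- run_cohort(p, s)
      expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
      expect_true(all(tr$occupancy >= -1e-12))
      for (st in absorbing_states()) {
        expect_true(all(diff(tr$occupancy[, st]) >= -1e-12))
      }
      # spot-check transition rows at three stages
      for (stg in unique(c(0L, p$horizon_years %/% 2L,
                           p$horizon_years - 1L))) {
        P <- build_transition_matrix(p, s, stg)
        expect_true(all(abs(rowSums(P) - 1) < 1e-12))
        expect_true(all(P >= 0 & P <= 1))
        for (st in absorbing_states()) expect_equal(unname(P[st, st]), 1)
      }
    }
  }
})

test_that("discounting never increases totals and vanishes at rate zero", {
  set.seed(99)
  for (k in 1:5) {
    p <- random_valid_params()
    p$discount_rate <- stats::runif(1, 0.01, 0.08)
    s <- make_strategy("purevu", "medicare", p)
    tr <- run_cohort(p, s)
    expect_lt(sum(tr$discounted_cost), sum(tr$cycle_cost) + 1e-9)
    expect_lt(sum(tr$discounted_qaly), sum(tr$cycle_qaly))
    p0 <- p
    p0$discount_rate <- 0
    tr0 <- run_cohort(p0, s)
    expect_equal(sum(tr0$discounted_cost), sum(tr0$cycle_cost))
    res <- accrue_outcomes(tr0, p0, s)
    expect_equal(res$total_cost, sum(tr0$cycle_cost))
    expect_equal(res$total_qaly, sum(tr0$cycle_qaly))
  }
})

test_that("cumulative incidence books inflows and rejects non-cancer states", {
  # never-screeners with full adenoma carriage: advanced incidence has a
  # geometric closed form occ_t = ((1-p_do)(1-p_a2e))^t
  p <- toy_two_state_params(p_death = 0.02)
  p$p_compliance_screening <- 0
  p$p_adenoma_prevalence <- 1
  p$p_progression_adenoma_to_early <- 0.05
  s <- make_strategy("soc", "medicare", p)
  tr <- run_cohort(p, s)
  surv <- (1 - 0.02) * (1 - 0.05)
  expected <- sum(surv^(0:23) * (1 - 0.02) * 0.05)
  expect_equal(cumulative_incidence(tr, "ADVANCED_CRC"), expected,
               tolerance = 1e-10)
  expect_equal(cumulative_incidence(tr, "EARLY_CRC"), 0)
  expect_error(cumulative_incidence(tr, "REMISSION"), "CRC states")
})

test_that("cohort accrual matches the occupancy-weighted cost vectors", {
  p <- default_parameters()
  s <- make_strategy("purevu", "medicare", p)
  tr <- run_cohort(p, s)
  res <- accrue_outcomes(tr, p, s)
  expect_equal(res$total_cost, sum(tr$discounted_cost), tolerance = 1e-9)
  expect_equal(res$total_qaly, sum(tr$discounted_qaly), tolerance = 1e-9)
  expect_equal(res$cost_per_qaly, res$total_cost / res$total_qaly)
  expect_gte(res$cum_incidence_early_crc, 0)
  expect_lte(res$cum_incidence_early_crc, 1)
})

test_that("transition builder rejects invalid stages", {
  p <- default_parameters()
  s <- make_strategy("soc", "medicare", p)
  expect_error(build_transition_matrix(p, s, -1), "non-negative")
  expect_error(build_transition_matrix(p, s, p$horizon_years), "horizon")
})

test_that("trace export has one row per stage with the expected columns", {
  p <- toy_two_state_params(horizon = 6)
  tab <- trace_table(run_cohort(p, make_strategy("soc", "medicare", p)))
  expect_equal(nrow(tab), 6)
  expect_true(all(c("stage", health_states(), "cycle_cost",
                    "discounted_qaly") %in% names(tab)))
})
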