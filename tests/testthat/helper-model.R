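# Shared fixtures, built in code.

# Two-state geometric toy: everyone starts compliant, dies at 10%/year,
# utility 1, no screening effects, no costs, no discounting. The discounted
# QALY total has the closed form sum_{t=0}^{H-1} 0.9^t.
toy_two_state_params <- function(horizon = 24L, p_death = 0.1,
                                 discount = 0) {
  p <- default_parameters("medicare")
  p$p_compliance_screening <- 1
  p$p_adenoma_prevalence <- 0
  p$p_adenoma_incidence <- 0
  p$p_adenoma_recurrence <- 0
  p$p_lapse_after_inadequate <- 0
  p$p_progression_early_to_advanced <- 0
  p$p_remission_early <- 0
  p$p_death_early_crc <- 0
  p$p_death_other <- p_death
  p$discount_rate <- discount
  p$horizon_years <- as.integer(horizon)
  for (f in c("cost_colonoscopy_dx", "cost_physician",
              "cost_colonoscopy_polypectomy", "cost_complication",
              "cost_early_crc_annual", "cost_advanced_crc_annual",
              "cost_remission_annual", "cost_purevu_device"))
    p[[f]] <- 0
  u <- as.list(stats::setNames(rep(0, 9), health_states()))
  u$COMPLIANT_SCREENING <- 1
  p$utility_by_state <- u
  p$psa_distributions <- list()
  p
}

# A random valid parameter set drawn from safe ranges.
random_valid_params <- function() {
  p <- default_parameters("medicare")
  r <- function(lo, hi) stats::runif(1, lo, hi)
  p$p_compliance_screening <- r(0.1, 0.95)
  p$p_inadequate_prep_soc <- r(0.05, 0.5)
  p$p_inadequate_prep_purevu <- r(0.01, 0.2)
  p$p_repeat_after_inadequate <- r(0.2, 0.9)
  p$p_repeat_uptake <- r(0.3, 1)
  p$p_inadequate_repeat <- r(0, 0.8)
  p$p_lapse_after_inadequate <- r(0, 1)
  p$p_surveillance_compliance <- r(0.2, 1)
  p$sens_adequate <- r(0.7, 1)
  p$sens_inadequate <- r(0.2, 0.7)
  p$p_complication <- r(0, 0.05)
  p$p_adenoma_prevalence <- r(0.05, 0.5)
  p$p_adenoma_incidence <- r(0, 0.05)
  p$p_adenoma_recurrence <- r(0, 0.3)
  p$p_progression_adenoma_to_early <- r(0.005, 0.3)
  p$p_progression_early_to_advanced <- r(0.01, 0.3)
  p$p_remission_early <- r(0.05, 0.5)
  p$p_death_early_crc <- r(0, 0.05)
  p$p_death_other <- r(0, 0.1)
  p$discount_rate <- r(0, 0.08)
  p$horizon_years <- sample(5:30, 1)
  p$psa_distributions <- list()
  stopifnot(is_valid(validate_parameters(p)))
  p
}

# Brute-force 1:1 matching oracle for tiny instances: enumerates every
# assignment of treated units to distinct controls within the caliper and
# returns the maximum pair count and, among those, the minimum total
# distance.
match_oracle <- function(lt, lc, caliper) {
  n_t <- length(lt)
  best <- list(pairs = 0L, dist = Inf)
  recurse <- function(i, used, npair, dist) {
    if (i > n_t) {
      if (npair > best$pairs ||
          (npair == best$pairs && dist < best$dist)) {
        best <<- list(pairs = npair, dist = dist)
      }
      return(invisible())
    }
    recurse(i + 1L, used, npair, dist)  # leave treated i unmatched
    for (j in seq_along(lc)) {
      if (!used[j] && abs(lt[i] - lc[j]) <= caliper) {
        used[j] <- TRUE
        recurse(i + 1L, used, npair + 1L, dist + abs(lt[i] - lc[j]))
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(lc)), 0L, 0)
  best
}
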