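#' Present-value discount factor
#'
#' End-of-cycle discounting convention: outcomes accrued in cycle `t` are
#' multiplied by `(1 + rate)^-t`, so the entry cycle (`t = 0`) is
#' undiscounted.
#'
#' @param rate Annual discount rate, non-negative (base case 0.03).
#' @param t Stage index (years from model entry), non-negative.
#' @return `(1 + rate)^-t`, in `(0, 1]`.
#' @export
#' @examples
#' discount_factor(0.03, 1)
discount_factor <- function(rate, t) {
  if (any(rate < 0)) stop("discount rate must be non-negative", call. = FALSE)
  if (any(t < 0)) stop("stage index must be non-negative", call. = FALSE)
  (1 + rate)^(-t)
}

# ---------------------------------------------------------------------------
# Internal single-pass model builder.
#
# The nine observable states are augmented by a deterministic "adenoma
# carrier" fraction tracked within each alive non-cancer state (mean-field
# sub-state): carriers progress to EARLY_CRC at the annual adenoma-to-cancer
# rate, are cleared by polypectomy when detected at a colonoscopy, and are
# replenished by adenoma incidence (recurrence in the surveillance state).
# Because carrier composition depends on the cohort's screening history, the
# stage-t transition matrix is computed by running the cohort recursion from
# stage 0; the pass below produces, for every stage, the transition matrix,
# the per-occupant cost vector, and the carrier fractions, all of which are
# shared verbatim by the cohort engine and the microsimulation oracle.
# ---------------------------------------------------------------------------
.arm_model <- function(params, strategy, initial_occupancy = NULL) {
  H <- as.integer(params$horizon_years)
  states <- health_states()
  S <- length(states)
  i <- function(nm) match(nm, states)
  CS <- i("COMPLIANT_SCREENING"); NPC <- i("NONCOMPLIANT_POST_COLONOSCOPY")
  NWS <- i("NONCOMPLIANT_WITH_SYSTEM"); AS <- i("ADENOMA_SURVEILLANCE")
  EC <- i("EARLY_CRC"); AC <- i("ADVANCED_CRC"); REM <- i("REMISSION")
  DCRC <- i("DEATH_CRC"); DOTH <- i("DEATH_OTHER")

  p_do <- params$p_death_other
  p_a2e <- params$p_progression_adenoma_to_early
  p_e2a <- params$p_progression_early_to_advanced
  p_rem <- params$p_remission_early
  p_dec <- params$p_death_early_crc
  p_dac <- max(0, 1 / params$life_expectancy_advanced_crc - p_do)
  s_in <- params$sens_inadequate
  q <- .effective_inadequate(strategy)
  rep_p <- .effective_repeat(params)
  p_lapse <- params$p_lapse_after_inadequate
  d_scr <- .detection_prob(params, strategy, p_repeat = rep_p)
  d_surv <- d_scr  # inadequate surveillance exams are repeated the same way
  f_surv <- params$p_surveillance_compliance / params$surveillance_interval_years
  p_inc <- params$p_adenoma_incidence
  p_rec <- params$p_adenoma_recurrence
  c_scr <- params$p_compliance_screening
  interval <- params$screening_interval_years

  u <- unlist(params$utility_by_state[states])

  # per-occupant annual cost of the cancer states (literature treatment
  # costs; the payer multiplier applies to colonoscopy services only)
  mk <- params$cancer_cost_multiplier
  cost_state_base <- numeric(S)
  cost_state_base[EC] <- mk * params$cost_early_crc_annual
  cost_state_base[AC] <- mk * params$cost_advanced_crc_annual
  cost_state_base[REM] <- mk * params$cost_remission_annual

  if (is.null(initial_occupancy)) {
    occ <- numeric(S)
    occ[CS] <- c_scr
    occ[NWS] <- 1 - c_scr
  } else {
    stopifnot(length(initial_occupancy) == S)
    if (!is.null(names(initial_occupancy)))
      initial_occupancy <- initial_occupancy[states]
    occ <- as.numeric(initial_occupancy)
    if (abs(sum(occ) - 1) > 1e-9 || any(occ < 0))
      stop("initial occupancy must be a probability vector over the states",
           call. = FALSE)
  }
  carrier <- numeric(S)  # carrier occupancy mass within CS/NPC/NWS/AS
  carrier[c(CS, NPC, NWS)] <- occ[c(CS, NPC, NWS)] * params$p_adenoma_prevalence

  transitions <- array(0, dim = c(H, S, S),
                       dimnames = list(NULL, states, states))
  costs <- matrix(0, H, S, dimnames = list(NULL, states))
  occupancy <- matrix(0, H, S, dimnames = list(NULL, states))
  carrier_frac <- matrix(0, H, 4,
                         dimnames = list(NULL, states[c(CS, NPC, NWS, AS)]))
  attend <- numeric(H)

  frac <- function(mass, total) if (total > 1e-300) mass / total else 0

  for (t in seq_len(H) - 1L) {
    a_cs <- frac(carrier[CS], occ[CS])
    a_npc <- frac(carrier[NPC], occ[NPC])
    a_nws <- frac(carrier[NWS], occ[NWS])
    a_as <- frac(carrier[AS], occ[AS])

    # everyone entering CS does so by attending the entry screen; later
    # rounds are attended with the per-opportunity compliance rate
    screening_stage <- (t %% interval) == 0
    att <- if (!screening_stage) 0 else if (t == 0) 1 else c_scr

    P <- matrix(0, S, S)
    P[DCRC, DCRC] <- 1
    P[DOTH, DOTH] <- 1

    # --- COMPLIANT_SCREENING ------------------------------------------------
    lapse_n <- att * q * (1 - rep_p) * p_lapse              # non-carrier
    lapse_c <- att * q * (1 - rep_p) * (1 - s_in) * p_lapse # undetected carrier
    det_c <- att * d_scr
    stay_c <- 1 - det_c - lapse_c
    P[CS, DOTH] <- p_do
    P[CS, AS] <- (1 - p_do) * a_cs * det_c
    P[CS, NPC] <- (1 - p_do) * (a_cs * lapse_c + (1 - a_cs) * lapse_n)
    P[CS, EC] <- (1 - p_do) * a_cs * stay_c * p_a2e
    P[CS, CS] <- 1 - sum(P[CS, -CS])

    # --- NONCOMPLIANT states (natural history only) ------------------------
    # cancers in patients outside the screening programme present late:
    # adenoma progression routes directly to advanced disease (stage shift)
    for (st in c(NPC, NWS)) {
      a <- if (st == NPC) a_npc else a_nws
      P[st, DOTH] <- p_do
      P[st, AC] <- (1 - p_do) * a * p_a2e
      P[st, st] <- 1 - sum(P[st, -st])
    }

    # --- ADENOMA_SURVEILLANCE ----------------------------------------------
    clear_p <- f_surv * d_surv
    P[AS, DOTH] <- p_do
    P[AS, EC] <- (1 - p_do) * a_as * (1 - clear_p) * p_a2e
    P[AS, AS] <- 1 - sum(P[AS, -AS])

    # --- cancer states ------------------------------------------------------
    P[EC, DOTH] <- p_do
    P[EC, DCRC] <- p_dec
    P[EC, AC] <- p_e2a
    P[EC, REM] <- p_rem
    P[EC, EC] <- 1 - sum(P[EC, -EC])
    P[AC, DOTH] <- p_do
    P[AC, DCRC] <- p_dac
    P[AC, AC] <- 1 - sum(P[AC, -AC])
    P[REM, DOTH] <- p_do
    P[REM, REM] <- 1 - sum(P[REM, -REM])

    if (any(P < -1e-12)) {
      stop("negative residual transition probability; parameter set is ",
           "internally inconsistent", call. = FALSE)
    }
    P[P < 0] <- 0

    # --- per-occupant costs -------------------------------------------------
    cost_t <- cost_state_base
    if (att > 0) {
      cost_t[CS] <- att * colonoscopy_episode_cost(
        params, strategy, p_polypectomy = a_cs * d_scr,
        p_repeat = rep_p)$expected_cost
    }
    cost_t[AS] <- f_surv * colonoscopy_episode_cost(
      params, strategy, p_polypectomy = a_as * d_surv,
      p_repeat = rep_p)$expected_cost

    transitions[t + 1L, , ] <- P
    costs[t + 1L, ] <- cost_t
    occupancy[t + 1L, ] <- occ
    carrier_frac[t + 1L, ] <- c(a_cs, a_npc, a_nws, a_as)
    attend[t + 1L] <- att

    # --- advance occupancy and carrier masses -------------------------------
    occ_next <- as.numeric(occ %*% P)

    cs_mass <- occ[CS]; npc_mass <- occ[NPC]; nws_mass <- occ[NWS]
    as_mass <- occ[AS]
    surv <- 1 - p_do

    # carriers staying put (undetected, unlapsed, not progressing)
    carr_cs_stay <- cs_mass * a_cs * surv * stay_c * (1 - p_a2e)
    carr_npc_stay <- npc_mass * a_npc * surv * (1 - p_a2e)
    carr_nws_stay <- nws_mass * a_nws * surv * (1 - p_a2e)
    carr_as_stay <- as_mass * a_as * surv * (1 - clear_p) * (1 - p_a2e)

    # non-carriers remaining in each state (new-adenoma pool)
    ncar_cs_stay <- cs_mass * (1 - a_cs) * surv * (1 - lapse_n)
    ncar_npc_stay <- npc_mass * (1 - a_npc) * surv
    ncar_nws_stay <- nws_mass * (1 - a_nws) * surv
    ncar_as_stay <- as_mass * ((1 - a_as) + a_as * clear_p) * surv

    # carrier flows between states: lapsing undetected carriers enter NPC;
    # detected carriers enter AS polypectomised, i.e. as non-carriers
    carr_into_npc <- cs_mass * a_cs * surv * lapse_c

    carrier_next <- numeric(S)
    carrier_next[CS] <- carr_cs_stay + ncar_cs_stay * p_inc
    carrier_next[NPC] <- carr_npc_stay + carr_into_npc +
      (ncar_npc_stay + cs_mass * (1 - a_cs) * surv * lapse_n) * p_inc
    carrier_next[NWS] <- carr_nws_stay + ncar_nws_stay * p_inc
    carrier_next[AS] <- carr_as_stay + ncar_as_stay * p_rec

    occ <- occ_next
    carrier <- carrier_next
  }

  list(
    states = states, horizon = H,
    transitions = transitions, costs = costs, utilities = u,
    occupancy = occupancy, carrier = carrier_frac, attend = attend,
    idx = list(CS = CS, NPC = NPC, NWS = NWS, AS = AS, EC = EC, AC = AC,
               REM = REM, DCRC = DCRC, DOTH = DOTH)
  )
}

#' Stage-specific transition matrix
#'
#' Builds the 9x9 one-year transition matrix of the cohort model at a given
#' stage. At screening stages (stage divisible by the screening interval)
#' the row of the compliant state embeds the colonoscopy decision tree —
#' attendance, prep adequacy under the strategy, within-episode repeat after
#' inadequate prep, adenoma detection with routing to surveillance, and
#' lapse to non-compliance after an unrepeated inadequate exam. In all other
#' stages only natural history and mortality apply. Because the adenoma
#' carrier composition of each state depends on the cohort's screening
#' history, the chain is time-inhomogeneous and the matrix is regenerated
#' per stage.
#'
#' @param params Validated parameter set.
#' @param strategy A `cea_strategy`.
#' @param stage Non-negative integer cycle index (years from entry), below
#'   the horizon.
#' @return A matrix with `health_states()` dimnames; every row sums to 1.
#' @export
#' @examples
#' P <- build_transition_matrix(default_parameters(), make_strategy("soc"), 0)
#' rowSums(P)
build_transition_matrix <- function(params, strategy, stage) {
  .assert_valid(params)
  if (stage < 0 || stage != round(stage))
    stop("stage must be a non-negative integer", call. = FALSE)
  if (stage >= params$horizon_years)
    stop("stage must be below horizon_years", call. = FALSE)
  model <- .arm_model(params, strategy)
  P <- model$transitions[stage + 1L, , ]
  dimnames(P) <- list(model$states, model$states)
  attr(P, "stage") <- as.integer(stage)
  P
}

#' Run the deterministic cohort simulation
#'
#' Propagates the cohort through the stage-dependent transition matrices for
#' the full horizon. At entry the cohort splits into compliant screeners and
#' never-screeners by the screening compliance rate; the entry colonoscopy
#' happens at stage 0 for the compliant.
#'
#' @param params Validated parameter set.
#' @param strategy A `cea_strategy`.
#' @param initial_occupancy Optional probability vector over
#'   [health_states()] overriding the default entry split (used for
#'   validation scenarios).
#' @return An object of class `cohort_trace`: list with `occupancy`
#'   (stage x state matrix, rows summing to 1), `cycle_cost` and
#'   `cycle_qaly` (undiscounted per-stage expectations), `discounted_cost`
#'   and `discounted_qaly`, `inflow_early` and `inflow_advanced` (per-stage
#'   new entrants into the cancer states), and `carrier` (per-stage adenoma
#'   carrier fractions).
#' @export
#' @examples
#' tr <- run_cohort(default_parameters(), make_strategy("soc"))
#' head(tr$occupancy[, 1:4])
run_cohort <- function(params, strategy, initial_occupancy = NULL) {
  .assert_valid(params)
  if (params$horizon_years < 1)
    stop("horizon_years must be at least 1", call. = FALSE)
  model <- .arm_model(params, strategy, initial_occupancy = initial_occupancy)
  H <- model$horizon
  EC <- model$idx$EC; AC <- model$idx$AC

  cycle_cost <- rowSums(model$occupancy * model$costs)
  cycle_qaly <- as.numeric(model$occupancy %*% model$utilities)

  inflow_early <- numeric(H)
  inflow_advanced <- numeric(H)
  for (t in seq_len(H)) {
    occ <- model$occupancy[t, ]
    P <- model$transitions[t, , ]
    inflow_early[t] <- sum(occ[-EC] * P[-EC, EC])
    inflow_advanced[t] <- sum(occ[-AC] * P[-AC, AC])
  }

  w <- rep(1, H)
  if (isTRUE(params$half_cycle_correction)) {
    w[1] <- 0.5
    w[H] <- w[H] + 0.5  # terminal half-cycle folded into the last stage
  }
  disc <- discount_factor(params$discount_rate, seq_len(H) - 1L)

  structure(
    list(
      occupancy = model$occupancy,
      cycle_cost = w * cycle_cost,
      cycle_qaly = w * cycle_qaly,
      discounted_cost = disc * w * cycle_cost,
      discounted_qaly = disc * w * cycle_qaly,
      inflow_early = inflow_early,
      inflow_advanced = inflow_advanced,
      carrier = model$carrier,
      strategy = strategy$name,
      payer = strategy$payer,
      horizon = H
    ),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> ", x$strategy, "/", x$payer, ", ", x$horizon,
      " stages\n", sep = "")
  cat("  discounted totals: $", round(sum(x$discounted_cost)), " / ",
      round(sum(x$discounted_qaly), 2), " QALYs\n", sep = "")
  invisible(x)
}

#' Lifetime discounted outcomes of an arm
#'
#' Sums the per-stage expectations of a cohort trace into lifetime
#' discounted cost and QALYs and the cumulative incidence of the cancer
#' states (total inflow of new entrants over all stages).
#'
#' @param trace A `cohort_trace`.
#' @param params The parameter set the trace was run under (supplies the
#'   discount rate).
#' @param strategy The strategy the trace was run under (labelling only).
#' @return An object of class `arm_result`: list with `total_cost`,
#'   `total_qaly`, `cost_per_qaly`, `cum_incidence_early_crc`,
#'   `cum_incidence_advanced_crc`, `strategy`, `payer`.
#' @export
accrue_outcomes <- function(trace, params, strategy) {
  disc <- discount_factor(params$discount_rate, seq_len(trace$horizon) - 1L)
  total_cost <- sum(disc * trace$cycle_cost)
  total_qaly <- sum(disc * trace$cycle_qaly)
  structure(
    list(
      total_cost = total_cost,
      total_qaly = total_qaly,
      cost_per_qaly = if (total_qaly > 0) total_cost / total_qaly else NA_real_,
      cum_incidence_early_crc = sum(trace$inflow_early),
      cum_incidence_advanced_crc = sum(trace$inflow_advanced),
      strategy = strategy$name,
      payer = strategy$payer
    ),
    class = "arm_result"
  )
}

#' @export
print.arm_result <- function(x, ...) {
  cat("<arm_result> ", x$strategy, "/", x$payer, ": $",
      round(x$total_cost), " / ", round(x$total_qaly, 2), " QALYs ($",
      round(x$cost_per_qaly), "/QALY)\n", sep = "")
  cat("  cumulative incidence: early CRC ",
      sprintf("%.2f%%", 100 * x$cum_incidence_early_crc), ", advanced CRC ",
      sprintf("%.2f%%", 100 * x$cum_incidence_advanced_crc), "\n", sep = "")
  invisible(x)
}

#' Cumulative incidence of a cancer state
#'
#' Total inflow of new entrants into `EARLY_CRC` or `ADVANCED_CRC` over all
#' stages of a trace.
#'
#' @param trace A `cohort_trace`.
#' @param state `"EARLY_CRC"` or `"ADVANCED_CRC"`.
#' @return Lifetime fraction of the cohort ever entering the state.
#' @export
cumulative_incidence <- function(trace, state) {
  if (!state %in% c("EARLY_CRC", "ADVANCED_CRC"))
    stop("cumulative incidence is defined for the CRC states only",
         call. = FALSE)
  if (state == "EARLY_CRC") sum(trace$inflow_early)
  else sum(trace$inflow_advanced)
}

#' Run one arm end to end
#'
#' Convenience wrapper: builds the strategy from the parameter set, runs the
#' cohort and accrues lifetime outcomes.
#'
#' @param params Validated parameter set.
#' @param arm `"soc"` or `"purevu"`.
#' @param payer Payer; defaults to the parameter set's own payer.
#' @return An `arm_result`.
#' @export
#' @examples
#' run_arm(default_parameters(), "soc")
run_arm <- function(params, arm, payer = params$payer) {
  strategy <- make_strategy(arm, payer, params)
  accrue_outcomes(run_cohort(params, strategy), params, strategy)
}

#' Export a cohort trace as a per-stage table
#'
#' @param trace A `cohort_trace`.
#' @return Data frame with one row per stage: state occupancies, cycle cost
#'   and QALY, and their discounted accruals.
#' @export
trace_table <- function(trace) {
  data.frame(
    stage = seq_len(trace$horizon) - 1L,
    trace$occupancy,
    cycle_cost = trace$cycle_cost,
    cycle_qaly = trace$cycle_qaly,
    discounted_cost = trace$discounted_cost,
    discounted_qaly = trace$discounted_qaly,
    check.names = FALSE
  )
}
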