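#' Microsimulate individual patient trajectories
#'
#' Monte-Carlo twin of [run_cohort()]: `n` patients are walked stage by
#' stage through the same stage-dependent transition structure as the
#' cohort engine, with the within-stage colonoscopy episode resolved event
#' by event (attendance, prep adequacy, device deployment, within-episode
#' repeat, adenoma detection and polypectomy, complications, lapse from the
#' programme), so that per-patient discounted cost and QALY accruals have
#' exactly the cohort expectations. The state-frequency table across
#' patients is an unbiased estimate of the cohort occupancy at every stage,
#' which is what makes the microsimulation an independent oracle for the
#' deterministic engine.
#'
#' @param params Validated parameter set.
#' @param strategy A `cea_strategy`.
#' @param n Number of patients.
#' @param seed Integer seed; identical seeds reproduce identical output.
#' @param initial_occupancy Optional probability vector over
#'   [health_states()] for the entry draw (default: the engine's entry
#'   split).
#' @return An object of class `microsim_result`: `states` (n x horizon
#'   integer matrix of state indices into [health_states()]), `cost`
#'   and `qaly` (per-patient discounted totals), `events` (data frame of
#'   per-patient event counts: colonoscopies, inadequate preps, device
#'   uses, repeats, polypectomies, complications), `state_freq`
#'   (stage x state frequency matrix).
#' @export
#' @examples
#' \donttest{
#' ms <- simulate_patients(default_parameters(), make_strategy("soc"),
#'                         n = 200, seed = 1)
#' colMeans(ms$events)
#' }
simulate_patients <- function(params, strategy, n, seed = NULL,
                              initial_occupancy = NULL) {
  .assert_valid(params)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  model <- .arm_model(params, strategy, initial_occupancy = initial_occupancy)
  H <- model$horizon
  S <- length(model$states)
  ix <- model$idx
  u <- model$utilities
  disc <- discount_factor(params$discount_rate, seq_len(H) - 1L)

  m <- strategy$payer_multiplier
  q_present <- if (strategy$name == "purevu") strategy$device_use_fraction
               else strategy$p_inadequate_prep
  p_residual <- if (strategy$name == "purevu") strategy$p_inadequate_prep
                else 1  # SOC: a presenting-inadequate exam stays inadequate
  rep_p <- .effective_repeat(params)
  p_lapse <- params$p_lapse_after_inadequate
  f_surv <- params$p_surveillance_compliance / params$surveillance_interval_years
  exam_fee <- m * (params$cost_colonoscopy_dx + params$cost_physician)
  polyp_fee <- m * params$cost_colonoscopy_polypectomy
  compl_fee <- m * params$cost_complication
  device_fee <- (if (isFALSE(params$device_payer_multiplied)) 1 else m) *
    strategy$device_cost
  mk <- params$cancer_cost_multiplier
  state_cost <- numeric(S)
  state_cost[ix$EC] <- mk * params$cost_early_crc_annual
  state_cost[ix$AC] <- mk * params$cost_advanced_crc_annual
  state_cost[ix$REM] <- mk * params$cost_remission_annual

  # entry draw
  if (is.null(initial_occupancy)) {
    p0 <- numeric(S)
    p0[ix$CS] <- params$p_compliance_screening
    p0[ix$NWS] <- 1 - params$p_compliance_screening
  } else {
    p0 <- as.numeric(initial_occupancy[model$states])
  }
  state <- sample.int(S, n, replace = TRUE, prob = p0)

  states_mat <- matrix(0L, n, H)
  cost <- numeric(n)
  qaly <- numeric(n)
  ev <- matrix(0L, n, 6, dimnames = list(NULL, c(
    "colonoscopies", "inadequate_preps", "device_uses", "repeats",
    "polypectomies", "complications")))

  for (t in seq_len(H) - 1L) {
    states_mat[, t + 1L] <- state
    qaly <- qaly + disc[t + 1L] * u[state]
    cost <- cost + disc[t + 1L] * state_cost[state]
    a <- model$carrier[t + 1L, ]
    att <- model$attend[t + 1L]
    next_state <- state

    # --- colonoscopy episodes (screening in CS, surveillance in AS) -------
    for (st in c(ix$CS, ix$AS)) {
      idx <- which(state == st)
      if (!length(idx)) next
      is_cs <- st == ix$CS
      p_exam <- if (is_cs) att else f_surv
      if (p_exam == 0) next
      exam <- idx[stats::runif(length(idx)) < p_exam]
      if (!length(exam)) next
      k <- length(exam)
      a_st <- if (is_cs) a["COMPLIANT_SCREENING"] else a["ADENOMA_SURVEILLANCE"]
      carrier <- stats::runif(k) < a_st
      presenting <- stats::runif(k) < q_present
      residual <- presenting & (stats::runif(k) < p_residual)
      repeated <- residual & (stats::runif(k) < rep_p)
      repeat_failed <- repeated &
        (stats::runif(k) < params$p_inadequate_repeat)
      inadequate_final <- (residual & !repeated) | repeat_failed
      sens <- ifelse(inadequate_final, params$sens_inadequate,
                     params$sens_adequate)
      detected <- carrier & (stats::runif(k) < sens)
      lapse <- if (is_cs) (residual & !repeated) & !detected &
                          (stats::runif(k) < p_lapse)
               else rep(FALSE, k)
      n_exams <- 1L + as.integer(repeated)
      complication <- stats::rbinom(k, n_exams, params$p_complication)
      device <- if (strategy$name == "purevu") presenting else rep(FALSE, k)

      cost[exam] <- cost[exam] + disc[t + 1L] * (
        n_exams * exam_fee + detected * polyp_fee +
          complication * compl_fee + device * device_fee)
      ev[exam, "colonoscopies"] <- ev[exam, "colonoscopies"] + n_exams
      ev[exam, "inadequate_preps"] <- ev[exam, "inadequate_preps"] +
        as.integer(residual)
      ev[exam, "device_uses"] <- ev[exam, "device_uses"] + as.integer(device)
      ev[exam, "repeats"] <- ev[exam, "repeats"] + as.integer(repeated)
      ev[exam, "polypectomies"] <- ev[exam, "polypectomies"] +
        as.integer(detected)
      ev[exam, "complications"] <- ev[exam, "complications"] + complication

      undetected_carrier <- carrier & !detected
      progress <- undetected_carrier & !lapse &
        (stats::runif(k) < params$p_progression_adenoma_to_early)
      if (is_cs) {
        next_state[exam[detected]] <- ix$AS
        next_state[exam[lapse]] <- ix$NPC
        next_state[exam[progress]] <- ix$EC
      } else {
        next_state[exam[progress]] <- ix$EC
      }
      # non-examined members progress below with the rest of their state
      no_exam <- setdiff(idx, exam)
      if (length(no_exam)) {
        carrier_ne <- stats::runif(length(no_exam)) < a_st
        prog_ne <- carrier_ne &
          (stats::runif(length(no_exam)) < params$p_progression_adenoma_to_early)
        next_state[no_exam[prog_ne]] <- ix$EC
      }
    }

    # --- natural history in the non-screened alive states ------------------
    # outside the programme, progressing cancers present as advanced disease
    for (st in c(ix$NPC, ix$NWS)) {
      idx <- which(state == st)
      if (!length(idx)) next
      a_st <- if (st == ix$NPC) a["NONCOMPLIANT_POST_COLONOSCOPY"]
              else a["NONCOMPLIANT_WITH_SYSTEM"]
      carrier <- stats::runif(length(idx)) < a_st
      prog <- carrier &
        (stats::runif(length(idx)) < params$p_progression_adenoma_to_early)
      next_state[idx[prog]] <- ix$AC
    }
    # CS members at a non-screening stage
    if (att == 0) {
      idx <- which(state == ix$CS)
      if (length(idx)) {
        carrier <- stats::runif(length(idx)) < a["COMPLIANT_SCREENING"]
        prog <- carrier &
          (stats::runif(length(idx)) < params$p_progression_adenoma_to_early)
        next_state[idx[prog]] <- ix$EC
      }
    }

    # --- cancer states ------------------------------------------------------
    P <- model$transitions[t + 1L, , ]
    for (st in c(ix$EC, ix$AC, ix$REM)) {
      idx <- which(state == st)
      if (!length(idx)) next
      next_state[idx] <- sample.int(S, length(idx), replace = TRUE,
                                    prob = P[st, ])
    }

    # --- other-cause death overrides the year's transition ------------------
    non_crc_alive <- which(!(state %in% c(ix$DCRC, ix$DOTH)))
    dies <- non_crc_alive[stats::runif(length(non_crc_alive)) <
                            params$p_death_other]
    # cancer-state rows already embed other-cause death in their matrix draw
    dies <- dies[!state[dies] %in% c(ix$EC, ix$AC, ix$REM)]
    next_state[dies] <- ix$DOTH

    state <- next_state
  }

  freq <- matrix(0, H, S, dimnames = list(NULL, model$states))
  for (t in seq_len(H)) {
    tab <- tabulate(states_mat[, t], nbins = S)
    freq[t, ] <- tab / n
  }

  structure(
    list(states = states_mat, cost = cost, qaly = qaly,
         events = as.data.frame(ev), state_freq = freq,
         strategy = strategy$name, payer = strategy$payer, n = n),
    class = "microsim_result"
  )
}

#' @export
print.microsim_result <- function(x, ...) {
  cat("<microsim_result> ", x$n, " patients, ", x$strategy, "/", x$payer,
      "\n", sep = "")
  cat("  mean discounted cost $", round(mean(x$cost), 2), ", mean QALYs ",
      round(mean(x$qaly), 3), "\n", sep = "")
  invisible(x)
}

#' Specification of a synthetic colonoscopy-outcome study
#'
#' Describes the generator for study datasets used to exercise the
#' propensity module: patient age and sex, device allocation, cecal
#' intubation, and a logistic success model with configurable
#' coefficients.
#'
#' @param n Number of records.
#' @param age_mean,age_sd Age distribution (years).
#' @param p_male Probability of male sex.
#' @param p_device Probability of device (treatment) allocation.
#' @param cecal_shape1,cecal_shape2 Beta parameters of the cecal-intubation
#'   score in `[0, 1]`.
#' @param coef Named coefficients of the success model on the raw
#'   covariates: `intercept`, `age`, `sex`, `device_used`,
#'   `cecal_intubation`.
#' @param seed Integer seed.
#' @return An object of class `study_spec`.
#' @export
study_spec <- function(n, age_mean = 62, age_sd = 8, p_male = 0.54,
                       p_device = 0.5, cecal_shape1 = 18, cecal_shape2 = 2,
                       coef = c(intercept = -3.5, age = 0.05, sex = 0.8,
                                device_used = 1.0, cecal_intubation = 2.0),
                       seed = NULL) {
  stopifnot(n >= 1, p_male >= 0, p_male <= 1, p_device >= 0, p_device <= 1,
            age_sd >= 0)
  needed <- c("intercept", "age", "sex", "device_used", "cecal_intubation")
  if (!all(needed %in% names(coef)))
    stop("coef must name: ", paste(needed, collapse = ", "), call. = FALSE)
  structure(list(n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
                 p_male = p_male, p_device = p_device,
                 cecal_shape1 = cecal_shape1, cecal_shape2 = cecal_shape2,
                 coef = coef, seed = seed),
            class = "study_spec")
}

#' Generate a synthetic colonoscopy-outcome study
#'
#' Draws covariates per the spec and the binary completion outcome from the
#' logistic model at the spec's coefficients. Reproducible by seed.
#'
#' @param spec A [study_spec()].
#' @return Data frame with columns `age` (years), `sex` (1 = male),
#'   `device_used` (1 = cleansing device), `cecal_intubation` (score in
#'   `[0, 1]`), `success` (1 = completed colonoscopy).
#' @export
#' @examples
#' head(generate_study(study_spec(n = 5, seed = 42)))
generate_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n
  age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
  sex <- stats::rbinom(n, 1, spec$p_male)
  device <- stats::rbinom(n, 1, spec$p_device)
  cecal <- stats::rbeta(n, spec$cecal_shape1, spec$cecal_shape2)
  b <- spec$coef
  eta <- b[["intercept"]] + b[["age"]] * age + b[["sex"]] * sex +
    b[["device_used"]] * device + b[["cecal_intubation"]] * cecal
  success <- stats::rbinom(n, 1, stats::plogis(eta))
  data.frame(age = age, sex = sex, device_used = device,
             cecal_intubation = cecal, success = success)
}
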