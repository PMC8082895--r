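#' Define an analysis arm
#'
#' The analysis compares two strategies for screening colonoscopy, each
#' priced at Medicare or private reimbursement:
#'
#' * `soc` — standard of care: 25% of exams are inadequately prepped; an
#'   inadequately prepped exam is repeated within the screening episode with
#'   probability `p_repeat_after_inadequate`, otherwise the miss rate of the
#'   poor-quality exam applies.
#' * `purevu` — the intra-procedural cleansing device is deployed in the 25%
#'   of exams presenting with inadequate prep (at its list price); 5% of
#'   device-assisted exams remain inadequate.
#'
#' @param arm `"soc"` or `"purevu"`.
#' @param payer `"medicare"` or `"private"`.
#' @param params Parameter set supplying the device list price, the prep
#'   rates and the payer multiplier; defaults to [default_parameters()] for
#'   the chosen payer.
#' @return An object of class `cea_strategy` with fields `name`,
#'   `p_inadequate_prep`, `device_cost`, `device_use_fraction`, `payer`,
#'   `payer_multiplier`.
#' @export
#' @examples
#' make_strategy("purevu", "medicare")$p_inadequate_prep
make_strategy <- function(arm = c("soc", "purevu"),
                          payer = c("medicare", "private"),
                          params = default_parameters(payer)) {
  arm <- match.arg(arm)
  payer <- match.arg(payer)
  multiplier <- if (payer == "private") params$payer_multiplier else 1.0
  structure(
    list(
      name = arm,
      p_inadequate_prep = if (arm == "purevu") params$p_inadequate_prep_purevu
                          else params$p_inadequate_prep_soc,
      device_cost = if (arm == "purevu") params$cost_purevu_device else 0,
      # fraction of exams presenting with inadequate prep, i.e. where the
      # device is deployed in the purevu arm
      device_use_fraction = if (arm == "purevu") params$p_inadequate_prep_soc
                            else 0,
      payer = payer,
      payer_multiplier = multiplier
    ),
    class = "cea_strategy"
  )
}

#' @export
print.cea_strategy <- function(x, ...) {
  cat("<cea_strategy> ", x$name, " / ", x$payer,
      " (multiplier ", x$payer_multiplier, ")\n", sep = "")
  invisible(x)
}

# Effective probability that a screening episode is never adequately
# examined this round: SOC, the raw inadequate-prep rate; purevu, the
# residual rate among device-assisted exams times the device-use fraction.
.effective_inadequate <- function(strategy) {
  if (strategy$name == "purevu") {
    strategy$device_use_fraction * strategy$p_inadequate_prep
  } else {
    strategy$p_inadequate_prep
  }
}

# Per-exam adenoma detection probability for a carrier, composed over the
# prep-adequacy branches: adequate (or device-cleaned) exams detect at the
# adequate sensitivity; inadequate exams are repeated with probability
# `p_repeat` (the definitive repeat is adequate), otherwise the poor-prep
# miss rate applies.
.detection_prob <- function(params, strategy,
                            p_repeat = params$p_repeat_after_inadequate) {
  q <- .effective_inadequate(strategy)
  # the repeat exam itself fails prep at an elevated rate
  s_rep <- (1 - params$p_inadequate_repeat) * params$sens_adequate +
    params$p_inadequate_repeat * params$sens_inadequate
  (1 - q) * params$sens_adequate +
    q * (p_repeat * s_rep + (1 - p_repeat) * params$sens_inadequate)
}

# Repeat attendance used by the cohort engine: repeat behaviour is
# compliance behaviour, anchored so that the base 60% compliance gives the
# published repeat rate.
.effective_repeat <- function(params) {
  min(1, params$p_repeat_uptake * params$p_compliance_screening)
}

#' Apply the private-payer reimbursement multiplier
#'
#' Private-insurer reimbursement for colonoscopy services runs 163–248% of
#' the Medicare fee; costs on the Medicare scale are converted by a simple
#' ratio.
#'
#' @param cost_medicare Cost on the Medicare scale (non-negative).
#' @param multiplier Reimbursement ratio, at least 1 (Medicare itself is 1).
#' @return `cost_medicare * multiplier`.
#' @export
#' @examples
#' payer_adjust(100, 1.63)
payer_adjust <- function(cost_medicare, multiplier) {
  if (any(cost_medicare < 0)) stop("cost must be non-negative", call. = FALSE)
  if (any(multiplier < 1)) stop("multiplier must be at least 1", call. = FALSE)
  cost_medicare * multiplier
}

#' Expected cost of a colonoscopy episode
#'
#' Composes the expected cost of one attended colonoscopy episode under a
#' strategy: the diagnostic procedure and physician fee, the polypectomy
#' increment when an adenoma is removed, expected complication costs, the
#' expected cost of a repeat exam after inadequate preparation, and the
#' device charge in the purevu arm. All medical components are payer
#' adjusted; the device is charged at list price and is exempt from the
#' payer multiplier.
#'
#' @param params Validated parameter set.
#' @param strategy A `cea_strategy`.
#' @param p_polypectomy Probability the episode removes an adenoma. Defaults
#'   to adenoma prevalence times the strategy's per-exam detection
#'   probability; the cohort engine passes the current carrier fraction of
#'   the state instead.
#' @param p_repeat Probability an inadequately prepped exam is repeated
#'   within the episode. Defaults to `p_repeat_after_inadequate`; the
#'   cohort engine passes the compliance-coupled repeat attendance instead.
#'
#' @details The device charge is treated as a procedure add-on reimbursed on
#' the same payer scale as the other colonoscopy services (its $750 price is
#' on the Medicare reference scale). Setting
#' `params$device_payer_multiplied <- FALSE` charges the device at flat list
#' price instead.
#' @return An object of class `episode_cost`: list with `expected_cost` and
#'   a `components` vector (`base_procedure`, `physician`,
#'   `polypectomy_increment`, `complication`, `repeat_exam`, `device`).
#' @export
#' @examples
#' colonoscopy_episode_cost(default_parameters(), make_strategy("purevu"))
colonoscopy_episode_cost <- function(params, strategy,
                                     p_polypectomy = NULL,
                                     p_repeat = params$p_repeat_after_inadequate) {
  if (is.null(p_polypectomy)) {
    p_polypectomy <- params$p_adenoma_prevalence *
      .detection_prob(params, strategy, p_repeat = p_repeat)
  }
  m <- strategy$payer_multiplier
  q <- .effective_inadequate(strategy)
  rep_p <- p_repeat
  n_exams <- 1 + q * rep_p   # expected exams in the episode

  components <- c(
    base_procedure = m * params$cost_colonoscopy_dx,
    physician = m * params$cost_physician,
    polypectomy_increment = m * p_polypectomy * params$cost_colonoscopy_polypectomy,
    complication = m * n_exams * params$p_complication * params$cost_complication,
    repeat_exam = m * q * rep_p *
      (params$cost_colonoscopy_dx + params$cost_physician),
    device = (if (isFALSE(params$device_payer_multiplied)) 1 else m) *
      strategy$device_use_fraction * strategy$device_cost
  )
  structure(list(expected_cost = sum(components), components = components),
            class = "episode_cost")
}

#' @export
print.episode_cost <- function(x, ...) {
  cat("<episode_cost> expected $", round(x$expected_cost, 2), "\n", sep = "")
  print(round(x$components, 2))
  invisible(x)
}
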