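#' Distribution specification for probabilistic sensitivity analysis
#'
#' Describes the second-order uncertainty distribution attached to a model
#' parameter. Supported families are those conventionally used in health
#' economic models: `beta` for probabilities and utilities, `gamma` for
#' costs, `uniform` and `triangular` for range-only evidence, `normal` for
#' symmetric uncertainty, and `point` for parameters held fixed.
#'
#' @param kind One of `"beta"`, `"gamma"`, `"uniform"`, `"triangular"`,
#'   `"normal"`, `"point"`.
#' @param params Named list of family parameters: `shape1`/`shape2` (beta),
#'   `shape`/`scale` (gamma), `min`/`max` (uniform), `min`/`mode`/`max`
#'   (triangular), `mean`/`sd` (normal), `value` (point).
#' @param support Optional length-2 numeric `(low, high)`; draws are clipped
#'   by rejection to this interval.
#' @return An object of class `dist_spec`.
#' @export
#' @examples
#' dist_spec("beta", list(shape1 = 36, shape2 = 24))
#' dist_spec("uniform", list(min = 1.63, max = 2.48))
dist_spec <- function(kind, params, support = NULL) {
  kind <- match.arg(kind, c("beta", "gamma", "uniform", "triangular",
                            "normal", "point"))
  stopifnot(is.list(params))
  spec <- structure(list(kind = kind, params = params, support = support),
                    class = "dist_spec")
  err <- .check_dist_spec(spec)
  if (!is.null(err)) stop(err, call. = FALSE)
  spec
}

# Returns NULL if valid, otherwise a message.
.check_dist_spec <- function(spec) {
  p <- spec$params
  need <- function(nm) {
    miss <- setdiff(nm, names(p))
    if (length(miss)) return(paste0("missing parameter(s): ",
                                    paste(miss, collapse = ", ")))
    NULL
  }
  msg <- switch(spec$kind,
    beta = {
      m <- need(c("shape1", "shape2"))
      if (is.null(m) && (p$shape1 <= 0 || p$shape2 <= 0))
        m <- "beta shapes must be positive"
      m
    },
    gamma = {
      m <- need(c("shape", "scale"))
      if (is.null(m) && (p$shape <= 0 || p$scale <= 0))
        m <- "gamma shape/scale must be positive"
      m
    },
    uniform = {
      m <- need(c("min", "max"))
      if (is.null(m) && p$min >= p$max) m <- "uniform requires min < max"
      m
    },
    triangular = {
      m <- need(c("min", "mode", "max"))
      if (is.null(m) && !(p$min < p$max && p$mode >= p$min && p$mode <= p$max))
        m <- "triangular requires min < max and min <= mode <= max"
      m
    },
    normal = {
      m <- need(c("mean", "sd"))
      if (is.null(m) && p$sd < 0) m <- "normal sd must be non-negative"
      m
    },
    point = need("value")
  )
  if (!is.null(msg)) return(msg)
  if (!is.null(spec$support)) {
    if (length(spec$support) != 2 || spec$support[1] >= spec$support[2])
      return("support must be (low, high) with low < high")
    if (spec$kind == "point" &&
        (p$value < spec$support[1] || p$value > spec$support[2]))
      return("point value outside its support")
  }
  NULL
}

# Beta spec from a mean and an effective sample size (method of moments).
.beta_mean_n <- function(mean, n, support = c(0, 1)) {
  dist_spec("beta", list(shape1 = mean * n, shape2 = (1 - mean) * n),
            support = support)
}

# Gamma spec from a mean and coefficient of variation.
.gamma_mean_cv <- function(mean, cv = 0.15) {
  shape <- 1 / cv^2
  dist_spec("gamma", list(shape = shape, scale = mean / shape),
            support = c(0, Inf))
}

#' Base-case parameter set
#'
#' Returns the full configuration of the lifetime screening model for a
#' 60-year-old average-risk cohort: a 10-yearly screening colonoscopy
#' programme with 60% compliance, a 25% inadequate-preparation rate under
#' standard of care versus 5% residual inadequacy when the intra-procedural
#' cleansing device is used, a $750 device list price, 3% annual discounting,
#' and a 24-year horizon equal to the cohort's remaining life expectancy.
#'
#' Headline values (compliance, prep rates, device price, discount rate,
#' payer multiplier range, life expectancies, sex mix) are the published
#' base case. Detection, complication, natural-history, cost and utility
#' inputs are supplementary-sourced defaults: plausible 2019-USD Medicare
#' values, with three natural-history parameters
#' (`p_progression_adenoma_to_early`, `p_progression_early_to_advanced`,
#' `p_adenoma_incidence`) calibrated so the deterministic model reproduces
#' the published base-case cost/QALY cells; see the methods vignette.
#' Every value can be overridden via [load_parameters()] or by assignment.
#'
#' @param payer `"medicare"` (reference reimbursement scale, multiplier 1)
#'   or `"private"` (multiplier defaults to the midpoint of the published
#'   1.63–2.48 range).
#' @return An object of class `cea_parameters`: a named list of model inputs
#'   including the `utility_by_state` mapping and the `psa_distributions`
#'   used by [run_psa()].
#' @export
#' @examples
#' p <- default_parameters("medicare")
#' p$cost_purevu_device
#' default_parameters("private")$payer_multiplier
default_parameters <- function(payer = c("medicare", "private")) {
  payer <- match.arg(payer)
  u <- c(
    COMPLIANT_SCREENING           = 0.96,
    NONCOMPLIANT_POST_COLONOSCOPY = 0.96,
    NONCOMPLIANT_WITH_SYSTEM      = 0.96,
    ADENOMA_SURVEILLANCE          = 0.96,
    EARLY_CRC                     = 0.74,
    ADVANCED_CRC                  = 0.50,
    REMISSION                     = 0.88,
    DEATH_CRC                     = 0.00,
    DEATH_OTHER                   = 0.00
  )
  params <- list(
    # screening programme
    p_compliance_screening   = 0.60,
    p_inadequate_prep_soc    = 0.25,
    p_inadequate_prep_purevu = 0.05,   # residual inadequacy among device-assisted exams
    p_repeat_after_inadequate = 0.575, # repeat colonoscopy within 3 years (midpoint 55-60%)
    # attendance at the repeat exam is compliance behaviour: the engine uses
    # p_repeat_uptake * p_compliance_screening, which equals
    # p_repeat_after_inadequate at the 60% base compliance
    p_repeat_uptake = 0.575 / 0.60,
    # patients whose prep failed once fail again on the repeat exam at an
    # elevated rate (supplementary-sourced)
    p_inadequate_repeat = 0.55,
    p_lapse_after_inadequate = 0.10,   # inadequate, never-repeated exam -> lapse from programme
    p_surveillance_compliance = 0.85,
    screening_interval_years = 10L,
    surveillance_interval_years = 3L,
    # detection (supplementary-sourced)
    sens_adequate   = 0.97,
    spec_adequate   = 1.00,
    sens_inadequate = 0.52,            # 42-48% miss rate in poorly prepped colons
    p_complication  = 0.005,
    # natural history (calibrated parameters, see vignette)
    p_adenoma_prevalence            = 0.30,
    p_adenoma_incidence             = 0.002,
    p_adenoma_recurrence            = 0.05,
    p_progression_adenoma_to_early  = 0.15,
    p_progression_early_to_advanced = 0.025,
    p_remission_early               = 0.30,
    p_death_early_crc               = 0.004,
    p_death_other                   = 0.002,
    life_expectancy_no_crc       = 24,
    life_expectancy_early_crc    = 23,
    life_expectancy_advanced_crc = 4.8,
    # costs, 2019 USD, Medicare reference scale (supplementary-sourced;
    # cancer-care streams calibrated, see vignette)
    cost_colonoscopy_dx          = 380,
    cost_physician               = 140,
    cost_colonoscopy_polypectomy = 250,  # increment over a diagnostic exam
    cost_complication            = 8000,
    cost_early_crc_annual        = 36993,
    cost_advanced_crc_annual     = 1573,
    cost_remission_annual        = 800,
    cost_purevu_device           = 750,
    payer           = payer,
    payer_multiplier = if (payer == "private") (1.63 + 2.48) / 2 else 1.0,
    # commercial oncology reimbursement runs above Medicare, but by less
    # than the colonoscopy-fee multiplier (supplementary-sourced)
    cancer_cost_multiplier = if (payer == "private") 1.1835 else 1.0,
    # cohort / accounting
    utility_by_state = as.list(u),
    discount_rate    = 0.03,
    start_age        = 60,
    sex_mix          = 0.54,
    horizon_years    = 24L,
    half_cycle_correction = FALSE,
    device_payer_multiplied = TRUE,
    psa_distributions = list()
  )
  params$psa_distributions <- .default_psa_distributions(params)
  structure(params, class = "cea_parameters")
}

# Default second-order distributions (supplementary-sourced): beta for
# probabilities and utilities, gamma for costs, uniform where only a
# published range exists. Structural integers and the device list price
# stay fixed.
.default_psa_distributions <- function(p) {
  d <- list(
    p_compliance_screening   = .beta_mean_n(p$p_compliance_screening, 60),
    p_inadequate_prep_soc    = .beta_mean_n(p$p_inadequate_prep_soc, 100),
    p_inadequate_prep_purevu = .beta_mean_n(p$p_inadequate_prep_purevu, 100),
    p_repeat_after_inadequate = dist_spec(
      "uniform", list(min = 0.55, max = 0.60), support = c(0, 1)),
    sens_inadequate = dist_spec(
      "uniform", list(min = 0.52, max = 0.58), support = c(0, 1)),
    sens_adequate  = .beta_mean_n(p$sens_adequate, 100),
    p_complication = .beta_mean_n(p$p_complication, 2000),
    p_adenoma_prevalence = dist_spec(
      "uniform", list(min = 0.20, max = 0.30), support = c(0, 1)),
    p_progression_adenoma_to_early =
      .beta_mean_n(p$p_progression_adenoma_to_early, 400),
    p_progression_early_to_advanced =
      .beta_mean_n(p$p_progression_early_to_advanced, 200),
    cost_colonoscopy_dx      = .gamma_mean_cv(p$cost_colonoscopy_dx),
    cost_physician           = .gamma_mean_cv(p$cost_physician),
    cost_complication        = .gamma_mean_cv(p$cost_complication),
    cost_early_crc_annual    = .gamma_mean_cv(p$cost_early_crc_annual),
    cost_advanced_crc_annual = .gamma_mean_cv(p$cost_advanced_crc_annual)
  )
  if (identical(p$payer, "private")) {
    d$payer_multiplier <- dist_spec(
      "uniform", list(min = 1.63, max = 2.48), support = c(1, Inf))
  }
  d
}

# Field groups used by the validator and by sweep/threshold argument checks.
.prob_fields <- function() {
  c("p_compliance_screening", "p_inadequate_prep_soc",
    "p_inadequate_prep_purevu", "p_repeat_after_inadequate",
    "p_repeat_uptake", "p_inadequate_repeat", "p_lapse_after_inadequate",
    "p_surveillance_compliance",
    "sens_adequate", "spec_adequate", "sens_inadequate", "p_complication",
    "p_adenoma_prevalence", "p_adenoma_incidence", "p_adenoma_recurrence",
    "p_progression_adenoma_to_early", "p_progression_early_to_advanced",
    "p_remission_early", "p_death_early_crc", "p_death_other", "sex_mix")
}

.cost_fields <- function() {
  c("cost_colonoscopy_dx", "cost_physician", "cost_colonoscopy_polypectomy",
    "cost_complication", "cost_early_crc_annual", "cost_advanced_crc_annual",
    "cost_remission_annual", "cost_purevu_device")
}

.numeric_fields <- function() {
  c(.prob_fields(), .cost_fields(),
    "life_expectancy_no_crc", "life_expectancy_early_crc",
    "life_expectancy_advanced_crc", "payer_multiplier",
    "cancer_cost_multiplier", "discount_rate",
    "screening_interval_years", "surveillance_interval_years",
    "start_age", "horizon_years")
}

#' Validate a parameter set
#'
#' Checks every schema invariant (probabilities in `[0, 1]`, non-negative
#' costs, utilities in `[0, 1]`, discount rate and intervals, payer
#' multiplier at least 1, internal consistency of the early-CRC exit
#' probabilities, well-formed PSA distributions) and reports **all**
#' violations, not only the first.
#'
#' @param params A `cea_parameters` object (or plain named list).
#' @return An object of class `validation_report` with `errors` and
#'   `warnings` data frames (`field`, `message`). The configuration is
#'   accepted iff `errors` is empty; see [is_valid()].
#' @export
#' @examples
#' validate_parameters(default_parameters())
validate_parameters <- function(params) {
  errors <- list()
  warns <- list()
  add_err <- function(field, message) {
    errors[[length(errors) + 1L]] <<- data.frame(field = field,
                                                 message = message)
  }
  add_warn <- function(field, message) {
    warns[[length(warns) + 1L]] <<- data.frame(field = field,
                                               message = message)
  }

  for (f in .numeric_fields()) {
    v <- params[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      add_err(f, "missing or not a finite scalar")
    }
  }
  ok <- function(f) {
    v <- params[[f]]
    !is.null(v) && is.numeric(v) && length(v) == 1 && is.finite(v)
  }
  for (f in .prob_fields()) {
    if (ok(f) && (params[[f]] < 0 || params[[f]] > 1))
      add_err(f, "probability outside [0, 1]")
  }
  for (f in .cost_fields()) {
    if (ok(f) && params[[f]] < 0) add_err(f, "cost must be non-negative")
  }
  if (ok("discount_rate") && params$discount_rate < 0)
    add_err("discount_rate", "must be non-negative")
  if (ok("payer_multiplier") && params$payer_multiplier < 1)
    add_err("payer_multiplier", "must be at least 1 (Medicare = 1)")
  if (ok("cancer_cost_multiplier") && params$cancer_cost_multiplier < 1)
    add_err("cancer_cost_multiplier", "must be at least 1 (Medicare = 1)")
  for (f in c("screening_interval_years", "surveillance_interval_years",
              "horizon_years")) {
    if (ok(f) && (params[[f]] < 1 || params[[f]] != round(params[[f]])))
      add_err(f, "must be a positive integer")
  }
  for (f in c("life_expectancy_no_crc", "life_expectancy_early_crc",
              "life_expectancy_advanced_crc")) {
    if (ok(f) && params[[f]] < 1) add_err(f, "life expectancy below 1 year")
  }
  if (!identical(params$payer, "medicare") &&
      !identical(params$payer, "private"))
    add_err("payer", "must be \"medicare\" or \"private\"")

  u <- params$utility_by_state
  if (is.null(u) || !all(health_states() %in% names(u))) {
    add_err("utility_by_state", "must map every health state to a utility")
  } else {
    uv <- unlist(u[health_states()])
    if (any(!is.finite(uv) | uv < 0 | uv > 1))
      add_err("utility_by_state", "utilities must lie in [0, 1]")
    if (all(is.finite(uv)) && any(uv[absorbing_states()] != 0))
      add_warn("utility_by_state", "death-state utilities are usually 0")
  }

  # early-CRC annual exits must not exceed 1
  exit_fields <- c("p_progression_early_to_advanced", "p_remission_early",
                   "p_death_early_crc", "p_death_other")
  if (all(vapply(exit_fields, ok, logical(1)))) {
    tot <- sum(unlist(params[exit_fields]))
    if (tot > 1)
      add_err("p_progression_early_to_advanced",
              sprintf("early-CRC annual exit probabilities sum to %.3f > 1",
                      tot))
  }

  if (!is.null(params$psa_distributions)) {
    for (nm in names(params$psa_distributions)) {
      spec <- params$psa_distributions[[nm]]
      msg <- .check_dist_spec(spec)
      if (!is.null(msg))
        add_err(paste0("psa_distributions.", nm), msg)
      else if (!nm %in% names(params))
        add_err(paste0("psa_distributions.", nm),
                "distribution attached to unknown field")
    }
  }

  empty <- data.frame(field = character(), message = character())
  structure(
    list(errors = if (length(errors)) do.call(rbind, errors) else empty,
         warnings = if (length(warns)) do.call(rbind, warns) else empty),
    class = "validation_report"
  )
}

#' @rdname validate_parameters
#' @param report A `validation_report`.
#' @return `is_valid()`: `TRUE` iff the report carries no errors.
#' @export
is_valid <- function(report) nrow(report$errors) == 0L

#' @export
print.validation_report <- function(x, ...) {
  if (is_valid(x)) {
    cat("Parameter set accepted (no errors")
    if (nrow(x$warnings)) cat(", ", nrow(x$warnings), " warning(s)", sep = "")
    cat(")\n")
  } else {
    cat("Parameter set rejected:\n")
    for (i in seq_len(nrow(x$errors)))
      cat("  - ", x$errors$field[i], ": ", x$errors$message[i], "\n", sep = "")
  }
  if (nrow(x$warnings)) {
    cat("Warnings:\n")
    for (i in seq_len(nrow(x$warnings)))
      cat("  - ", x$warnings$field[i], ": ", x$warnings$message[i], "\n",
          sep = "")
  }
  invisible(x)
}

# Stops with a validation error unless params pass all checks.
.assert_valid <- function(params) {
  rep <- validate_parameters(params)
  if (!is_valid(rep)) {
    stop("invalid parameter set:\n  ",
         paste0(rep$errors$field, ": ", rep$errors$message, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(params)
}

#' Read a parameter configuration from YAML
#'
#' Reads a structured-text (YAML) configuration. Any field absent from the
#' file keeps its [default_parameters()] value for the file's payer (or for
#' the `payer` argument when the file does not name one), so a minimal file
#' may override only a handful of inputs. The merged set is validated and
#' must pass.
#'
#' @param path Path to a YAML file, e.g. one written by [write_parameters()].
#' @param payer Default payer used when the file does not set one.
#' @return A validated `cea_parameters` object.
#' @export
load_parameters <- function(path, payer = "medicare") {
  if (!file.exists(path)) stop("parameter file not found: ", path,
                               call. = FALSE)
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("cannot parse parameter file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(raw)) stop("parameter file ", path,
                          " does not contain a key/value mapping",
                          call. = FALSE)
  if (!is.null(raw$payer)) payer <- raw$payer
  if (!payer %in% c("medicare", "private"))
    stop("payer must be \"medicare\" or \"private\", got: ", payer,
         call. = FALSE)
  params <- default_parameters(payer)

  unknown <- setdiff(names(raw), names(params))
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(raw)) {
    if (nm == "psa_distributions") next
    if (nm == "utility_by_state") {
      for (st in names(raw[[nm]])) params$utility_by_state[[st]] <- raw[[nm]][[st]]
    } else if (nm %in% c("screening_interval_years",
                         "surveillance_interval_years", "horizon_years")) {
      params[[nm]] <- as.integer(raw[[nm]])
    } else {
      params[[nm]] <- raw[[nm]]
    }
  }
  if (!is.null(raw$psa_distributions)) {
    params$psa_distributions <- lapply(raw$psa_distributions, function(d) {
      dist_spec(d$kind, d$params,
                support = if (!is.null(d$support)) as.numeric(d$support))
    })
  } else {
    # second-order distributions follow the (possibly overridden) base values
    params$psa_distributions <- .default_psa_distributions(params)
  }
  .assert_valid(params)
  params
}

#' Write a parameter configuration to YAML
#'
#' Serializes a parameter set, including its PSA distributions, so that
#' `load_parameters(write_parameters(p, f))` returns a field-identical set.
#'
#' @param params A validated `cea_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  .assert_valid(params)
  out <- unclass(params)
  out$psa_distributions <- lapply(out$psa_distributions, function(d) {
    list(kind = d$kind, params = d$params,
         support = if (!is.null(d$support)) as.numeric(d$support))
  })
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Flatten a parameter set for reporting
#'
#' @param x A `cea_parameters` object.
#' @param row.names,optional,... Ignored; present for S3 compatibility.
#' @return A data frame with columns `field` and `value` covering every
#'   scalar input and per-state utility (PSA distributions are excluded).
#' @export
as.data.frame.cea_parameters <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  fields <- .numeric_fields()
  vals <- vapply(fields, function(f) as.numeric(x[[f]]), numeric(1))
  u <- unlist(x$utility_by_state[health_states()])
  data.frame(
    field = c(fields, paste0("utility_by_state.", health_states())),
    value = c(vals, as.numeric(u)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("<cea_parameters> ", x$payer, " payer, ",
      x$horizon_years, "-year horizon\n", sep = "")
  cat("  compliance ", x$p_compliance_screening,
      ", inadequate prep SOC ", x$p_inadequate_prep_soc,
      " / device ", x$p_inadequate_prep_purevu,
      ", device $", x$cost_purevu_device, "\n", sep = "")
  cat("  ", length(x$psa_distributions),
      " fields carry PSA distributions\n", sep = "")
  invisible(x)
}
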