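# Reporting conventions: dollars to the nearest integer, QALYs to 2
# decimals. Rounding is applied at the writing stage only; computation
# keeps full precision.
.fmt_dollars <- function(x) round(x)
.fmt_qaly <- function(x) round(x, 2)

# Resolve a configuration argument: NULL -> shipped defaults, path ->
# load_parameters(), cea_parameters -> used as-is (re-validated).
.resolve_config <- function(config, payer = "medicare") {
  if (is.null(config)) return(default_parameters(payer))
  if (inherits(config, "cea_parameters")) {
    p <- config
    if (!identical(p$payer, payer)) {
      defaults <- default_parameters(payer)
      p$payer <- payer
      p$payer_multiplier <- defaults$payer_multiplier
      p$cancer_cost_multiplier <- defaults$cancer_cost_multiplier
    }
    .assert_valid(p)
    return(p)
  }
  load_parameters(config, payer = payer)
}

# Every report run writes a manifest next to its outputs.
.write_manifest <- function(out_dir, command, config, seed, outputs) {
  manifest <- list(
    command = command,
    config = if (is.character(config)) config else "(defaults)",
    seed = if (is.null(seed)) NA else seed,
    package_version = as.character(utils::packageVersion("prepcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)
  )
  path <- file.path(out_dir, "manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Base-case report: lifetime costs and QALYs for all four arms
#'
#' Runs both strategies at Medicare and private reimbursement and writes
#' the base-case table (cost, QALYs, cost/QALY per arm, with reporting
#' rounding), the per-stage cohort traces, and a run manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param config `NULL` (shipped defaults), a YAML path, or a
#'   `cea_parameters` object.
#' @return Invisibly, the base-case data frame (full precision).
#' @export
report_base_case <- function(out_dir, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  outputs <- character()
  for (payer in c("medicare", "private")) {
    params <- .resolve_config(config, payer)
    for (arm in c("purevu", "soc")) {
      strategy <- make_strategy(arm, payer, params)
      trace <- run_cohort(params, strategy)
      res <- accrue_outcomes(trace, params, strategy)
      rows[[paste(payer, arm)]] <- data.frame(
        payer = payer, arm = arm,
        cost = res$total_cost, qaly = res$total_qaly,
        cost_per_qaly = res$total_cost / res$total_qaly,
        cum_incidence_early_crc = res$cum_incidence_early_crc,
        cum_incidence_advanced_crc = res$cum_incidence_advanced_crc
      )
      trace_file <- file.path(out_dir, sprintf("trace_%s_%s.csv", arm, payer))
      utils::write.csv(trace_table(trace), trace_file, row.names = FALSE)
      outputs <- c(outputs, trace_file)
    }
  }
  full <- do.call(rbind, rows)
  printed <- transform(full,
                       cost = .fmt_dollars(cost),
                       qaly = .fmt_qaly(qaly),
                       cost_per_qaly = .fmt_dollars(cost_per_qaly))
  table_file <- file.path(out_dir, "base_case.csv")
  utils::write.csv(printed, table_file, row.names = FALSE)
  .write_manifest(out_dir, "base-case", config, NULL,
                  c(table_file, outputs))
  invisible(full)
}

#' One-way sweep report
#'
#' @param out_dir Output directory.
#' @param parameter Swept field name.
#' @param grid Numeric grid.
#' @param config Configuration (see [report_base_case()]).
#' @param payer Payer for costing.
#' @return Invisibly, the `sweep_result`.
#' @export
report_sweep <- function(out_dir, parameter, grid, config = NULL,
                         payer = "private") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- .resolve_config(config, payer)
  sw <- one_way_sweep(params, parameter, grid, payer = payer)
  f <- file.path(out_dir, sprintf("sweep_%s_%s.csv", parameter, payer))
  utils::write.csv(as.data.frame(sw), f, row.names = FALSE)
  .write_manifest(out_dir, paste("sweep", parameter), config, NULL, f)
  invisible(sw)
}

#' Threshold report
#'
#' @inheritParams report_sweep
#' @param bracket Length-2 search bracket.
#' @param tol Bisection resolution (default per [find_threshold()]).
#' @return Invisibly, the `threshold_result`.
#' @export
report_threshold <- function(out_dir, parameter, bracket, tol = NULL,
                             config = NULL, payer = "medicare") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- .resolve_config(config, payer)
  th <- find_threshold(params, parameter, bracket, tol = tol, payer = payer)
  f <- file.path(out_dir, sprintf("threshold_%s_%s.json", parameter, payer))
  jsonlite::write_json(
    list(parameter = th$parameter, threshold = th$threshold,
         bracket = th$bracket, tolerance = th$tolerance,
         predicate = th$predicate, payer = th$payer),
    f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_manifest(out_dir, paste("threshold", parameter), config, NULL, f)
  invisible(th)
}

#' PSA report
#'
#' @inheritParams report_sweep
#' @param n_max Number of Monte-Carlo draws.
#' @param seed Integer seed.
#' @param wtp Willingness to pay per QALY.
#' @return Invisibly, the `psa_result`.
#' @export
report_psa <- function(out_dir, config = NULL, payer = "medicare",
                       n_max = 2000L, seed = 1L, wtp = 50000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- .resolve_config(config, payer)
  psa <- run_psa(params, n_max = n_max, seed = seed, wtp = wtp)
  f_samples <- file.path(out_dir, "psa_samples.csv")
  utils::write.csv(psa$samples, f_samples, row.names = FALSE)
  plane <- summarize_ce_plane(psa)
  f_summary <- file.path(out_dir, "psa_summary.json")
  jsonlite::write_json(
    list(n = nrow(psa$samples), wtp = psa$wtp, seed = seed,
         inb_mean = psa$inb_mean, inb_ci95 = psa$inb_ci95,
         prob_positive_inb = psa$prob_positive_inb,
         converged_at = if (is.na(psa$converged_at)) NULL
                        else psa$converged_at,
         n_icer_excluded = psa$n_icer_excluded,
         quadrant_fractions = as.list(plane$quadrant_fractions)),
    f_summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_manifest(out_dir, "psa", config, seed, c(f_samples, f_summary))
  invisible(psa)
}

#' Propensity-analysis report
#'
#' Generates (or loads) a colonoscopy-outcome study, fits the outcome and
#' treatment logistic models, matches device to standard-of-care patients
#' on the propensity score, and writes the study data, model coefficients,
#' matched pairs and balance table.
#'
#' @param out_dir Output directory.
#' @param study Data frame of study records, or `NULL` to generate a
#'   synthetic study of size `n`.
#' @param n Synthetic study size when `study` is `NULL`.
#' @param seed Integer seed for the generator.
#' @param caliper Matching caliper (default per [match_scores()]).
#' @return Invisibly, a list with the fitted models, matched set and
#'   balance table.
#' @export
report_propensity <- function(out_dir, study = NULL, n = 2000L, seed = 1L,
                              caliper = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(study)) study <- generate_study(study_spec(n = n, seed = seed))
  outcome_model <- fit_logistic(
    study, c("age", "sex", "device_used", "cecal_intubation"))
  treatment_model <- fit_logistic(study, c("age", "sex"),
                                  outcome = "device_used")
  scores <- propensity_score(treatment_model, study)
  treated <- which(study$device_used == 1)
  control <- which(study$device_used == 0)
  matched <- match_scores(scores[treated], scores[control], caliper = caliper)
  balance <- balance_check(study[treated, ], study[control, ], matched,
                           c("age", "sex"))
  f_study <- file.path(out_dir, "study.csv")
  utils::write.csv(study, f_study, row.names = FALSE)
  f_coef <- file.path(out_dir, "logistic_models.csv")
  utils::write.csv(
    rbind(cbind(model = "outcome", outcome_model$wald),
          cbind(model = "treatment", treatment_model$wald)),
    f_coef, row.names = FALSE)
  f_pairs <- file.path(out_dir, "matched_pairs.csv")
  utils::write.csv(matched$pairs, f_pairs, row.names = FALSE)
  f_bal <- file.path(out_dir, "balance.csv")
  utils::write.csv(balance, f_bal, row.names = FALSE)
  .write_manifest(out_dir, "propensity", NULL, seed,
                  c(f_study, f_coef, f_pairs, f_bal))
  invisible(list(outcome_model = outcome_model,
                 treatment_model = treatment_model,
                 matched = matched, balance = balance))
}

#' Microsimulation report
#'
#' @inheritParams report_sweep
#' @param arm `"soc"` or `"purevu"`.
#' @param n Number of simulated patients.
#' @param seed Integer seed.
#' @return Invisibly, the `microsim_result`.
#' @export
report_simulate <- function(out_dir, arm = "soc", payer = "medicare",
                            n = 10000L, seed = 1L, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- .resolve_config(config, payer)
  strategy <- make_strategy(arm, payer, params)
  ms <- simulate_patients(params, strategy, n = n, seed = seed)
  f_freq <- file.path(out_dir, sprintf("microsim_state_freq_%s_%s.csv",
                                       arm, payer))
  utils::write.csv(
    data.frame(stage = seq_len(nrow(ms$state_freq)) - 1L, ms$state_freq,
               check.names = FALSE),
    f_freq, row.names = FALSE)
  f_pat <- file.path(out_dir, sprintf("microsim_patients_%s_%s.csv",
                                      arm, payer))
  utils::write.csv(
    data.frame(patient = seq_len(ms$n), cost = ms$cost, qaly = ms$qaly,
               ms$events),
    f_pat, row.names = FALSE)
  .write_manifest(out_dir, paste("simulate", arm), config, seed,
                  c(f_freq, f_pat))
  invisible(ms)
}
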