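#' Fit a logistic regression model to colonoscopy study records
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, as implemented by [stats::glm()] with a binomial family) of a
#' binary outcome on study covariates. Two uses share this machinery: the
#' outcome model (`success ~ age + sex + device_used + cecal_intubation`)
#' reported with Wald tests, and the treatment model
#' (`device_used ~ age + sex`) whose fitted probabilities are the
#' propensity scores used for matching.
#'
#' @param records Data frame of study records (see [generate_study()] for
#'   the column conventions: `age`, `sex`, `device_used`,
#'   `cecal_intubation`, `success`).
#' @param covariates Character vector of predictor column names.
#' @param outcome Name of the binary outcome column (default `"success"`).
#' @return An object of class `propensity_model`: `coefficients` (named,
#'   including `(Intercept)`), `vcov`, `converged`, `covariate_names`,
#'   `outcome`, `log_likelihood`, `null_log_likelihood`, and `wald` (data
#'   frame with estimate, SE, z, p per coefficient).
#' @export
#' @examples
#' set.seed(1)
#' d <- generate_study(study_spec(n = 500, seed = 1))
#' fit_logistic(d, c("age", "sex", "device_used", "cecal_intubation"))
fit_logistic <- function(records, covariates, outcome = "success") {
  if (nrow(records) < 10)
    stop("at least 10 records are required", call. = FALSE)
  missing_cols <- setdiff(c(covariates, outcome), names(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  y <- records[[outcome]]
  if (length(unique(y)) < 2)
    stop("outcome is constant; the model is degenerate", call. = FALSE)

  form <- stats::as.formula(
    paste(outcome, "~", paste(covariates, collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = records, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (separation || any(abs(stats::coef(fit)) > 20))
    stop("complete or quasi-complete separation detected; coefficients are ",
         "not identifiable", call. = FALSE)

  co <- stats::coef(fit)
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  z <- co / se
  null_ll <- as.numeric(
    stats::logLik(stats::glm(stats::as.formula(paste(outcome, "~ 1")),
                             data = records, family = stats::binomial())))
  structure(
    list(
      coefficients = co,
      vcov = V,
      converged = fit$converged,
      covariate_names = covariates,
      outcome = outcome,
      log_likelihood = as.numeric(stats::logLik(fit)),
      null_log_likelihood = null_ll,
      wald = data.frame(term = names(co), estimate = unname(co),
                        se = unname(se), z = unname(z),
                        p = unname(2 * stats::pnorm(-abs(z))))
    ),
    class = "propensity_model"
  )
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("<propensity_model> ", x$outcome, " ~ ",
      paste(x$covariate_names, collapse = " + "),
      if (!x$converged) "  (NOT converged)", "\n", sep = "")
  print(transform(x$wald, estimate = signif(estimate, 4),
                  se = signif(se, 3), z = round(z, 2), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Propensity / predicted-probability scores
#'
#' Applies the logistic inverse link to the linear predictor of a fitted
#' model, per record.
#'
#' @param model A converged `propensity_model`.
#' @param records Data frame carrying every model covariate.
#' @return Numeric vector of scores in `(0, 1)`.
#' @export
propensity_score <- function(model, records) {
  if (!model$converged)
    stop("model did not converge; scores are unreliable", call. = FALSE)
  missing_cols <- setdiff(model$covariate_names, names(records))
  if (length(missing_cols))
    stop("records lack covariate(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  X <- cbind(1, as.matrix(records[model$covariate_names]))
  eta <- as.numeric(X %*% model$coefficients)
  stats::plogis(eta)
}

#' Greedy 1:1 propensity-score matching within a caliper
#'
#' Nearest-neighbour matching on the logit of the propensity score: treated
#' units are processed in descending score order; each is paired with the
#' closest unused control within the caliper. Controls are used at most
#' once (matching without replacement).
#'
#' @param scores_treated,scores_control Propensity scores in `(0, 1)`.
#' @param caliper Maximum allowed |logit difference| within a pair. Default
#'   0.2 standard deviations of the pooled logit scores (the common
#'   convention).
#' @return An object of class `matched_set`: `pairs` (data frame `treated`,
#'   `control` of indices into the two score vectors, plus `distance`),
#'   `caliper`, `unmatched_treated`.
#' @export
#' @examples
#' match_scores(c(0.5, 0.6), c(0.52, 0.61, 0.9))
match_scores <- function(scores_treated, scores_control, caliper = NULL) {
  lt <- stats::qlogis(scores_treated)
  lc <- stats::qlogis(scores_control)
  if (is.null(caliper)) {
    caliper <- 0.2 * stats::sd(c(lt, lc))
    if (!is.finite(caliper) || caliper == 0) caliper <- 0.2
  }
  if (caliper <= 0) stop("caliper must be positive", call. = FALSE)

  order_t <- order(lt, decreasing = TRUE)
  used <- logical(length(lc))
  pairs <- vector("list", length(lt))
  n_pairs <- 0L
  for (ti in order_t) {
    d <- abs(lc - lt[ti])
    d[used] <- Inf
    ci <- which.min(d)
    if (length(ci) && is.finite(d[ci]) && d[ci] <= caliper) {
      used[ci] <- TRUE
      n_pairs <- n_pairs + 1L
      pairs[[n_pairs]] <- data.frame(treated = ti, control = ci,
                                     distance = d[ci])
    }
  }
  pairs <- if (n_pairs) do.call(rbind, pairs[seq_len(n_pairs)])
           else data.frame(treated = integer(), control = integer(),
                           distance = numeric())
  structure(
    list(pairs = pairs, caliper = caliper,
         unmatched_treated = length(lt) - n_pairs),
    class = "matched_set"
  )
}

#' @export
print.matched_set <- function(x, ...) {
  cat("<matched_set> ", nrow(x$pairs), " pairs, ",
      x$unmatched_treated, " treated unmatched (caliper ",
      signif(x$caliper, 3), " on the logit scale)\n", sep = "")
  invisible(x)
}

#' Covariate balance of a matched set
#'
#' Standardized mean differences over the matched units:
#' `(mean_treated - mean_control) / pooled SD`, the conventional balance
#' diagnostic after propensity matching.
#'
#' @param records_treated,records_control Data frames the score vectors
#'   were computed from (row order must match).
#' @param matched A `matched_set` over those score vectors.
#' @param covariates Covariate columns to check.
#' @return Data frame with `covariate`, `smd`, `degenerate` (`TRUE` where
#'   the pooled SD is zero and the SMD is reported as 0).
#' @export
balance_check <- function(records_treated, records_control, matched,
                          covariates) {
  if (nrow(matched$pairs) < 1)
    stop("at least one matched pair is required", call. = FALSE)
  t_rows <- records_treated[matched$pairs$treated, , drop = FALSE]
  c_rows <- records_control[matched$pairs$control, , drop = FALSE]
  out <- lapply(covariates, function(cv) {
    xt <- t_rows[[cv]]; xc <- c_rows[[cv]]
    pooled <- sqrt((stats::var(xt) + stats::var(xc)) / 2)
    if (!is.finite(pooled) || pooled == 0) {
      data.frame(covariate = cv, smd = 0, degenerate = TRUE)
    } else {
      data.frame(covariate = cv, smd = (mean(xt) - mean(xc)) / pooled,
                 degenerate = FALSE)
    }
  })
  do.call(rbind, out)
}
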