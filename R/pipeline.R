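# End-to-end feasibility driver: simulate -> fit -> validate -> match ->
# balance, with optional artifact files. Deterministic given the root seed.

#' Run the full design-feasibility pipeline on synthetic data
#'
#' Chains the five study stages: (1) simulate a retrospective development
#' cohort (seed offset 0); (2) apply the incident-user filter, drop
#' low-prevalence candidate predictors and fit the propensity model, freezing
#' its decile boundaries; (3) simulate a temporally distinct cohort (offset 2)
#' and validate the frozen model; (4) simulate a prospective arrival stream
#' (offset 1) and run the greedy decile/sex/caliper matcher; (5) assemble the
#' matched-sample balance report with the post-matching c-statistic. Every
#' stage is deterministic given the configuration seed.
#'
#' @param config A [sim_config()].
#' @param n_cases Referred cases in the prospective stream.
#' @param criteria A [match_criteria()].
#' @param covariates Covariate list for the propensity model; defaults to all
#'   configured covariates that survive [filter_low_prevalence()].
#' @param min_prevalence Low-prevalence threshold for candidate predictors.
#' @param out_dir Optional directory; when given, the cohorts, model, match
#'   table, close-out log, balance report and a stage summary are written as
#'   text artifacts.
#' @return A `pipeline_result` list with elements `model`, `validation`,
#'   `match_result`, `match_summary`, `balance`, `post_matching_c`, and
#'   `config`.
#' @export
#' @examples
#' res <- run_pipeline(sim_config(n_patients = 3000, seed = 5), n_cases = 20)
#' print(res)
run_pipeline <- function(config, n_cases = 100L, criteria = match_criteria(),
                         covariates = NULL, min_prevalence = 0.01,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  validate_sim_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  art <- function(name) if (is.null(out_dir)) NULL else file.path(out_dir, name)

  dev <- stage("simulate", simulate_development_cohort(config))
  dev <- stage("simulate", suppressMessages(incident_user_filter(dev)))
  if (!is.null(out_dir)) write_cohort(dev, art("development_cohort.csv"))

  candidates <- if (is.null(covariates)) {
    c(names(config$binary_prevalences), names(config$continuous_params))
  } else covariates
  kept <- stage("fit", filter_low_prevalence(dev, sort(candidates), min_prevalence))
  model <- stage("fit", fit_propensity(stats::reformulate(kept, "initiated"), dev))
  if (!is.null(out_dir)) write_model(model, art("propensity_model.json"))

  val_cohort <- stage("validate", simulate_development_cohort(config, seed_offset = 2L))
  validation <- stage("validate", temporal_validate(model, val_cohort))
  if (!is.null(out_dir)) {
    write_cohort(val_cohort, art("validation_cohort.csv"))
    write_report(validation$calibration, art("calibration.csv"))
  }

  stream <- stage("match", simulate_arrival_stream(config, n_cases = n_cases))
  matched <- stage("match", match_prospective(stream, model, criteria))
  msum <- match_summary(matched)
  if (!is.null(out_dir)) {
    write_cohort(stream, art("arrival_stream.csv"))
    write_report(matched$matches, art("matches.csv"))
    write_report(matched$log, art("match_log.csv"))
  }

  enrolled <- stream[stream$id %in% c(matched$matches$case_id,
                                      matched$matches$control_id), , drop = FALSE]
  balance <- if (nrow(matched$matches) > 0) {
    stage("balance", balance_report(enrolled, "referred", kept, refit_c = TRUE))
  } else NULL
  if (!is.null(out_dir) && !is.null(balance)) {
    write_report(balance, art("balance_report.csv"))
  }

  result <- structure(list(
    model = model,
    validation = validation,
    match_result = matched,
    match_summary = msum,
    balance = balance,
    post_matching_c = if (is.null(balance)) NA_real_
                      else attr(balance, "post_matching_c"),
    post_matching_c_frozen = if (nrow(matched$matches) > 0) {
      post_matching_c(enrolled, kept, method = "frozen", model = model)
    } else NA_real_,
    config = config,
    n_cases = n_cases
  ), class = "pipeline_result")
  if (!is.null(out_dir)) {
    utils::capture.output(print(result), file = art("summary.txt"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("== Development ==\n")
  cat("  cohort n:", x$model$fit_meta$n, " events:", x$model$fit_meta$events, "\n")
  cat("  development c-statistic:",
      format(x$model$fit_meta$c_statistic, digits = 4), "\n")
  cat("== Temporal validation ==\n")
  cat("  validation c-statistic:",
      format(x$validation$c_statistic, digits = 4), "\n")
  cat("  recalibration intercept/slope:",
      format(attr(x$validation$calibration, "recalibration_intercept"), digits = 3),
      "/",
      format(attr(x$validation$calibration, "recalibration_slope"), digits = 3),
      "\n")
  cat("== Prospective matching ==\n")
  print(x$match_summary)
  cat("== Balance ==\n")
  if (is.null(x$balance)) {
    cat("  no matched sample; balance not computed\n")
  } else {
    cat("  max |unadjusted SD| over PS covariates:",
        format(max(abs(x$balance$sd_unadjusted[
          x$balance$section == "propensity score"])), digits = 3), "\n")
    cat("  post-matching c-statistic (refit):",
        format(x$post_matching_c, digits = 4), "\n")
    cat("  post-matching c-statistic (frozen score):",
        format(x$post_matching_c_frozen, digits = 4), "\n")
  }
  invisible(x)
}
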