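# Discrimination and calibration diagnostics, including temporal validation of
# a frozen propensity model on a later cohort.

#' Concordance statistic (area under the ROC curve)
#'
#' Probability that a randomly chosen event receives a higher score than a
#' randomly chosen non-event, with ties counted half. Computed by the
#' Mann-Whitney rank formula, which equals the exhaustive all-pairs count.
#'
#' @param scores Numeric scores (higher = more event-like).
#' @param labels Binary 0/1 outcomes, at least one of each class.
#' @return The c-statistic, in \[0, 1\].
#' @export
#' @examples
#' c_statistic(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
c_statistic <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("input error: scores and labels differ in length")
  }
  if (anyNA(scores) || anyNA(labels)) stop("input error: missing values")
  if (!all(labels %in% c(0, 1))) stop("input error: labels must be binary 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("input error: need at least one event and one non-event")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration table with recalibration intercept and slope
#'
#' Summarizes agreement between predicted and observed event probabilities:
#' patients are cut into equal-count bins of predicted probability, and each
#' bin reports its size, mean prediction, and observed event fraction. A
#' logistic recalibration fit of the outcome on the linear predictor supplies
#' the calibration intercept (ideal 0) and slope (ideal 1).
#'
#' @param model A `propensity_model` (or a numeric vector of scores).
#' @param cohort Data frame holding the model covariates and outcome column
#'   (or, when `model` is a score vector, the binary outcomes).
#' @param n_bins Number of equal-count bins (default 10, minimum 2). Constant
#'   predictions collapse to a single effective bin.
#' @return A `calibration_table`: a data frame with columns `bin`, `n`,
#'   `mean_predicted`, `observed_fraction`, and attributes
#'   `recalibration_intercept` and `recalibration_slope`.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 5000, seed = 3)
#' cohort <- simulate_development_cohort(cfg)
#' m <- fit_propensity(initiated ~ pain_medication + age + anxiety, cohort)
#' calibration_table(m, cohort)
calibration_table <- function(model, cohort, n_bins = 10) {
  if (n_bins < 2) stop("input error: n_bins must be at least 2")
  if (inherits(model, "propensity_model")) {
    if (nrow(cohort) == 0) stop("input error: empty cohort")
    p <- as.numeric(predict(model, cohort))
    y <- cohort[[model$response]]
    if (is.null(y)) stop("input error: cohort lacks outcome column '",
                         model$response, "'")
  } else {
    p <- as.numeric(model)
    y <- cohort
    if (length(p) == 0) stop("input error: empty cohort")
  }
  if (stats::var(p) == 0) {
    bins <- rep(1L, length(p))
    slope <- NA_real_
    intercept <- NA_real_
  } else {
    bins <- ceiling(rank(p, ties.method = "first") * n_bins / length(p))
    recal <- stats::glm(y ~ stats::qlogis(p), family = stats::binomial())
    intercept <- unname(stats::coef(recal)[1])
    slope <- unname(stats::coef(recal)[2])
  }
  tab <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    sel <- bins == b
    data.frame(bin = b, n = sum(sel), mean_predicted = mean(p[sel]),
               observed_fraction = mean(y[sel]))
  }))
  structure(tab, class = c("calibration_table", "data.frame"),
            recalibration_intercept = intercept, recalibration_slope = slope)
}

#' @export
print.calibration_table <- function(x, ...) {
  cat("Calibration table (", nrow(x), " bins)\n", sep = "")
  print.data.frame(cbind(x[, c("bin", "n")],
                         round(x[, c("mean_predicted", "observed_fraction")], 4)),
                   row.names = FALSE)
  cat("recalibration intercept:",
      format(attr(x, "recalibration_intercept"), digits = 4),
      " slope:", format(attr(x, "recalibration_slope"), digits = 4), "\n")
  invisible(x)
}

#' Temporal validation of a frozen propensity model
#'
#' Scores a temporally distinct cohort with the frozen model (no refitting)
#' and reports its discrimination (c-statistic) and calibration. The drop
#' between the development and validation c-statistics measures how well the
#' score transports to future patients.
#'
#' @param model A fitted `propensity_model`.
#' @param later_cohort Data frame from a later period, carrying the model
#'   covariates and outcome column.
#' @param n_bins Bins for the calibration table.
#' @return A `temporal_validation` list with elements `c_statistic`,
#'   `calibration`, and `n`.
#' @export
temporal_validate <- function(model, later_cohort, n_bins = 10) {
  scores <- as.numeric(predict(model, later_cohort))
  y <- later_cohort[[model$response]]
  if (is.null(y)) {
    stop("input error: cohort lacks outcome column '", model$response, "'")
  }
  structure(list(
    c_statistic = c_statistic(scores, y),
    calibration = calibration_table(scores, y, n_bins),
    n = nrow(later_cohort),
    development_c = model$fit_meta$c_statistic
  ), class = "temporal_validation")
}

#' @export
print.temporal_validation <- function(x, ...) {
  cat("Temporal validation (n = ", x$n, ")\n", sep = "")
  cat("  development c-statistic:", format(x$development_c, digits = 4), "\n")
  cat("  validation  c-statistic:", format(x$c_statistic, digits = 4), "\n")
  print(x$calibration)
  invisible(x)
}
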