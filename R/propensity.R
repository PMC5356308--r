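# Propensity (treatment-initiation) model: maximum-likelihood logistic fit,
# frozen decile boundaries for transport, scoring of new patients.

#' Drop binary candidate predictors with very low prevalence
#'
#' Low-prevalence predictors yield imprecise coefficients that transport
#' poorly, so binary candidates whose minority-class prevalence falls below
#' `min_prevalence` are removed before fitting. Continuous candidates are
#' always retained; the rule is inclusive (a prevalence exactly at the
#' threshold is kept) and the input order is preserved.
#'
#' @param cohort Data frame of patients.
#' @param candidate_names Character vector of candidate covariate columns.
#' @param min_prevalence Minimum minority-class prevalence, in (0, 0.5).
#' @return The retained candidate names, in input order.
#' @export
#' @examples
#' d <- data.frame(rare = rep(c(1, 0), c(2, 998)), common = rbinom(1000, 1, 0.4))
#' filter_low_prevalence(d, c("rare", "common"), 0.01)
filter_low_prevalence <- function(cohort, candidate_names, min_prevalence = 0.01) {
  if (min_prevalence <= 0 || min_prevalence >= 0.5) {
    stop("input error: min_prevalence must lie in (0, 0.5)")
  }
  missing <- setdiff(candidate_names, names(cohort))
  if (length(missing) > 0) {
    stop("input error: unknown covariate name(s): ", paste(missing, collapse = ", "))
  }
  keep <- vapply(candidate_names, function(nm) {
    x <- cohort[[nm]]
    if (!all(x %in% c(0, 1))) return(TRUE)  # continuous: always retained
    p <- mean(x)
    min(p, 1 - p) >= min_prevalence
  }, logical(1))
  candidate_names[keep]
}

#' Fit a propensity score model
#'
#' Fits a maximum-likelihood logistic regression of treatment initiation on a
#' fixed, pre-specified covariate list (no data-driven variable selection; the
#' covariates are an explicit input via the formula) and freezes the decile
#' boundaries of the fitted probabilities over the development cohort, so the
#' score can later be transported: new patients are scored with the frozen
#' equation and assigned to the decile of the development score distribution
#' (deciles by rank of the observed distribution, not bands of absolute risk).
#'
#' Convergence follows iteratively reweighted least squares with a relative
#' deviance-change tolerance of 1e-10. Perfect separation and singular designs
#' are reported as errors rather than returned as degenerate fits. A small
#' optional ridge penalty is available to rescue separated fits.
#'
#' @param formula Model formula, e.g. `initiated ~ age + pain_medication`.
#' @param data Development cohort data frame; no missing values are allowed in
#'   the outcome or covariates.
#' @param ridge Nonnegative L2 penalty on the covariate coefficients
#'   (default 0 = plain maximum likelihood).
#' @return An object of class `propensity_model` with components
#'   `coefficients`, `covariate_names`, `decile_boundaries` (9 ascending
#'   probabilities), `fitted` (development-cohort scores), and `fit_meta`
#'   (cohort size, event count, convergence, deviance, apparent c-statistic).
#' @seealso [predict.propensity_model()], [decile_of()], [temporal_validate()]
#' @export
#' @examples
#' cohort <- simulate_development_cohort(sim_config(n_patients = 2000, seed = 1))
#' m <- fit_propensity(initiated ~ pain_medication + anxiety + age, cohort)
#' coef(m)
#' m$decile_boundaries
fit_propensity <- function(formula, data, ridge = 0) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (anyNA(y) || anyNA(X)) stop("fit error: missing values in outcome or covariates")
  if (!all(y %in% c(0, 1))) stop("fit error: outcome must be binary 0/1")
  if (sum(y) < 1 || sum(1 - y) < 1) {
    stop("fit error: need at least one event and one non-event")
  }
  if (qr(X)$rank < ncol(X)) {
    stop("fit error: singular design matrix (collinear covariates)")
  }

  if (ridge > 0) {
    fit <- .ridge_logistic(X, y, ridge)
    beta <- fit$coefficients
    fitted <- as.numeric(stats::plogis(X %*% beta))
    converged <- fit$converged
    deviance <- fit$deviance
    iter <- fit$iter
  } else {
    warned_sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          warned_sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    beta <- fit$coefficients
    if (warned_sep && max(abs(beta[-1])) > 10) {
      culprit <- names(which.max(abs(beta[-1])))
      stop("fit error: perfect (or quasi-perfect) separation; ",
           "covariate '", culprit, "' separates the groups")
    }
    fitted <- fit$fitted.values
    converged <- fit$converged
    deviance <- fit$deviance
    iter <- fit$iter
  }

  tt <- stats::delete.response(stats::terms(formula, data = data))
  boundaries <- unname(stats::quantile(fitted, probs = (1:9) / 10, type = 2))
  w <- pmax(fitted * (1 - fitted), 1e-12)
  std_errors <- tryCatch(
    sqrt(diag(solve(crossprod(X, w * X)))),
    error = function(e) rep(NA_real_, length(beta))
  )
  names(std_errors) <- names(beta)
  attr(fitted, "y") <- as.numeric(y)
  structure(list(
    coefficients = beta,
    std_errors = std_errors,
    covariate_names = attr(stats::terms(formula, data = data), "term.labels"),
    decile_boundaries = boundaries,
    fitted = fitted,
    response = all.vars(formula)[1],
    terms = tt,
    formula = formula,
    fit_meta = list(
      n = length(y), events = sum(y), converged = converged,
      deviance = deviance, iterations = iter, ridge = ridge,
      c_statistic = c_statistic(fitted, y)
    )
  ), class = "propensity_model")
}

# Penalised IRLS with an L2 penalty on all non-intercept coefficients.
.ridge_logistic <- function(X, y, lambda, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / pmax(w, 1e-12)
    beta <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    dev <- -2 * sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
    if (abs(dev - dev_old) / (abs(dev) + 0.1) < tol) break
    dev_old <- dev
  }
  list(coefficients = stats::setNames(as.numeric(beta), colnames(X)),
       converged = it < maxit, deviance = dev, iter = it)
}

#' Score patients with a fitted propensity model
#'
#' Computes the modeled probability of treatment initiation for new patients
#' from the frozen coefficients (inverse logit of the linear predictor).
#'
#' @param object A `propensity_model`.
#' @param newdata Data frame carrying every model covariate; if omitted, the
#'   development-cohort fitted scores are returned.
#' @param type `"response"` for probabilities (default) or `"link"` for the
#'   linear predictor.
#' @param ... Unused.
#' @return Numeric vector of scores, strictly inside (0, 1) for `"response"`.
#' @export
predict.propensity_model <- function(object, newdata = NULL,
                                     type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- stats::qlogis(object$fitted)
  } else {
    needed <- all.vars(object$terms)
    missing <- setdiff(needed, names(newdata))
    if (length(missing) > 0) {
      stop("input error: patient data lacks model covariate(s): ",
           paste(missing, collapse = ", "))
    }
    if (anyNA(newdata[needed])) stop("input error: missing covariate values")
    X <- stats::model.matrix(object$terms, newdata)
    eta <- as.numeric(X %*% object$coefficients)
  }
  if (type == "link") return(eta)
  # keep responses strictly inside (0, 1) at double precision
  pmin(pmax(stats::plogis(eta), .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' @rdname predict.propensity_model
#' @param model A `propensity_model`.
#' @param patients Data frame of patients to score.
#' @export
score <- function(model, patients) predict(model, patients, type = "response")

#' Map a propensity probability to its frozen development decile
#'
#' Deciles are defined by the observed development-score distribution: the 9
#' frozen interior boundaries plus virtual boundaries 0 and 1 partition (0,1)
#' into 10 right-closed intervals, and a probability exactly on a boundary
#' falls in the lower decile.
#'
#' @param model A `propensity_model` with frozen `decile_boundaries`.
#' @param probability Numeric vector of probabilities in (0, 1).
#' @return Integer decile indices in 1..10.
#' @export
#' @examples
#' cohort <- simulate_development_cohort(sim_config(n_patients = 2000, seed = 1))
#' m <- fit_propensity(initiated ~ pain_medication + age, cohort)
#' decile_of(m, c(0.001, 0.5))
decile_of <- function(model, probability) {
  if (is.null(model$decile_boundaries)) {
    stop("state error: model has no frozen decile boundaries")
  }
  if (any(probability <= 0 | probability >= 1)) {
    stop("input error: probabilities must lie strictly in (0, 1)")
  }
  as.integer(findInterval(probability, model$decile_boundaries, left.open = TRUE) + 1L)
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity score model (logistic)\n")
  cat("  development cohort:", x$fit_meta$n, "patients,",
      x$fit_meta$events, "events\n")
  cat("  covariates:", length(x$covariate_names), "\n")
  cat("  apparent c-statistic:", format(x$fit_meta$c_statistic, digits = 4), "\n")
  cat("  decile boundaries (frozen):\n")
  print(signif(x$decile_boundaries, 4))
  invisible(x)
}

#' @export
summary.propensity_model <- function(object, ...) {
  structure(list(
    coefficients = object$coefficients,
    std_errors = object$std_errors,
    fit_meta = object$fit_meta,
    decile_boundaries = object$decile_boundaries,
    decile_counts = tabulate(decile_of(object, pmin(pmax(object$fitted, 1e-15),
                                                    1 - 1e-15)), 10)
  ), class = "summary.propensity_model")
}

#' @export
print.summary.propensity_model <- function(x, ...) {
  cat("Propensity score model summary\n\nCoefficients (log-odds):\n")
  tab <- cbind(estimate = x$coefficients, std_error = x$std_errors,
               z = x$coefficients / x$std_errors)
  print(signif(tab, 4))
  cat("\nDevelopment decile occupancy:\n")
  print(stats::setNames(x$decile_counts, paste0("d", 1:10)))
  cat("\nApparent c-statistic:", format(x$fit_meta$c_statistic, digits = 4),
      " deviance:", format(x$fit_meta$deviance, digits = 6), "\n")
  invisible(x)
}

#' @export
coef.propensity_model <- function(object, ...) object$coefficients

#' Plot the development score distribution by treatment group
#'
#' Histograms of the fitted propensity scores for initiators and
#' non-initiators on a common log-odds axis, with the frozen decile
#' boundaries overlaid.
#'
#' @param x A `propensity_model`.
#' @param y,... Unused / passed to [graphics::hist()].
#' @export
plot.propensity_model <- function(x, y, ...) {
  lp <- stats::qlogis(x$fitted)
  grp <- attr(x$fitted, "y")
  brk <- seq(min(lp), max(lp), length.out = 41)
  graphics::hist(lp, breaks = brk, col = "grey85", border = "white",
                 main = "Development propensity score distribution",
                 xlab = "linear predictor (log-odds of initiation)", ...)
  graphics::abline(v = stats::qlogis(x$decile_boundaries), col = "steelblue", lty = 3)
  invisible(x)
}

#' Simulate initiation outcomes from a fitted propensity model
#'
#' Draws Bernoulli initiation indicators at the modeled probabilities, either
#' for the development cohort or for new patients.
#'
#' @param object A `propensity_model`.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional seed.
#' @param newdata Optional data frame of patients to simulate for.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of 0/1 outcomes.
#' @export
simulate.propensity_model <- function(object, nsim = 1, seed = NULL,
                                      newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, newdata)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Residuals of a propensity model
#'
#' @param object A `propensity_model`.
#' @param type `"response"` (observed minus fitted) or `"pearson"`.
#' @param ... Unused.
#' @export
residuals.propensity_model <- function(object,
                                       type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  y <- attr(object$fitted, "y")
  if (is.null(y)) stop("state error: development outcomes not retained")
  r <- y - object$fitted
  if (type == "pearson") r / sqrt(object$fitted * (1 - object$fitted)) else r
}

#' Serialize a propensity model to a portable text artifact
#'
#' Writes the frozen model (covariate names, coefficients, decile boundaries,
#' formula, fit metadata) as JSON at full double precision, so a round trip
#' through [read_model()] is lossless to 15 significant digits.
#'
#' @param model A `propensity_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    artifact = "propensity_model",
    formula = paste(deparse(model$formula), collapse = " "),
    response = model$response,
    covariate_names = model$covariate_names,
    coefficient_names = names(model$coefficients),
    coefficients = unname(model$coefficients),
    decile_boundaries = model$decile_boundaries,
    fit_meta = model$fit_meta
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized propensity model
#'
#' @param path Path to a JSON artifact written by [write_model()].
#' @return A `propensity_model` (without development-cohort fitted scores).
#' @export
read_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) NULL)
  if (!identical(payload$artifact, "propensity_model")) {
    stop("input error: ", path, " is not a serialized propensity model")
  }
  formula <- stats::as.formula(payload$formula)
  structure(list(
    coefficients = stats::setNames(payload$coefficients, payload$coefficient_names),
    covariate_names = payload$covariate_names,
    decile_boundaries = payload$decile_boundaries,
    fitted = NULL,
    response = payload$response,
    terms = stats::delete.response(stats::terms(formula)),
    formula = formula,
    fit_meta = payload$fit_meta
  ), class = "propensity_model")
}
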