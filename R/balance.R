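# Covariate balance diagnostics: standardized differences (arcsine scale for
# binary covariates, pooled-SD scale for continuous), decile-adjusted
# standardized differences, and the post-matching c-statistic.

#' Standardized difference for a binary covariate
#'
#' Arcsine-scale standardized difference between two group prevalences,
#' `2 * (arcsin(sqrt(P1)) - arcsin(sqrt(P2)))` in radians, positive when group
#' 1 (treated/referred) has the larger prevalence.
#'
#' @param p1,p2 Group prevalences in \[0, 1\] (group 1 = treated/referred).
#' @return The standardized difference.
#' @export
#' @examples
#' sd_binary(0.250, 0.111)  # ~0.368
sd_binary <- function(p1, p2) {
  if (any(c(p1, p2) < 0 | c(p1, p2) > 1)) {
    stop("input error: proportions must lie in [0, 1]")
  }
  2 * (asin(sqrt(p1)) - asin(sqrt(p2)))
}

#' Standardized difference for a continuous covariate
#'
#' Difference in group means divided by the pooled standard deviation. The
#' default pooling is the unweighted root-mean-square of the two group SDs,
#' `sqrt((sd1^2 + sd2^2) / 2)`; sample-size-weighted pooling is available via
#' `weighted = TRUE`.
#'
#' @param mean1,sd1,n1 Mean, SD and size of group 1 (treated/referred).
#' @param mean2,sd2,n2 Mean, SD and size of group 2. `n1`/`n2` are only used
#'   for weighted pooling.
#' @param weighted Use (n-1)-weighted pooled SD instead of the equal-weight
#'   form.
#' @return The standardized difference.
#' @export
#' @examples
#' sd_continuous(53.8, 14.0, 55.2, 15.0)  # ~ -0.097
sd_continuous <- function(mean1, sd1, mean2, sd2, n1 = NULL, n2 = NULL,
                          weighted = FALSE) {
  if (sd1 < 0 || sd2 < 0) stop("input error: standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) return(0)
    stop("input error: both SDs zero with unequal means; ",
         "standardized difference undefined")
  }
  pooled <- if (weighted) {
    if (is.null(n1) || is.null(n2)) {
      stop("input error: weighted pooling needs n1 and n2")
    }
    sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  } else {
    sqrt((sd1^2 + sd2^2) / 2)
  }
  (mean1 - mean2) / pooled
}

#' Stratum-adjusted standardized difference
#'
#' Standardized difference after stratification (typically on propensity-score
#' deciles), reported on the unadjusted scale so adjusted and unadjusted
#' values are directly comparable. For a continuous covariate the
#' stratum-size-weighted mean of within-stratum mean differences is divided by
#' the unadjusted pooled SD; for a binary covariate the stratum-weighted
#' adjusted prevalences are combined with the arcsine formula. Strata in which
#' a group is absent are dropped with a warning.
#'
#' @param x Covariate values (patient level).
#' @param group Binary indicator, 1 = treated/referred.
#' @param strata Stratum labels (e.g. propensity deciles).
#' @param type `"auto"` detects binary (values all 0/1), or force
#'   `"binary"`/`"continuous"`.
#' @param weights `"total"` (stratum share of the whole sample, default) or
#'   `"treated"` (stratum share of the treated group).
#' @return The adjusted standardized difference.
#' @export
#' @examples
#' x <- c(1, 0, 1, 0, 1, 1, 0, 0)
#' g <- c(1, 1, 0, 0, 1, 1, 0, 0)
#' s <- c(1, 1, 1, 1, 2, 2, 2, 2)
#' sd_adjusted(x, g, s)
sd_adjusted <- function(x, group, strata, type = c("auto", "binary", "continuous"),
                        weights = c("total", "treated")) {
  type <- match.arg(type)
  weights <- match.arg(weights)
  if (length(x) != length(group) || length(x) != length(strata)) {
    stop("input error: x, group and strata differ in length")
  }
  if (type == "auto") type <- if (all(x %in% c(0, 1))) "binary" else "continuous"

  levs <- sort(unique(strata))
  ok <- vapply(levs, function(s) {
    sel <- strata == s
    any(group[sel] == 1) && any(group[sel] == 0)
  }, logical(1))
  if (any(!ok)) {
    warning("dropping ", sum(!ok), " stratum/strata with a group absent")
    levs <- levs[ok]
  }
  if (length(levs) == 0) stop("input error: no stratum contains both groups")
  keep <- strata %in% levs

  w <- vapply(levs, function(s) {
    if (weights == "total") sum(strata[keep] == s) / sum(keep)
    else sum(strata[keep] == s & group[keep] == 1) / sum(group[keep] == 1)
  }, numeric(1))

  m <- function(s, g) mean(x[keep][strata[keep] == s & group[keep] == g])
  if (type == "binary") {
    p1 <- sum(w * vapply(levs, m, numeric(1), g = 1))
    p2 <- sum(w * vapply(levs, m, numeric(1), g = 0))
    sd_binary(min(max(p1, 0), 1), min(max(p2, 0), 1))
  } else {
    diff_adj <- sum(w * (vapply(levs, m, numeric(1), g = 1) -
                         vapply(levs, m, numeric(1), g = 0)))
    # unadjusted-scale denominator, from the full (unstratified) groups
    s1 <- stats::sd(x[group == 1])
    s2 <- stats::sd(x[group == 0])
    diff_adj / sqrt((s1^2 + s2^2) / 2)
  }
}

#' Post-matching c-statistic
#'
#' Overall balance diagnostic for a matched sample: the propensity model (same
#' covariate list) is refit on the matched patients only and its apparent
#' c-statistic is returned. Values near 0.5 indicate the matched groups are
#' indistinguishable on the covariates; values near 1 indicate gross residual
#' imbalance. A separated refit (one covariate splits the groups perfectly) is
#' reported as maximal imbalance (1.0) with a warning rather than an error.
#'
#' The in-sample refit carries optimism: with `p` covariates it sits above 0.5
#' even for perfectly balanced groups, by roughly `0.1 * sqrt(523 * p / 16 / n)`
#' for study-sized samples, so small matched samples report values well above
#' 0.5 regardless of balance. `method = "frozen"` instead computes the
#' c-statistic of an already-fitted transported score on the matched sample (a
#' one-degree-of-freedom diagnostic with negligible optimism); it requires
#' `model`.
#'
#' @param matched Data frame of matched patients.
#' @param covariate_names Covariates of the propensity model.
#' @param group_var Column with the binary group indicator
#'   (default `"referred"`).
#' @param method `"refit"` (default): apparent c of the refit propensity model;
#'   `"frozen"`: c of the frozen transported score.
#' @param model The frozen `propensity_model`, required for
#'   `method = "frozen"`.
#' @return The post-matching c-statistic in \[0.5, 1\] up to sampling noise.
#' @export
post_matching_c <- function(matched, covariate_names, group_var = "referred",
                            method = c("refit", "frozen"), model = NULL) {
  method <- match.arg(method)
  if (is.null(matched[[group_var]])) {
    stop("input error: matched sample lacks group column '", group_var, "'")
  }
  missing <- setdiff(covariate_names, names(matched))
  if (length(missing) > 0) {
    stop("input error: matched sample lacks covariate(s): ",
         paste(missing, collapse = ", "))
  }
  if (method == "frozen") {
    if (is.null(model)) stop("input error: method 'frozen' needs the model")
    return(c_statistic(as.numeric(predict(model, matched)), matched[[group_var]]))
  }
  f <- stats::reformulate(covariate_names, response = group_var)
  fit <- tryCatch(fit_propensity(f, matched), error = function(e) e)
  if (inherits(fit, "error")) {
    if (grepl("separation", conditionMessage(fit))) {
      warning("post-matching refit separated: reporting maximal imbalance (1.0); ",
              conditionMessage(fit))
      return(1.0)
    }
    stop(fit)
  }
  fit$fit_meta$c_statistic
}

#' Assemble a covariate balance report
#'
#' One row per covariate with group summaries, the unadjusted standardized
#' difference, and (when a stratum column is supplied) the decile-adjusted
#' standardized difference on the unadjusted scale. Covariates are sectioned
#' into those that entered the propensity score and others examined for
#' residual confounding. Flags mark |SD| > 0.1 and > 0.05.
#'
#' @param data Data frame (a matched sample or a full cohort).
#' @param group_var Binary group column, 1 = treated/referred.
#' @param ps_covariates Covariates in the propensity model.
#' @param other_covariates Covariates outside the model (optional).
#' @param strata Optional stratum labels (e.g. `decile_of(model, score(...))`)
#'   aligned with `data`; enables the adjusted column.
#' @param refit_c Also compute the post-matching c-statistic over
#'   `ps_covariates` (default FALSE).
#' @return A `balance_report` data frame with attribute `post_matching_c` when
#'   requested.
#' @export
balance_report <- function(data, group_var, ps_covariates,
                           other_covariates = character(0), strata = NULL,
                           refit_c = FALSE) {
  all_cov <- c(ps_covariates, other_covariates)
  if (anyDuplicated(all_cov)) {
    stop("input error: covariate name collision between sections: ",
         paste(unique(all_cov[duplicated(all_cov)]), collapse = ", "))
  }
  missing <- setdiff(c(all_cov, group_var), names(data))
  if (length(missing) > 0) {
    stop("input error: data lacks column(s): ", paste(missing, collapse = ", "))
  }
  g <- data[[group_var]]
  rows <- lapply(all_cov, function(nm) {
    x <- data[[nm]]
    binary <- all(x %in% c(0, 1))
    x1 <- x[g == 1]; x2 <- x[g == 0]
    sd_un <- if (binary) sd_binary(mean(x1), mean(x2))
             else sd_continuous(mean(x1), stats::sd(x1), mean(x2), stats::sd(x2))
    sd_adj <- if (is.null(strata)) NA_real_ else sd_adjusted(x, g, strata)
    data.frame(
      covariate = nm,
      section = if (nm %in% ps_covariates) "propensity score" else "other",
      type = if (binary) "binary" else "continuous",
      summary1 = mean(x1), summary2 = mean(x2),
      sd_unadjusted = sd_un, sd_adjusted = sd_adj,
      flag_0.1 = abs(sd_un) > 0.1, flag_0.05 = abs(sd_un) > 0.05,
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    covariate = character(0), section = character(0), type = character(0),
    summary1 = numeric(0), summary2 = numeric(0),
    sd_unadjusted = numeric(0), sd_adjusted = numeric(0),
    flag_0.1 = logical(0), flag_0.05 = logical(0), stringsAsFactors = FALSE)
  out <- out[order(match(out$section, c("propensity score", "other"))), ]
  rownames(out) <- NULL
  pmc <- if (refit_c) post_matching_c(data, ps_covariates, group_var) else NA_real_
  structure(out, class = c("balance_report", "data.frame"),
            post_matching_c = pmc,
            n1 = sum(g == 1), n2 = sum(g == 0))
}

#' @export
print.balance_report <- function(x, digits = 3, ...) {
  cat("Covariate balance report (group 1: n = ", attr(x, "n1"),
      ", group 2: n = ", attr(x, "n2"), ")\n", sep = "")
  shown <- x
  num <- c("summary1", "summary2", "sd_unadjusted", "sd_adjusted")
  shown[num] <- lapply(shown[num], round, digits = digits)
  for (sec in unique(shown$section)) {
    cat("\n-- ", sec, " covariates --\n", sep = "")
    print.data.frame(
      shown[shown$section == sec,
            c("covariate", "type", "summary1", "summary2",
              "sd_unadjusted", "sd_adjusted")],
      row.names = FALSE)
  }
  if (!is.na(attr(x, "post_matching_c"))) {
    cat("\npost-matching c-statistic:",
        format(attr(x, "post_matching_c"), digits = 4), "\n")
  }
  invisible(x)
}
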