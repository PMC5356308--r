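# Delimited-text I/O for patient cohorts. Text formats keep every artifact
# auditable; round trips are lossless to 15 significant digits.

.required_cohort_columns <- function() {
  c("id", "sex", "referred", "initiated", "pain_score", "days_since_pain_visit")
}

#' Write a patient cohort as delimited text
#'
#' Comma-separated, header row, UTF-8, "." decimal. Column order is enforced
#' as: `id`, `sex`, `referred`, `initiated`, `pain_score`,
#' `days_since_pain_visit`, covariates in alphabetical order, then eligibility
#' flags; unknown extra columns are preserved after those.
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  req <- .required_cohort_columns()
  missing <- setdiff(req, names(cohort))
  if (length(missing) > 0) {
    stop("schema error: cohort lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  flags <- intersect(names(.default_exclusion_rates()), names(cohort))
  covs <- sort(setdiff(names(cohort), c(req, flags, "arrival")))
  extra <- intersect("arrival", names(cohort))
  out <- cohort[, c(req, covs, flags, extra), drop = FALSE]
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) {
    # as.character keeps 15 significant digits for doubles
    format(x, digits = 15, trim = TRUE, scientific = FALSE)
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a patient cohort from delimited text
#'
#' Validates the schema written by [write_cohort()]: required columns present,
#' `pain_score` an integer in 0..10, flags and treatment indicators 0/1.
#' Malformed rows are reported with their line number (header = line 1).
#'
#' @param path Path to a cohort CSV.
#' @return Cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  req <- .required_cohort_columns()
  missing <- setdiff(req, names(cohort))
  if (length(missing) > 0) {
    stop("schema error: ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(cohort) == 0) return(cohort)
  bad <- which(is.na(cohort$pain_score) | cohort$pain_score < 0 |
               cohort$pain_score > 10 | cohort$pain_score %% 1 != 0)
  if (length(bad) > 0) {
    stop("validation error: pain_score out of range 0..10 at line ",
         paste(bad + 1L, collapse = ", "))
  }
  for (col in c("referred", "initiated")) {
    bad <- which(!(cohort[[col]] %in% c(0, 1)))
    if (length(bad) > 0) {
      stop("validation error: ", col, " not 0/1 at line ",
           paste(bad + 1L, collapse = ", "))
    }
  }
  cohort
}

#' Write a balance (or any tabular) report as delimited text
#'
#' @param report A data frame (e.g. a `balance_report`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
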