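# Prospective enrollment matcher: screen arriving patients for eligibility and
# greedily match referred cases to non-referred controls on frozen propensity
# decile, sex, and a patient-reported pain-score caliper, without replacement.

# Screening exclusions in reporting order. `flag` is the cohort column; the
# pain criterion is score-based and has no flag.
.exclusion_catalog <- function() {
  data.frame(
    flag = c("cancer", "dementia", "psychoses", "hospice", "declined",
             NA, "non_persistent_pain", "already_started",
             "prior_acupuncture_6mo", "pregnant", "moving"),
    reason = c("cancer", "dementia", "psychoses", "hospice",
               "declined screening", "pain bothersomeness < 4",
               "non-persistent pain", "already started acupuncture",
               "recent acupuncture use", "pregnant", "moving out of area"),
    stringsAsFactors = FALSE
  )
}

#' Matching criteria for prospective enrollment
#'
#' @param caliper_pain Maximum allowed absolute difference in the 0-10 pain
#'   bothersomeness score between case and control (default 2 points).
#' @param controls_per_case Target number of controls per case (default 2).
#' @param max_screened_per_case Maximum number of same-decile candidates
#'   screened per case (default 15).
#' @param require_same_sex Require case and control to share sex (default on).
#' @param require_same_decile Require the frozen propensity decile to match
#'   (default on).
#' @param exact_ratio Discard partially matched cases (those that found fewer
#'   than `controls_per_case` controls) instead of keeping them (default off).
#' @return A validated `match_criteria` list.
#' @export
match_criteria <- function(caliper_pain = 2, controls_per_case = 2,
                           max_screened_per_case = 15,
                           require_same_sex = TRUE, require_same_decile = TRUE,
                           exact_ratio = FALSE) {
  if (caliper_pain < 0) stop("input error: caliper_pain must be >= 0")
  if (controls_per_case < 1) stop("input error: controls_per_case must be >= 1")
  if (max_screened_per_case < controls_per_case) {
    stop("input error: max_screened_per_case must be >= controls_per_case")
  }
  structure(list(caliper_pain = caliper_pain,
                 controls_per_case = as.integer(controls_per_case),
                 max_screened_per_case = as.integer(max_screened_per_case),
                 require_same_sex = isTRUE(require_same_sex),
                 require_same_decile = isTRUE(require_same_decile),
                 exact_ratio = isTRUE(exact_ratio)),
            class = "match_criteria")
}

# Vectorized screening: returns a character vector, "" when eligible,
# otherwise the first exclusion reason in reporting order.
.screen_first_reason <- function(cohort) {
  cat_ <- .exclusion_catalog()
  missing <- setdiff(stats::na.omit(cat_$flag), names(cohort))
  if (length(missing) > 0) {
    stop("input error: missing eligibility flag(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(cohort$pain_score)) stop("input error: missing pain_score")
  reason <- character(nrow(cohort))
  for (i in rev(seq_len(nrow(cat_)))) {
    hit <- if (is.na(cat_$flag[i])) cohort$pain_score < 4 else cohort[[cat_$flag[i]]] == 1
    reason[hit] <- cat_$reason[i]
  }
  reason
}

#' Screen one arriving patient for study eligibility
#'
#' A patient screens eligible when the pain bothersomeness score is at least 4
#' and every exclusion flag (registry exclusions, declined screening,
#' non-persistent pain, already-started or recent acupuncture, pregnancy,
#' planned move) is zero. Declining to be screened is itself an exclusion.
#'
#' @param patient A one-row data frame (or list coercible to one) with
#'   `pain_score` and all eligibility flags.
#' @return A list with `eligible` (logical) and `reasons` (character vector of
#'   all failed exclusions, in reporting order; empty when eligible).
#' @export
#' @examples
#' stream <- simulate_arrival_stream(sim_config(seed = 1), n_cases = 2)
#' screen_eligibility(stream[1, ])
screen_eligibility <- function(patient) {
  patient <- as.data.frame(patient)
  if (nrow(patient) != 1) stop("input error: screen one patient at a time")
  cat_ <- .exclusion_catalog()
  missing <- setdiff(stats::na.omit(cat_$flag), names(patient))
  if (length(missing) > 0) {
    stop("input error: missing eligibility flag(s): ",
         paste(missing, collapse = ", "))
  }
  hits <- vapply(seq_len(nrow(cat_)), function(i) {
    if (is.na(cat_$flag[i])) patient$pain_score < 4 else patient[[cat_$flag[i]]] == 1
  }, logical(1))
  list(eligible = !any(hits), reasons = cat_$reason[hits])
}

#' Restrict a cohort to incident (new) treatment users
#'
#' A valid propensity score at treatment start requires incident users, so
#' patients with recent (six-month) prior referral for or use of the treatment
#' are removed before model development.
#'
#' @param cohort Data frame with a `prior_acupuncture_6mo` flag.
#' @return The cohort without flagged patients; the number removed is reported
#'   via `message()`, and an empty result raises a warning.
#' @export
incident_user_filter <- function(cohort) {
  if (is.null(cohort$prior_acupuncture_6mo)) {
    stop("input error: cohort lacks the prior_acupuncture_6mo flag")
  }
  flagged <- cohort$prior_acupuncture_6mo == 1
  message("incident-user filter removed ", sum(flagged), " of ", nrow(cohort),
          " patients")
  out <- cohort[!flagged, , drop = FALSE]
  if (nrow(out) == 0) warning("incident-user filter removed every patient")
  out
}

#' Match referred cases to controls in an arrival stream
#'
#' Executes the prospective two-step match in arrival order (greedy, no
#' re-optimization, without replacement). For each eligible referred case, the
#' pool of same-decile, not-yet-consumed candidates is drawn in arrival order
#' up to `max_screened_per_case`; each drawn candidate is screened for
#' eligibility and checked against the sex and pain-score caliper criteria.
#' Among surviving candidates, controls are chosen by the most recent pain
#' visit (ascending `days_since_pain_visit`, ties broken by earlier arrival)
#' up to `controls_per_case`. Consumed controls are retired for later cases,
#' and so are candidates who screened ineligible (their exclusion is
#' patient-level and permanent); screened-but-surplus candidates, and
#' candidates who merely failed the case-specific sex or caliper check, remain
#' available. Cases with no usable candidate are reported unmatched, never an
#' error.
#'
#' @param stream Data frame from [simulate_arrival_stream()] (or the same
#'   schema), ordered by arrival.
#' @param model A `propensity_model` with frozen decile boundaries.
#' @param criteria A [match_criteria()].
#' @return A `match_result` list: `matches` (one row per case-control pair),
#'   `match_sets` (per-case records), `unmatched` (case ids with no control),
#'   `ineligible_cases`, `log` (close-out log), and `criteria`.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 4000, seed = 11)
#' dev <- simulate_development_cohort(cfg)
#' m <- fit_propensity(initiated ~ pain_medication + age + anxiety, dev)
#' res <- match_prospective(simulate_arrival_stream(cfg, n_cases = 10), m)
#' summary(res)
match_prospective <- function(stream, model, criteria = match_criteria()) {
  stopifnot(inherits(criteria, "match_criteria"))
  stream <- stream[order(if (is.null(stream$arrival)) seq_len(nrow(stream))
                         else stream$arrival), , drop = FALSE]
  n <- nrow(stream)
  scores <- if (n > 0) as.numeric(predict(model, stream)) else numeric(0)
  deciles <- if (n > 0) decile_of(model, pmin(pmax(scores, 1e-15), 1 - 1e-15))
             else integer(0)
  screen_reason <- if (n > 0) .screen_first_reason(stream) else character(0)

  case_idx <- which(stream$referred == 1)
  cand_idx <- which(stream$referred == 0)
  consumed <- logical(n)

  log_case <- list(); log_cand <- list(); log_action <- list()
  log_reason <- list(); log_n <- list()
  push <- function(case_id, cand_id, action, reason, count = 1L) {
    i <- length(log_case) + 1L
    log_case[[i]] <<- case_id; log_cand[[i]] <<- cand_id
    log_action[[i]] <<- action; log_reason[[i]] <<- reason
    log_n[[i]] <<- as.integer(count)
  }

  match_sets <- list()
  matches <- list()
  unmatched <- character(0)
  ineligible_cases <- character(0)

  # Per-decile candidate queues in arrival order, with a head pointer advanced
  # past consumed candidates, keep the per-case pool draw O(cap) amortized.
  cand_by_dec <- lapply(1:10, function(d) cand_idx[deciles[cand_idx] == d])
  ptr <- rep(1L, 10)
  unconsumed_in_dec <- vapply(cand_by_dec, length, integer(1))
  total_unconsumed <- length(cand_idx)

  first_unconsumed <- function(d, k) {
    q <- cand_by_dec[[d]]
    i <- ptr[d]
    while (i <= length(q) && consumed[q[i]]) i <- i + 1L
    ptr[d] <<- i
    out <- integer(0)
    while (i <= length(q) && length(out) < k) {
      if (!consumed[q[i]]) out <- c(out, q[i])
      i <- i + 1L
    }
    out
  }

  for (ci in case_idx) {
    cid <- stream$id[ci]
    if (nzchar(screen_reason[ci])) {
      ineligible_cases <- c(ineligible_cases, cid)
      push(cid, cid, "case_excluded", screen_reason[ci])
      next
    }
    if (criteria$require_same_decile) {
      d <- deciles[ci]
      pool <- first_unconsumed(d, criteria$max_screened_per_case)
      n_wrong <- total_unconsumed - unconsumed_in_dec[d]
      if (n_wrong > 0) push(cid, NA_character_, "never_screened", "wrong decile",
                            as.integer(n_wrong))
      n_over <- unconsumed_in_dec[d] - length(pool)
      if (n_over > 0) push(cid, NA_character_, "never_screened",
                           "exceeded screening cap", as.integer(n_over))
    } else {
      pool <- cand_idx[!consumed[cand_idx]]
      if (length(pool) > criteria$max_screened_per_case) {
        n_over <- length(pool) - criteria$max_screened_per_case
        push(cid, NA_character_, "never_screened", "exceeded screening cap",
             as.integer(n_over))
        pool <- pool[seq_len(criteria$max_screened_per_case)]
      }
    }
    keep <- integer(0)
    for (k in pool) {
      if (nzchar(screen_reason[k])) {
        push(cid, stream$id[k], "closed_out", screen_reason[k])
        # patient-level exclusion: retire from the pool permanently
        consumed[k] <- TRUE
        if (criteria$require_same_decile) {
          unconsumed_in_dec[deciles[k]] <- unconsumed_in_dec[deciles[k]] - 1L
        }
        total_unconsumed <- total_unconsumed - 1L
      } else if (criteria$require_same_sex && stream$sex[k] != stream$sex[ci]) {
        push(cid, stream$id[k], "closed_out", "sex mismatch")
      } else if (abs(stream$pain_score[k] - stream$pain_score[ci]) >
                 criteria$caliper_pain) {
        push(cid, stream$id[k], "closed_out", "pain caliper exceeded")
      } else {
        keep <- c(keep, k)
      }
    }
    if (length(keep) == 0) {
      unmatched <- c(unmatched, cid)
      push(cid, NA_character_, "unmatched", "no eligible candidate")
      next
    }
    ord <- keep[order(stream$days_since_pain_visit[keep], keep)]
    sel <- ord[seq_len(min(criteria$controls_per_case, length(ord)))]
    surplus <- setdiff(ord, sel)
    for (s in surplus) push(cid, stream$id[s], "closed_out", "surplus")
    if (criteria$exact_ratio && length(sel) < criteria$controls_per_case) {
      unmatched <- c(unmatched, cid)
      push(cid, NA_character_, "unmatched", "exact ratio not attainable")
      next
    }
    consumed[sel] <- TRUE
    if (criteria$require_same_decile) {
      unconsumed_in_dec[deciles[ci]] <- unconsumed_in_dec[deciles[ci]] - length(sel)
    }
    total_unconsumed <- total_unconsumed - length(sel)
    for (s in sel) push(cid, stream$id[s], "selected", "matched control")
    match_sets[[length(match_sets) + 1L]] <- list(
      case_id = cid, control_ids = stream$id[sel], decile = deciles[ci],
      case_pain_score = stream$pain_score[ci],
      control_pain_scores = stream$pain_score[sel],
      control_days_since_pain_visit = stream$days_since_pain_visit[sel])
    matches[[length(matches) + 1L]] <- data.frame(
      case_id = cid, control_id = stream$id[sel], decile = deciles[ci],
      case_sex = stream$sex[ci], control_sex = stream$sex[sel],
      case_pain = stream$pain_score[ci], control_pain = stream$pain_score[sel],
      control_days_since_pain_visit = stream$days_since_pain_visit[sel],
      stringsAsFactors = FALSE)
  }

  empty_matches <- data.frame(
    case_id = character(0), control_id = character(0), decile = integer(0),
    case_sex = character(0), control_sex = character(0),
    case_pain = integer(0), control_pain = integer(0),
    control_days_since_pain_visit = integer(0), stringsAsFactors = FALSE)
  empty_log <- data.frame(case_id = character(0), candidate_id = character(0),
                          action = character(0), reason = character(0),
                          n = integer(0), stringsAsFactors = FALSE)
  log_df <- if (length(log_case)) {
    data.frame(case_id = unlist(log_case), candidate_id = unlist(log_cand),
               action = unlist(log_action), reason = unlist(log_reason),
               n = unlist(log_n), stringsAsFactors = FALSE)
  } else empty_log
  structure(list(
    matches = if (length(matches)) do.call(rbind, matches) else empty_matches,
    match_sets = match_sets,
    unmatched = unmatched,
    ineligible_cases = ineligible_cases,
    log = log_df,
    criteria = criteria,
    n_cases = length(case_idx),
    stream_ids = stream$id
  ), class = "match_result")
}

#' Design-efficiency summary of a prospective matching run
#'
#' @param result A `match_result` from [match_prospective()].
#' @return A `match_summary` list: cases presented/eligible/matched, controls
#'   enrolled, mean controls per case, candidates screened per enrolled
#'   control, and close-out reason tallies.
#' @export
match_summary <- function(result) {
  stopifnot(inherits(result, "match_result"))
  n_matched <- length(result$match_sets)
  n_controls <- nrow(result$matches)
  screened <- sum(result$log$n[result$log$action %in% c("closed_out", "selected")])
  closeouts <- result$log[result$log$action %in% c("closed_out", "never_screened"), ]
  tallies <- if (nrow(closeouts)) {
    stats::aggregate(n ~ reason, data = closeouts, FUN = sum)
  } else {
    data.frame(reason = character(0), n = integer(0))
  }
  structure(list(
    n_cases = result$n_cases,
    n_ineligible_cases = length(result$ineligible_cases),
    n_matched_cases = n_matched,
    n_unmatched_cases = length(result$unmatched),
    n_controls = n_controls,
    mean_controls_per_case = if (n_matched > 0) n_controls / n_matched else NA_real_,
    screens_per_enrolled_control = if (n_controls > 0) screened / n_controls
                                   else NA_real_,
    closeout_tallies = tallies
  ), class = "match_summary")
}

#' @export
summary.match_result <- function(object, ...) match_summary(object)

#' @export
print.match_result <- function(x, ...) {
  cat("Prospective match result:", length(x$match_sets), "matched cases,",
      nrow(x$matches), "controls,", length(x$unmatched), "unmatched,",
      length(x$ineligible_cases), "ineligible cases\n")
  invisible(x)
}

#' @export
print.match_summary <- function(x, ...) {
  cat("Matching design-efficiency summary\n")
  cat("  referred cases presented: ", x$n_cases, "\n")
  cat("  ineligible cases:         ", x$n_ineligible_cases, "\n")
  cat("  matched cases:            ", x$n_matched_cases, "\n")
  cat("  unmatched eligible cases: ", x$n_unmatched_cases, "\n")
  cat("  controls enrolled:        ", x$n_controls, "\n")
  cat("  mean controls per case:   ", format(x$mean_controls_per_case, digits = 4), "\n")
  cat("  screens per control:      ",
      format(x$screens_per_enrolled_control, digits = 4), "\n")
  if (nrow(x$closeout_tallies)) {
    cat("  close-out reasons:\n")
    for (i in seq_len(nrow(x$closeout_tallies))) {
      cat("    ", x$closeout_tallies$reason[i], ": ", x$closeout_tallies$n[i],
          "\n", sep = "")
    }
  }
  invisible(x)
}
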