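test_that("eligibility screening applies the exclusion list in order", {
  p <- toy_patient("X1", 0, decile = 3, pain = 3)
  s <- screen_eligibility(p)
  expect_false(s$eligible)
  expect_identical(s$reasons, "pain bothersomeness < 4")

  expect_true(screen_eligibility(toy_patient("X2", 0, decile = 3, pain = 4))$eligible)

  s3 <- screen_eligibility(toy_patient("X3", 0, decile = 3, pain = 8, pregnant = 1L))
  expect_false(s3$eligible)
  expect_identical(s3$reasons, "pregnant")

  # multiple failures reported in the catalogue's order
  s4 <- screen_eligibility(toy_patient("X4", 0, decile = 1, pain = 2,
                                       declined = 1L, moving = 1L))
  expect_identical(s4$reasons,
                   c("declined screening", "pain bothersomeness < 4",
                     "moving out of area"))

  p5 <- toy_patient("X5", 0, decile = 1)
  p5$pregnant <- NULL
  expect_error(screen_eligibility(p5), "pregnant")
})

test_that("incident-user filter removes recently exposed patients", {
  cohort <- rbind(toy_patient("a", 0, 1), toy_patient("b", 0, 1),
                  toy_patient("c", 0, 1))
  expect_message(out <- incident_user_filter(cohort), "removed 0 of 3")
  expect_identical(out, cohort)

  cohort$prior_acupuncture_6mo <- c(1L, 0L, 1L)
  expect_message(out <- incident_user_filter(cohort), "removed 2 of 3")
  expect_identical(out$id, "b")

  cohort$prior_acupuncture_6mo <- 1L
  expect_warning(expect_message(out <- incident_user_filter(cohort)),
                 "every patient")
  expect_identical(nrow(out), 0L)
  expect_error(incident_user_filter(cohort[, 1:4]), "prior_acupuncture_6mo")
})

test_that("the worked matching instance resolves exactly as the rules dictate", {
  stream <- toy_stream(
    toy_patient("case", 1, decile = 3, sex = "F", pain = 6),
    toy_patient("c1", 0, decile = 3, sex = "F", pain = 7, days = 2),
    toy_patient("c2", 0, decile = 3, sex = "F", pain = 9, days = 1),
    toy_patient("c3", 0, decile = 4, sex = "F", pain = 6, days = 1),
    toy_patient("c4", 0, decile = 3, sex = "M", pain = 6, days = 1),
    toy_patient("c5", 0, decile = 3, sex = "F", pain = 5, days = 5)
  )
  res <- match_prospective(stream, toy_model(), match_criteria())
  expect_identical(sort(res$matches$control_id), c("c1", "c5"))
  expect_identical(res$match_sets[[1]]$decile, 3L)
  log <- res$log
  expect_identical(log$reason[log$candidate_id %in% "c2"], "pain caliper exceeded")
  expect_identical(log$reason[log$candidate_id %in% "c4"], "sex mismatch")
  expect_identical(log$reason[log$action == "never_screened"], "wrong decile")

  # recency rule: with one control wanted, the smaller days-since-visit wins
  res1 <- match_prospective(stream, toy_model(),
                            match_criteria(controls_per_case = 1))
  expect_identical(res1$matches$control_id, "c1")

  # empty candidate pool: reported unmatched, not an error
  lone <- toy_stream(toy_patient("case", 1, decile = 3))
  res0 <- match_prospective(lone, toy_model())
  expect_identical(res0$unmatched, "case")
  expect_identical(nrow(res0$matches), 0L)
})

test_that("ties in visit recency break by earlier arrival", {
  stream <- toy_stream(
    toy_patient("case", 1, decile = 5, pain = 6),
    toy_patient("late", 0, decile = 5, pain = 6, days = 3),
    toy_patient("early", 0, decile = 5, pain = 6, days = 3)
  )
  # both candidates tie on days; the first-arriving one is chosen
  res <- match_prospective(stream, toy_model(), match_criteria(controls_per_case = 1))
  expect_identical(res$matches$control_id, "late")
})

test_that("matched sets never violate decile, sex, caliper or replacement rules", {
  set.seed(101)
  m <- toy_model()
  for (i in 1:120) {
    crit <- match_criteria(
      caliper_pain = sample(0:3, 1),
      controls_per_case = sample(1:3, 1),
      max_screened_per_case = sample(5:15, 1)
    )
    stream <- random_stream(n_cases = sample(2:5, 1),
                            cands_per_case = sample(6:14, 1))
    res <- match_prospective(stream, m, crit)
    if (nrow(res$matches) == 0) next
    expect_true(all(res$matches$case_sex == res$matches$control_sex))
    expect_true(all(abs(res$matches$case_pain - res$matches$control_pain) <=
                    crit$caliper_pain))
    dec <- stats::setNames(decile_of(m, predict(m, stream)), stream$id)
    expect_true(all(dec[res$matches$control_id] == res$matches$decile))
    expect_true(all(dec[res$matches$case_id] == res$matches$decile))
    # without replacement: no control serves two cases
    expect_false(anyDuplicated(res$matches$control_id) > 0)
    # no selected control ever screened ineligible
    sel <- stream[match(res$matches$control_id, stream$id), ]
    expect_true(all(vapply(seq_len(nrow(sel)),
                           function(j) screen_eligibility(sel[j, ])$eligible,
                           logical(1))))
    # per-case control count within target
    expect_true(all(table(res$matches$case_id) <= crit$controls_per_case))
  }
})

test_that("relaxing every constraint matches all cases with an eligible candidate", {
  set.seed(202)
  crit <- match_criteria(caliper_pain = 10, controls_per_case = 1,
                         max_screened_per_case = 1000,
                         require_same_sex = FALSE, require_same_decile = FALSE)
  for (i in 1:20) {
    stream <- random_stream(n_cases = 3, cands_per_case = 10, excl_rate = 0.3)
    res <- match_prospective(stream, toy_model(), crit)
    n_elig_cand <- sum(vapply(which(stream$referred == 0), function(j) {
      screen_eligibility(stream[j, ])$eligible
    }, logical(1)))
    n_elig_cases <- sum(stream$referred == 1) - length(res$ineligible_cases)
    expect_identical(length(res$match_sets) + length(res$unmatched), n_elig_cases)
    if (n_elig_cand >= n_elig_cases) expect_length(res$unmatched, 0)
  }
})

test_that("permuting candidates leaves the match count unchanged when the pool is abundant", {
  set.seed(303)
  mkstream <- function(perm) {
    cases <- lapply(1:3, function(ci) toy_patient(sprintf("A%d", ci), 1, decile = 4,
                                                  sex = "F", pain = 6))
    cands <- lapply(1:30, function(k) toy_patient(sprintf("C%02d", k), 0, decile = 4,
                                                  sex = "F", pain = 6,
                                                  days = sample(0:10, 1)))[perm]
    do.call(toy_stream, c(cases, cands))
  }
  set.seed(1); s1 <- mkstream(1:30)
  set.seed(1); s2 <- mkstream(sample(30))
  crit <- match_criteria(max_screened_per_case = 30)
  expect_identical(length(match_prospective(s1, toy_model(), crit)$match_sets),
                   length(match_prospective(s2, toy_model(), crit)$match_sets))
})

test_that("the exact-ratio flag discards partially matched cases", {
  stream <- toy_stream(
    toy_patient("case", 1, decile = 2, pain = 6),
    toy_patient("only", 0, decile = 2, pain = 6, days = 1)
  )
  res <- match_prospective(stream, toy_model(),
                           match_criteria(exact_ratio = TRUE))
  expect_identical(nrow(res$matches), 0L)
  expect_identical(res$unmatched, "case")
})

test_that("the efficiency summary agrees with a brute-force replay of the log", {
  stream <- random_stream(n_cases = 5, cands_per_case = 12)
  res <- match_prospective(stream, toy_model(), match_criteria())
  s <- match_summary(res)
  expect_identical(s$n_controls, sum(res$log$action == "selected"))
  expect_identical(s$n_matched_cases, length(unique(res$matches$case_id)))
  if (s$n_matched_cases > 0) {
    expect_equal(s$mean_controls_per_case, s$n_controls / s$n_matched_cases)
    expect_gte(s$mean_controls_per_case, 1)
    expect_lte(s$mean_controls_per_case, 2)
  }
  # full matching at ratio 2 reports exactly 2.0
  full <- toy_stream(
    toy_patient("a", 1, decile = 5, pain = 6),
    toy_patient("k1", 0, decile = 5, pain = 6, days = 1),
    toy_patient("k2", 0, decile = 5, pain = 6, days = 2)
  )
  expect_equal(match_summary(match_prospective(full, toy_model(),
                                               match_criteria()))$mean_controls_per_case, 2)
})

test_that("criteria objects validate their invariants", {
  expect_error(match_criteria(caliper_pain = -1), "caliper")
  expect_error(match_criteria(controls_per_case = 0), "controls_per_case")
  expect_error(match_criteria(controls_per_case = 3, max_screened_per_case = 2),
               "max_screened_per_case")
})
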