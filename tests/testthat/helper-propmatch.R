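# Shared fixtures: a hand-built propensity model with known decile geometry,
# toy arrival streams, and independent oracles.

# A propensity model whose score is plogis(score_lp) and whose frozen decile
# boundaries are 0.1, ..., 0.9, so a patient placed at lp_for_decile(d) lands
# exactly in decile d.
toy_model <- function(boundaries = seq(0.1, 0.9, by = 0.1)) {
  f <- referred ~ score_lp
  structure(list(
    coefficients = c(`(Intercept)` = 0, score_lp = 1),
    std_errors = c(`(Intercept)` = NA_real_, score_lp = NA_real_),
    covariate_names = "score_lp",
    decile_boundaries = boundaries,
    fitted = NULL,
    response = "referred",
    terms = stats::delete.response(stats::terms(f)),
    formula = f,
    fit_meta = list(n = NA, events = NA)
  ), class = "propensity_model")
}

lp_for_decile <- function(d) stats::qlogis((d - 0.5) / 10)

# One toy stream row. All exclusion flags default to zero (screens eligible).
toy_patient <- function(id, referred, decile, sex = "F", pain = 6, days = 0,
                        arrival = NA_integer_, ...) {
  flags <- stats::setNames(as.list(rep(0L, 10)),
                           c("cancer", "dementia", "psychoses", "hospice",
                             "declined", "non_persistent_pain", "already_started",
                             "prior_acupuncture_6mo", "pregnant", "moving"))
  over <- list(...)
  flags[names(over)] <- over
  cbind(data.frame(arrival = arrival, id = id, sex = sex,
                   referred = as.integer(referred), initiated = 0L,
                   pain_score = as.integer(pain),
                   days_since_pain_visit = as.integer(days),
                   score_lp = lp_for_decile(decile),
                   stringsAsFactors = FALSE),
        as.data.frame(flags))
}

toy_stream <- function(...) {
  rows <- do.call(rbind, list(...))
  rows$arrival <- seq_len(nrow(rows))
  rows
}

# O(n1 * n0) all-pairs concordance oracle with half credit for ties.
auc_brute_force <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  cmp <- outer(s1, s0, ">") + 0.5 * outer(s1, s0, "==")
  mean(cmp)
}

# Random toy stream for matcher property tests: cases followed by candidate
# blocks with random deciles, sexes, pain scores and occasional exclusions.
random_stream <- function(n_cases = 4, cands_per_case = 12, excl_rate = 0.15) {
  rows <- list()
  idx <- 0L
  for (ci in seq_len(n_cases)) {
    idx <- idx + 1L
    rows[[idx]] <- toy_patient(sprintf("A%03d", ci), 1,
                               decile = sample(1:10, 1),
                               sex = sample(c("F", "M"), 1),
                               pain = sample(4:10, 1))
    for (k in seq_len(cands_per_case)) {
      idx <- idx + 1L
      args <- list(sprintf("C%03d_%02d", ci, k), 0,
                   decile = sample(1:10, 1),
                   sex = sample(c("F", "M"), 1),
                   pain = sample(0:10, 1),
                   days = sample(0:10, 1))
      if (stats::runif(1) < excl_rate) {
        args$declined <- 1L
      }
      rows[[idx]] <- do.call(toy_patient, args)
    }
  }
  out <- do.call(rbind, rows)
  out$arrival <- seq_len(nrow(out))
  out
}

# Small default-structure configuration for quick end-to-end tests.
quick_config <- function(n = 4000, seed = 1) sim_config(n_patients = n, seed = seed)

ps_covariate_names <- function(cfg = NULL) {
  s <- default_covariate_structure()
  sort(c(names(s$binary_prevalences), names(s$continuous_params)))
}
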