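test_that("arcsine standardized differences reproduce printed summaries", {
  # development cohort contrasts
  expect_lt(abs(sd_binary(0.250, 0.111) - 0.368), 0.002)
  expect_lt(abs(sd_binary(0.812, 0.650) - 0.370), 0.002)
  expect_lt(abs(sd_binary(0.296, 0.144) - 0.373), 0.005)
  # identities and extremes
  for (p in c(0, 0.2, 0.5, 1)) expect_equal(sd_binary(p, p), 0)
  expect_equal(sd_binary(1, 0), pi)
  expect_error(sd_binary(1.1, 0.2), "input error")
})

test_that("pooled-SD standardized differences reproduce printed summaries", {
  expect_lt(abs(sd_continuous(53.8, 14.0, 55.2, 15.0) - -0.097), 0.002)
  expect_equal(sd_continuous(5, 2, 5, 3), 0)
  expect_equal(sd_continuous(1, 1, 0, 1), 1)
  expect_error(sd_continuous(1, 0, 0, 0), "undefined")
  expect_equal(sd_continuous(3, 0, 3, 0), 0)
})

test_that("standardized differences are antisymmetric and scale-free", {
  set.seed(5)
  for (i in 1:20) {
    p <- runif(2)
    expect_equal(sd_binary(p[1], p[2]), -sd_binary(p[2], p[1]))
    m <- rnorm(2, 50, 10); s <- runif(2, 1, 5)
    expect_equal(sd_continuous(m[1], s[1], m[2], s[2]),
                 -sd_continuous(m[2], s[2], m[1], s[1]))
    a <- runif(1, 0.5, 3); b <- rnorm(1, 0, 10)
    expect_equal(sd_continuous(a * m[1] + b, a * s[1], a * m[2] + b, a * s[2]),
                 sd_continuous(m[1], s[1], m[2], s[2]))
  }
})

test_that("stratum-adjusted differences match direct arithmetic", {
  # perfect within-stratum balance -> 0
  x <- c(1, 0, 1, 0, 1, 1, 1, 1)
  g <- c(1, 1, 0, 0, 1, 1, 0, 0)
  s <- c(1, 1, 1, 1, 2, 2, 2, 2)
  expect_equal(sd_adjusted(x, g, s), 0)

  # single stratum degenerates to the unadjusted value
  x2 <- c(1, 1, 0, 1, 0, 0)
  g2 <- c(1, 1, 1, 0, 0, 0)
  expect_equal(sd_adjusted(x2, g2, rep(1, 6)),
               sd_binary(mean(x2[g2 == 1]), mean(x2[g2 == 0])))

  # two strata, hand-computed: continuous covariate
  xc <- c(10, 12, 8, 9, 20, 22, 15, 16)
  gc_ <- c(1, 1, 0, 0, 1, 1, 0, 0)
  sc <- c(1, 1, 1, 1, 2, 2, 2, 2)
  w <- c(0.5, 0.5)
  diff_hand <- w[1] * (mean(c(10, 12)) - mean(c(8, 9))) +
               w[2] * (mean(c(20, 22)) - mean(c(15, 16)))
  denom <- sqrt((stats::sd(xc[gc_ == 1])^2 + stats::sd(xc[gc_ == 0])^2) / 2)
  expect_equal(sd_adjusted(xc, gc_, sc), diff_hand / denom)

  # two strata, hand-computed: binary covariate with unequal stratum sizes
  xb <- c(1, 1, 0, 0, 0, 0, 1, 0, 1, 0)
  gb <- c(1, 1, 0, 0, 0, 1, 1, 0, 0, 0)
  sb <- c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2)
  p1 <- 0.5 * mean(xb[gb == 1 & sb == 1]) + 0.5 * mean(xb[gb == 1 & sb == 2])
  p2 <- 0.5 * mean(xb[gb == 0 & sb == 1]) + 0.5 * mean(xb[gb == 0 & sb == 2])
  expect_equal(sd_adjusted(xb, gb, sb), sd_binary(p1, p2))

  # treated-share weights variant
  wt <- c(2, 2) / 4
  p1t <- wt[1] * mean(xb[gb == 1 & sb == 1]) + wt[2] * mean(xb[gb == 1 & sb == 2])
  p2t <- wt[1] * mean(xb[gb == 0 & sb == 1]) + wt[2] * mean(xb[gb == 0 & sb == 2])
  expect_equal(sd_adjusted(xb, gb, sb, weights = "treated"), sd_binary(p1t, p2t))
})

test_that("strata missing a group are dropped with a warning", {
  x <- c(1, 0, 1, 1)
  g <- c(1, 0, 1, 1)   # stratum 2 has no controls
  s <- c(1, 1, 2, 2)
  expect_warning(v <- sd_adjusted(x, g, s), "dropping 1")
  expect_equal(suppressWarnings(sd_adjusted(x, g, s)),
               sd_binary(mean(x[g == 1 & s == 1]), mean(x[g == 0 & s == 1])))
  expect_error(suppressWarnings(sd_adjusted(c(1, 0), c(1, 1), c(1, 1))),
               "no stratum")
})

test_that("decile adjustment of a well-fitted score removes the mean imbalance", {
  # one moderate-size cohort: adjusted values shrink far below unadjusted ones
  cfg <- quick_config(n = 30000, seed = 23)
  dev <- simulate_development_cohort(cfg)
  m <- fit_propensity(stats::reformulate(ps_covariate_names(), "initiated"), dev)
  dec <- decile_of(m, m$fitted)
  un <- abs(sd_binary(mean(dev$pain_medication[dev$initiated == 1]),
                      mean(dev$pain_medication[dev$initiated == 0])))
  ad <- abs(sd_adjusted(dev$pain_medication, dev$initiated, dec))
  expect_lt(ad, un / 3)
})

test_that("post-matching c reflects covariate balance of the matched groups", {
  set.seed(31)
  cases <- data.frame(referred = 1, a = rbinom(300, 1, 0.4), b = rnorm(300))
  clones <- transform(cases, referred = 0)
  expect_equal(post_matching_c(rbind(cases, clones), c("a", "b")), 0.5,
               tolerance = 1e-3)

  sep <- rbind(transform(cases, s = 1), transform(clones, s = 0))
  expect_warning(v <- post_matching_c(sep, c("a", "b", "s")), "maximal imbalance")
  expect_equal(v, 1.0)

  expect_error(post_matching_c(cases, c("a", "zzz")), "zzz")

  # frozen-score variant: balanced clones give exactly 0.5
  m <- toy_model()
  str_ <- rbind(toy_patient("x", 1, 4), toy_patient("y", 0, 4))
  expect_equal(post_matching_c(str_, "score_lp", method = "frozen", model = m), 0.5)
  expect_error(post_matching_c(str_, "score_lp", method = "frozen"), "model")
})

test_that("balance reports reproduce printed-table arithmetic and are deterministic", {
  # groups constructed to carry the printed prevalences exactly
  mk <- function(n, p) rep(c(1L, 0L), c(round(n * p), n - round(n * p)))
  d <- data.frame(
    referred = rep(c(1L, 0L), c(1000, 1000)),
    opioid_therapy_plan = c(mk(1000, 0.288), mk(1000, 0.178)),
    pain_medication = c(mk(1000, 0.812), mk(1000, 0.650)),
    age = c(as.numeric(scale(rnorm(1000))) * 14.0 + 53.8,
            as.numeric(scale(rnorm(1000))) * 15.0 + 55.2)
  )
  rep1 <- balance_report(d, "referred",
                         c("opioid_therapy_plan", "pain_medication", "age"))
  expect_lt(abs(rep1$sd_unadjusted[rep1$covariate == "opioid_therapy_plan"] -
                0.261), 0.005)
  expect_lt(abs(rep1$sd_unadjusted[rep1$covariate == "pain_medication"] -
                0.370), 0.005)
  expect_lt(abs(rep1$sd_unadjusted[rep1$covariate == "age"] - -0.097), 0.005)
  expect_identical(balance_report(d, "referred",
                                  c("opioid_therapy_plan", "pain_medication", "age")),
                   rep1)

  # sectioning and collisions
  rep2 <- balance_report(d, "referred", "opioid_therapy_plan",
                         other_covariates = "age")
  expect_identical(rep2$section, c("propensity score", "other"))
  expect_error(balance_report(d, "referred", "age", other_covariates = "age"),
               "collision")
  empty <- balance_report(d, "referred", character(0))
  expect_identical(nrow(empty), 0L)
})
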