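toy_records <- function() {
  data.frame(
    chamber_id = paste0("C", 1:4),
    treatment = c("roach", "roach", "no_roach", "no_roach"),
    flight_id = "F1", nest_id = "N1",
    day = c(3L, 5L, 7L, 9L),
    garden_outcome = c("uncaring", "foundress_dead", "censored",
                       "uncaring"),
    foundress_died = c(FALSE, TRUE, FALSE, FALSE),
    disturbed = c(TRUE, FALSE, NA, NA)
  )
}

test_that("endpoint definitions select and censor the right events", {
  recs <- toy_records()
  comb <- endpoint_events(recs, "combined")
  expect_equal(sum(comb$event), 3L)
  unc <- endpoint_events(recs, "uncaring_only")
  expect_equal(sum(unc$event), 2L)
  # foundress-death chambers are censored at their day, not dropped
  expect_equal(nrow(unc), nrow(recs))
  expect_equal(unc$time, recs$day)

  all_cens <- recs; all_cens$garden_outcome <- "censored"
  all_cens$foundress_died <- FALSE
  expect_equal(sum(endpoint_events(all_cens, "combined")$event), 0L)
  expect_equal(sum(endpoint_events(all_cens, "uncaring_only")$event), 0L)

  # tally on a generated set with known outcome mix
  r <- generate_survival_experiment(experiment_design(seed = 3))
  expect_equal(sum(endpoint_events(r, "combined")$event),
               sum(r$garden_outcome != "censored"))
  expect_equal(sum(endpoint_events(r, "uncaring_only")$event),
               sum(r$garden_outcome == "uncaring"))

  expect_error(endpoint_events(recs, "everything"))
})

test_that("cox_fit maximizes the partial likelihood (brute-force oracle)", {
  # tie-free 6-subject fixture with interleaved group events, so the
  # partial-likelihood maximum is interior
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  x <- c(1, 0, 1, 0, 1, 0)
  oracle <- brute_force_loghr(time, event, x)
  for (tm in c("breslow", "efron")) {
    fit <- cox_fit(time, event, x, ties_method = tm)
    expect_equal(fit$log_hr, oracle, tolerance = 1e-6)
  }

  # a second, 8-subject tie-free fixture with censoring interleaved
  time <- c(2, 3, 5, 7, 11, 13, 17, 19)
  event <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  x <- c(0, 1, 1, 0, 1, 0, 1, 0)
  fit <- cox_fit(time, event, x)
  expect_equal(fit$log_hr, brute_force_loghr(time, event, x),
               tolerance = 1e-6)

  # result internals are mutually consistent
  expect_equal(fit$hr, exp(fit$log_hr))
  expect_equal(fit$delta * fit$hr, 1)
  expect_equal(fit$wald_z, fit$log_hr / fit$se)
  expect_true(fit$p_value >= 0 && fit$p_value <= 1)
})

test_that("Breslow and Efron agree exactly on tie-free data", {
  set.seed(5)
  n <- 40
  time <- sample(1000L, n) # distinct days
  event <- stats::runif(n) < 0.7
  x <- rep(0:1, each = n / 2)
  fb <- cox_fit(time, event, x, ties_method = "breslow")
  fe <- cox_fit(time, event, x, ties_method = "efron")
  expect_equal(fb$log_hr, fe$log_hr, tolerance = 1e-10)
  expect_equal(fb$se, fe$se, tolerance = 1e-10)
})

test_that("identical groups give null hazard ratios at 2se coverage", {
  set.seed(8)
  inside <- 0L
  for (i in 1:100) {
    time <- ceiling(stats::rexp(200, 0.05))
    event <- time <= 60
    time <- pmin(time, 60)
    fit <- cox_fit(time, event, rep(0:1, each = 100))
    inside <- inside + (abs(fit$log_hr) < 2 * fit$se)
  }
  expect_gte(inside, 93L)
})

test_that("monotone likelihood and bad groups are caught", {
  expect_error(cox_fit(1:6, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                       c(1, 1, 1, 0, 0, 0)), "group 0")
  expect_error(cox_fit(1:4, rep(TRUE, 4), c(0, 1, 2, 1)), "binary")
  expect_error(cox_fit(c(-1, 2, 3, 4), rep(TRUE, 4), c(0, 0, 1, 1)),
               "positive")
})

test_that("gamma frailty fits report a frailty variance", {
  r <- generate_survival_experiment(experiment_design(seed = 12,
                                                      frailty_sd = 0.6))
  ee <- endpoint_events(r, "combined")
  fit <- cox_fit(ee$time, ee$event, r$treatment == "roach",
                 frailty_group = interaction(r$flight_id, r$nest_id,
                                             drop = TRUE))
  expect_false(is.na(fit$frailty_variance))
  expect_gte(fit$frailty_variance, 0)
})

test_that("delta is the reciprocal hazard ratio", {
  expect_equal(delta_from_hr(3.36), 1 / 3.36)
  expect_equal(round(delta_from_hr(3.36), 1), 0.3)
  expect_equal(delta_from_hr(1), 1)
  expect_equal(delta_from_hr(4.44), 1 / 4.44)
  expect_error(delta_from_hr(0), "> 0")
  expect_error(delta_from_hr(-2), "> 0")
})

test_that("km_survivorship is the product-limit estimator", {
  # no events: flat at 1
  km <- km_survivorship(c(5, 5, 5), c(FALSE, FALSE, FALSE), rep("a", 3))
  expect_true(all(km$survival == 1))

  # two subjects, events at days 1 and 2
  km <- km_survivorship(c(1, 2), c(TRUE, TRUE), rep("a", 2))
  expect_equal(km$survival[km$day == 0], 1)
  expect_equal(km$survival[km$day == 1], 0.5)
  expect_equal(km$survival[km$day == 2], 0)

  # random censored data matches the naive day-by-day oracle
  set.seed(9)
  time <- ceiling(stats::rexp(60, 0.1))
  event <- stats::runif(60) < 0.7
  km <- km_survivorship(time, event, rep("g", 60))
  oracle <- naive_km(time, event)
  m <- merge(km[km$day > 0, ], oracle, by = "day")
  expect_equal(m$survival.x, m$survival.y, tolerance = 1e-12)

  # curves are nonincreasing within group
  r <- generate_survival_experiment(experiment_design(seed = 4))
  ee <- endpoint_events(r, "combined")
  km <- km_survivorship(ee$time, ee$event, r$treatment)
  for (g in unique(km$group)) {
    expect_true(all(diff(km$survival[km$group == g]) <= 1e-12))
  }
  expect_error(km_survivorship(c(-1, 2), c(TRUE, TRUE), c("a", "a")),
               "nonnegative")
})

test_that("chi-square on a 2x2 table matches hand computation", {
  r <- chi_square_2x2(10, 10, 10, 10, continuity_correction = FALSE)
  expect_equal(r$x2, 0)
  expect_equal(r$p, 1)
  expect_equal(r$df, 1L)

  # sum((O-E)^2/E) for (20,10)/(10,20): every cell contributes 5/3
  r <- chi_square_2x2(20, 10, 10, 20, continuity_correction = FALSE)
  expect_equal(r$x2, 20 / 3)

  # row swap leaves the statistic unchanged
  r2 <- chi_square_2x2(10, 20, 20, 10, continuity_correction = FALSE)
  expect_equal(r2$x2, r$x2)

  expect_error(chi_square_2x2(0, 0, 5, 5), "degenerate")
  expect_error(chi_square_2x2(-1, 2, 3, 4), ">= 0")
})

test_that("Clopper-Pearson intervals invert the binomial tails", {
  # the disturbance proportion and its interval
  ci <- proportion_ci(60, 96)
  expect_equal(ci$p_hat, 0.625)
  expect_equal(round(100 * ci$lower, 1), 52.0)
  expect_equal(round(100 * ci$upper, 1), 72.2)

  # brute-force tail inversion oracle
  for (k in c(1, 5, 9)) {
    ci <- proportion_ci(k, 10)
    oracle <- tail_inversion_ci(k, 10)
    expect_equal(ci$lower, unname(oracle["lower"]), tolerance = 1e-8)
    expect_equal(ci$upper, unname(oracle["upper"]), tolerance = 1e-8)
  }

  # boundaries
  expect_equal(proportion_ci(0, 10)$lower, 0)
  expect_equal(proportion_ci(10, 10)$upper, 1)

  # all methods bracket the point estimate within [0, 1]
  for (m in c("clopper_pearson", "wilson", "wald")) {
    ci <- proportion_ci(7, 25, method = m)
    expect_true(ci$lower >= 0 && ci$upper <= 1)
    expect_true(ci$lower <= ci$p_hat && ci$p_hat <= ci$upper)
  }
  expect_error(proportion_ci(11, 10))
  expect_error(proportion_ci(5, 10, level = 1))
})

test_that("survey_summary computes colony and alate prevalences", {
  sv <- data.frame(
    colony_id = paste0("c", 1:11), site = "s",
    alates_sampled = c(719, rep(500, 10)),
    alates_with_roach = c(50, 15, 12, 20, 11, 14, 25, 13, 0, 0, 0))
  s <- survey_summary(sv)
  expect_equal(s$V_field, 8 / 11)
  expect_equal(round(100 * s$V_field), 73)
  expect_equal(s$J_max, 50 / 719)
  expect_equal(round(s$J_max, 2), 0.07)

  # totals conserved
  expect_equal(s$totals$roaches, sum(sv$alates_with_roach))
  expect_equal(s$totals$alates, sum(sv$alates_sampled))
  expect_equal(sum(s$per_colony_prevalence$prevalence *
                     sv$alates_sampled), s$totals$roaches)

  # no hitchhikers anywhere
  sv$alates_with_roach <- 0
  s <- survey_summary(sv)
  expect_equal(s$V_field, 0)
  expect_equal(s$J_max, 0)

  # empty samples are excluded with a warning
  sv$alates_sampled[1] <- 0
  expect_warning(s <- survey_summary(sv), "excluded")
  expect_equal(s$totals$colonies, 10)

  expect_error(survey_summary(data.frame(colony_id = 1, alates_sampled = 5,
                                         alates_with_roach = 6)))
})
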