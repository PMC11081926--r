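test_that("censoring substitutes the final-decision onset idempotently", {
  tab <- data.frame(leaving_time = c(30, 105, 101.5),
                    censored = c(FALSE, TRUE, TRUE))
  out <- censor_nonleaves(tab)
  expect_equal(out$leaving_time, c(30, 101.5, 101.5))
  expect_identical(censor_nonleaves(out), out)
})

test_that("exclusion rules follow the active-decision and attention criteria", {
  tab <- data.frame(
    participant_id = rep(c("a", "b"), each = 4),
    environment_type = rep(c("high_generosity", "low_generosity"), 4),
    leaving_time = 50, censored = c(rep(FALSE, 4), TRUE, TRUE, TRUE, FALSE),
    study_variant = "S12")
  res <- apply_exclusions(tab, "S12")
  expect_equal(res$report$participant_id, "b")  # one active leave < 2 environments
  expect_equal(res$report$reason, "too_few_active_decisions")
  expect_true(all(res$table$participant_id == "a"))
  # compliant cohorts pass untouched
  ok <- apply_exclusions(tab[tab$participant_id == "a", ], "S12")
  expect_equal(nrow(ok$report), 0L)
  # attention rule is strict: more than 25% fails, exactly 25% is retained
  scores <- data.frame(participant_id = c("a", "b", "c"),
                       attention_fail_frac = c(0.26, 0.25, 0.10))
  tab4 <- data.frame(participant_id = rep(c("a", "b", "c"), 2),
                     environment_type = "high_generosity",
                     leaving_time = 40, censored = FALSE, study_variant = "S4")
  res4 <- apply_exclusions(tab4, "S4", scores)
  expect_equal(res4$report$participant_id, "a")
  expect_error(apply_exclusions(tab4, "S4"), "attention_fail_frac")
})

test_that("outlier trimming works within participant-condition cells", {
  cell <- data.frame(participant_id = "a", partner = "fair",
                     environment_type = "high_generosity",
                     leaving_time = c(10, 10, 10, 60))
  # sd ~25: 60 is within 2.5 SD of the mean, nothing trimmed
  expect_equal(trim_outliers(cell)$n_trimmed, 0L)
  const <- transform(cell, leaving_time = 20)
  expect_equal(trim_outliers(const)$n_trimmed, 0L)
  big <- data.frame(participant_id = "a", partner = "fair",
                    environment_type = "high_generosity",
                    leaving_time = c(rep(10, 20), 60))
  tr <- trim_outliers(big)
  expect_equal(tr$n_trimmed, 1L)
  expect_true(all(tr$table$leaving_time == 10))
  # idempotent: re-application trims nothing further here
  expect_equal(trim_outliers(tr$table)$n_trimmed, 0L)
})

test_that("derived outcomes read the trajectory at the leaving time", {
  tr <- fixture_trajectory()  # proportions .5 .4 .3 .2 .1, credits 100..20
  sess <- structure(list(study_variant = "S12",
                         groups = list(structure(list(
                           environment_type = "high_generosity",
                           partners = list(tr), duration = 300),
                           class = "group_spec")),
                         travel_delay = 8, decision_interval = 3.5),
                    class = "session_spec")
  tab <- data.frame(group_index = 1L, partner_index = 1L,
                    leaving_time = c(11, 14, 3.5 * 4),
                    censored = c(FALSE, FALSE, TRUE),
                    proportion_at_leaving = NA_real_,
                    credits_earned = NA_real_)
  out <- derive_outcomes(tab, sess)
  # t = 11 s falls in trial 3's window (onset 10.5): proportion 0.2
  expect_equal(out$proportion_at_leaving, c(0.2, 0.1, 0.1))
  # fully shown before 11 s: trials 0-2 (displays end at 3.5, 7, 10.5 s)
  expect_equal(out$credits_earned[1], 100 + 80 + 60)
  expect_equal(out$credits_earned[2], 100 + 80 + 60 + 40)
  expect_equal(out$credits_earned[3], sum(tr$decisions$credits_shared))
})

test_that("effect coding makes the intercept the grand mean on balanced data", {
  set.seed(71)
  tab <- fixture_trial_table(noise_sd = 1e-3)
  prep <- prepare_trial_table(tab)
  expect_setequal(unique(prep$partner_code), c(-0.5, 0.5))
  fit <- fit_lmm(prep)
  b <- fit$coefficients
  expect_equal(b$beta[b$term == "(Intercept)"], 27.5, tolerance = 1e-2)
  # half coding: main effects equal level differences averaged over the other
  expect_equal(b$beta[b$term == "partner_code"], -10, tolerance = 1e-2)
  expect_equal(b$beta[b$term == "env_code"], -15, tolerance = 1e-2)
  # unit coding halves the coefficients
  fit2 <- fit_lmm(prepare_trial_table(tab, coding = "unit"))
  b2 <- fit2$coefficients
  expect_equal(b2$beta[b2$term == "partner_code"], -5, tolerance = 1e-2)
  expect_true(all(fit$wald$chisq >= 0))
  expect_true(all(b$ci_lo <= b$beta & b$beta <= b$ci_hi))
})

test_that("degenerate designs are rejected", {
  tab <- fixture_trial_table(noise_sd = 0.1)
  one_env <- prepare_trial_table(tab[tab$environment_type == "high_generosity", ])
  expect_error(fit_lmm(one_env), "environment")
  one_id <- prepare_trial_table(tab[tab$participant_id == "p01", ])
  expect_error(fit_lmm(one_id), "two participants")
})

test_that("simple effects reproduce cell-mean contrasts on balanced data", {
  set.seed(72)
  tab <- fixture_trial_table(cell_means = c(fair_high = 40, unfair_high = 30,
                                            fair_low = 25, unfair_low = 20),
                             noise_sd = 1e-3)
  fit <- fit_lmm(prepare_trial_table(tab))
  se <- simple_effects(fit)
  # environment contrast (low - high) within each partner level
  est <- se$estimate[order(se$partner_code)]
  expect_equal(est, c(-15, -10), tolerance = 1e-2)  # fair (-0.5), unfair (+0.5)
})

test_that("covariate model comparison returns comparable BICs", {
  set.seed(73)
  spec <- cohort_spec(n_participants = 20, covariate = "depression",
                      covariate_effect = 0.2, seed = 74)
  beh <- generate_behaviour(sample_cohort(spec), "S4", n_groups = 2, seed = 75)
  tab <- prepare_trial_table(censor_nonleaves(beh$lt), scores = beh$scores)
  cmp <- compare_covariate_models(tab)
  expect_equal(cmp$model, c("depression", "loneliness", "joint"))
  expect_true(all(is.finite(cmp$bic)))
  # the joint model pays the parsimony price on a single-driver cohort
  expect_lt(cmp$bic[cmp$model == "depression"], cmp$bic[cmp$model == "joint"])
  expect_identical(cmp, compare_covariate_models(tab))  # deterministic refit
})

test_that("filter accounting reconciles every input row", {
  set.seed(76)
  spec <- cohort_spec(n_participants = 8, attention_fail_rate = c(1, rep(0.05, 7)),
                      seed = 77)
  beh <- generate_behaviour(sample_cohort(spec), "S4", n_groups = 2, seed = 78)
  n_in <- nrow(beh$lt)
  excl <- apply_exclusions(censor_nonleaves(beh$lt), "S4", beh$scores)
  n_excluded_rows <- n_in - nrow(excl$table)
  prep <- prepare_trial_table(excl$table, scores = beh$scores)
  tr <- trim_outliers(prep)
  expect_equal(nrow(tr$table) + tr$n_trimmed + n_excluded_rows, n_in)
})
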