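test_that("exponential decay evaluates the sharing trajectory", {
  expect_equal(decay_proportion(0.5, 0, 10), 0.5)
  expect_equal(decay_proportion(0.5, -0.125, 0), 0.5)
  # 0.5 * e^(-1), evaluated independently at high precision
  expect_equal(decay_proportion(0.5, -0.2, 5), 0.18393972058572117, tolerance = 1e-12)
  expect_error(decay_proportion(0.5, -0.2, -1), "non-negative")
})

test_that("fairness floor rule replaces or clamps small proportions", {
  expect_equal(apply_fairness_rule(c(0.5, 0.06, 0.04), "zero_replace"),
               c(0.5, 0.06, 0))
  expect_equal(apply_fairness_rule(c(0.5, 0.06, 0.04), "clamp"),
               c(0.5, 0.06, 0.05))
  # the boundary value is not "below 0.05"
  expect_equal(apply_fairness_rule(0.05, "zero_replace"), 0.05)
  expect_equal(apply_fairness_rule(0.05, "clamp"), 0.05)
  expect_error(apply_fairness_rule(c(0.5), "truncate"))
  expect_error(apply_fairness_rule(-0.1, "clamp"), "non-negative")
})

test_that("first offers are uniform within the variant's bounds", {
  set.seed(11)
  x12 <- sample_first_offer("S12", 1e5)
  x4 <- sample_first_offer("S4", 1e4)
  expect_true(all(x12 >= 0.475 & x12 <= 0.525))
  expect_true(all(x4 >= 0.47 & x4 <= 0.53))
  se <- (0.05 / sqrt(12)) / sqrt(1e5)
  expect_equal(mean(x12), 0.5, tolerance = 5 * se)
})

test_that("credit blocks sum to 500 within bounds", {
  set.seed(12)
  blocks <- sample_credit_block(500)
  expect_true(all(rowSums(blocks) == 500))
  expect_true(all(blocks >= 50 & blocks <= 200))
  expect_true(is.integer(blocks))
})

test_that("stakes are the credits/proportion quotient with the zero rule", {
  expect_equal(stake_from_credits(100, 0.5), 200)
  expect_equal(stake_from_credits(83, 0.415), 200)  # checked by 0.415 * 200 = 83
  set.seed(13)
  z <- stake_from_credits(rep(100, 200), rep(0, 200))
  expect_true(all(z >= 200 & z <= 2000))
})

test_that("the 17-rate variant's credit and timing samplers match their moments", {
  set.seed(14)
  cr <- sample_stake_s4(1e5)
  expect_equal(mean(cr), 400, tolerance = 3 * 30 / sqrt(1e5))
  expect_equal(sd(cr), 30, tolerance = 3 * 30 / sqrt(2e5))
  expect_equal(sample_stake_s4(5, sd = 0), rep(400, 5))
  du <- sample_trial_duration_s4(1e5)
  expect_equal(mean(du), 3.5, tolerance = 3 * (1 / sqrt(12)) / sqrt(1e5))
  expect_true(all(du >= 1.0))
  expect_equal(sample_trial_duration_s4(3, jitter_width = 0), rep(3.5, 3))
})

test_that("noisy trajectories decay with clamped gaussian noise", {
  spec <- partner_spec(-0.1, "S4")
  set.seed(15)
  p <- noisy_trajectory_s4(spec, noise_sd = 0)
  noiseless <- apply_fairness_rule(decay_proportion(0.5, -0.1, 0:29), "clamp")
  expect_equal(p[-1], noiseless[-1])  # trial 0 is the first-offer draw
  expect_true(p[1] >= 0.47 && p[1] <= 0.53)
  # moment check at a pre-clamp trial (trial 3: decayed value ~0.37 >> 0.05)
  set.seed(16)
  devs <- replicate(2e4, noisy_trajectory_s4(spec)[4]) - noiseless[4]
  expect_lt(abs(sd(devs) - 0.015), 3 * 0.015 / sqrt(4e4))
  set.seed(17)
  expect_true(all(noisy_trajectory_s4(partner_spec(-0.175, "S4")) >= 0.05))
})

test_that("partner trajectories have 30 decisions with the variant's rules", {
  set.seed(18)
  p3 <- build_partner(partner_spec(-0.2, "S3"))
  expect_equal(nrow(p3$decisions), 30L)
  # 0.5 e^(-0.2 t) < 0.05 for t >= 12, so the clamp binds
  expect_equal(min(p3$decisions$proportion), 0.05)
  p12f <- build_partner(partner_spec(-0.125, "S12"))
  p12u <- build_partner(partner_spec(-0.2, "S12"))
  expect_true(all(p12f$decisions$proportion[-1] >= p12u$decisions$proportion[-1]))
  expect_equal(p12f$decisions$onset_time, (0:29) * 3.5)
  # credits_shared = proportion * stake where the trajectory is positive
  with(p12f$decisions, expect_equal(credits_shared[proportion > 0],
                                    (proportion * stake)[proportion > 0],
                                    tolerance = 1e-9))
  # six-decision conservation on the sampled credit values
  expect_equal(unique(colSums(matrix(p12f$decisions$credit_value, nrow = 6))),
               500)
})

test_that("group composition honours the windowed fair:unfair ratios", {
  set.seed(19)
  for (i in 1:5) {
    g_hi <- build_group("high_generosity", "S12", n_partners = 16)
    cls <- vapply(g_hi$partners, function(p) p$spec$fairness_class, "")
    win <- matrix(cls, nrow = 4)
    expect_true(all(colSums(win == "fair") == 3))
    g_lo <- build_group("low_generosity", "S12", n_partners = 16)
    cls <- vapply(g_lo$partners, function(p) p$spec$fairness_class, "")
    expect_true(all(colSums(matrix(cls, nrow = 4) == "fair") == 1))
  }
  g3 <- build_group("high_effort", "S3", n_partners = 8)
  cls <- vapply(g3$partners, function(p) p$spec$fairness_class, "")
  expect_equal(sum(cls == "fair"), 4L)
  expect_error(build_group("high_effort", "S12"), "generosity")
  expect_error(build_group("high_generosity", "S3"), "effort")
})

test_that("sessions have the variant's group schedule, reproducibly", {
  set.seed(20)
  s12 <- build_session("S12", n_partners = 4)
  expect_length(s12$groups, 8L)
  envs <- vapply(s12$groups, `[[`, "", "environment_type")
  expect_equal(sum(envs == "high_generosity"), 4L)
  expect_equal(s12$travel_delay, 8)
  set.seed(21)
  s4 <- build_session("S4", n_partners = 4)
  expect_length(s4$groups, 10L)
  # seeded determinism: identical seeds give identical session logs
  set.seed(22); a <- session_log(build_session("S12", n_partners = 4))
  set.seed(22); b <- session_log(build_session("S12", n_partners = 4))
  expect_identical(a, b)
})

test_that("effort requirements are rounded fractions of the participant maximum", {
  cal <- effort_calibration(40)
  expect_equal(effort_requirement(cal, "low_effort"), 8L)
  expect_equal(effort_requirement(cal, "high_effort"), 36L)
  expect_error(effort_calibration(0), "positive")
  expect_error(effort_requirement(cal, "high_generosity"), "effort")
})

test_that("offered reward is neutral between partner classes", {
  set.seed(23)
  fair <- build_group("high_generosity", "S12", n_partners = 40)
  cls <- vapply(fair$partners, function(p) p$spec$fairness_class, "")
  cred <- t(vapply(fair$partners, function(p) p$decisions$credit_value,
                   numeric(30)))
  m_fair <- mean(cred[cls == "fair", ])
  m_unfair <- mean(cred[cls == "unfair", ])
  # both classes draw from the same constrained sampler: mean 500/6 each
  expect_equal(m_fair, 500 / 6, tolerance = 1.5)
  expect_equal(m_unfair, 500 / 6, tolerance = 2.5)
})

test_that("decay-rate ordering: smaller |rate| shares weakly more", {
  t_idx <- 0:29
  p_slow <- decay_proportion(0.5, -0.075, t_idx)
  p_fast <- decay_proportion(0.5, -0.175, t_idx)
  expect_true(all(p_slow >= p_fast))
})
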