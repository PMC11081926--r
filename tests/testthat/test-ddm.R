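test_that("parameter and signal constructors guard their invariants", {
  expect_error(ddm_params("fairness", threshold = Inf, drift_gain = 0.5,
                          noise_sd = 0.3), "finite")
  expect_error(ddm_params("fairness", threshold = 2, drift_gain = 0.5,
                          noise_sd = 0.3, start_bias = 2.5), "below threshold")
  expect_error(reward_signal(fixture_trajectory(), reward_scale = 0),
               "positive")
  expect_error(fairness_signal(structure(list(), class = "list")))
})

test_that("input signals follow step semantics over the decision stream", {
  tr <- fixture_trajectory(proportions = c(0.5, 0.4), credits = c(100, 0))
  f <- fairness_signal(tr)
  expect_equal(signal_at(f, 2), 0.5)
  expect_equal(signal_at(f, 4), 0.4)
  expect_equal(signal_at(f, 0), 0.5)  # first offer visible at connection
  expect_equal(f$horizon, 7)
  r <- reward_signal(tr, reward_scale = 0.01)
  expect_equal(r$values, c(1.0, 0))
  # F at every onset equals that decision's proportion, on generated partners
  set.seed(31)
  for (i in 1:5) {
    p <- build_partner(partner_spec(-0.125, "S12"))
    sig <- fairness_signal(p)
    expect_equal(signal_at(sig, p$decisions$onset_time),
                 p$decisions$proportion)
  }
})

test_that("noiseless simulation matches closed forms", {
  zero_sig <- ddm_signal(0, 0, 110)
  p <- ddm_params("standard", threshold = 10, drift_gain = 0.5, noise_sd = 0)
  out <- simulate_leaving(p, zero_sig)
  expect_equal(out$leaving_time, 20, tolerance = 0.001)
  expect_false(out$censored)
  expect_equal(deterministic_leaving(p, zero_sig)$leaving_time, 20)
  # zero net drift never crosses
  p2 <- ddm_params("fairness", threshold = 5, drift_gain = 0.4, noise_sd = 0)
  flat <- ddm_signal(0, 0.4, 50)
  expect_true(simulate_leaving(p2, flat)$censored)
  expect_true(deterministic_leaving(p2, flat)$censored)
})

test_that("stochastic simulator agrees with the analytic oracle at zero noise", {
  set.seed(32)
  for (i in 1:20) {
    sig <- random_signal()
    p <- ddm_params("fairness", threshold = runif(1, 1, 10),
                    drift_gain = runif(1, 0.2, 1.2), noise_sd = 0,
                    start_bias = runif(1, 0, 0.8))
    det <- deterministic_leaving(p, sig)
    sim <- simulate_leaving(p, sig)
    expect_equal(sim$censored, det$censored)
    if (!det$censored) {
      expect_lt(abs(sim$leaving_time - det$leaving_time), p$dt + 1e-9)
    }
  }
})

test_that("halving dt changes noiseless first-passage times by at most dt", {
  set.seed(33)
  sig <- random_signal()
  p1 <- ddm_params("fairness", threshold = 4, drift_gain = 0.6, noise_sd = 0,
                   dt = 0.002)
  p2 <- ddm_params("fairness", threshold = 4, drift_gain = 0.6, noise_sd = 0,
                   dt = 0.001)
  t1 <- simulate_leaving(p1, sig)$leaving_time
  t2 <- simulate_leaving(p2, sig)$leaving_time
  expect_lt(abs(t1 - t2), 0.002 + 1e-9)
})

test_that("evidence stays non-negative and starts at the bias", {
  p <- ddm_params("fairness", threshold = 5, drift_gain = 0.1, noise_sd = 0.5,
                  start_bias = 0.4, dt = 0.01)
  strong <- ddm_signal(0, 0.53, 30)  # strongly negative net drift
  set.seed(34)
  tr <- simulate_leaving(p, strong, trace = TRUE)
  expect_equal(tr$ea[1], 0.4)
  expect_true(all(tr$ea >= 0))
})

test_that("the standard variant is input-independent across environments", {
  p <- ddm_params("standard", threshold = 6, drift_gain = 0.4, noise_sd = 0.3,
                  dt = 0.02)
  set.seed(35)
  hi <- simulate_lt_distribution(p, "high_generosity", 200)
  set.seed(35)
  lo <- simulate_lt_distribution(p, "low_generosity", 200)
  expect_identical(hi$leaving_time, lo$leaving_time)
  expect_equal(nrow(hi), 200L)
})

test_that("environment mixtures order fairness-model leaving times", {
  # more fair partners (slower decay) mean evidence to leave accrues more
  # slowly, so the generous environment holds agents longer at equal params
  p <- ddm_params("fairness", threshold = 4, drift_gain = 0.3, noise_sd = 0.2,
                  start_bias = 0.4, dt = 0.02)
  set.seed(36)
  hi <- simulate_lt_distribution(p, "high_generosity", 3000)$leaving_time
  lo <- simulate_lt_distribution(p, "low_generosity", 3000)$leaving_time
  expect_gt(mean(hi), mean(lo))
})

test_that("pointwise-larger fairness input gives stochastically larger LTs", {
  p <- ddm_params("fairness", threshold = 4, drift_gain = 0.6, noise_sd = 0.3,
                  dt = 0.01)
  hi_sig <- ddm_signal(0, 0.45, 105)
  lo_sig <- ddm_signal(0, 0.25, 105)
  set.seed(37)
  lt_hi <- replicate(400, simulate_leaving(p, hi_sig)$leaving_time)
  lt_lo <- replicate(400, simulate_leaving(p, lo_sig)$leaving_time)
  qs <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(quantile(lt_hi, qs) >= quantile(lt_lo, qs) - 0.5))
})

test_that("mean leaving time is monotone in threshold and drift gain", {
  set.seed(38)
  mk <- function(th, dg) {
    p <- ddm_params("fairness", threshold = th, drift_gain = dg,
                    noise_sd = 0.3, dt = 0.02)
    lt <- simulate_lt_distribution(p, "high_generosity", 2000)$leaving_time
    c(mean(lt), sd(lt) / sqrt(length(lt)))
  }
  lo_th <- mk(3, 0.5); hi_th <- mk(6, 0.5)
  expect_gt(hi_th[1], lo_th[1] - 2 * (lo_th[2] + hi_th[2]))
  lo_dg <- mk(4, 0.4); hi_dg <- mk(4, 0.8)
  expect_lt(hi_dg[1], lo_dg[1] + 2 * (lo_dg[2] + hi_dg[2]))
})

test_that("session walking respects the task clock and censoring", {
  set.seed(39)
  sess <- build_session("S12", n_groups = 2, n_partners = 38)
  # an agent that never crosses: every interaction censored at 101.5 s
  never <- ddm_params("standard", threshold = 30, drift_gain = 0.01,
                      noise_sd = 0)
  pe <- list(high_generosity = never, low_generosity = never)
  tab <- simulate_participant_session(pe, sess)
  expect_true(all(tab$censored))
  expect_true(all(tab$leaving_time == 101.5))
  # schedule bound: interactions + travel fit in 300 s plus one overhang
  for (gi in unique(tab$group_index)) {
    sub <- tab[tab$group_index == gi, ]
    spent <- sum(ifelse(sub$censored, 105, sub$leaving_time) + 8)
    expect_lte(spent, 300 + 105 + 8)
  }
  # a higher threshold leads to fewer partners visited on average
  set.seed(40)
  quick <- ddm_params("standard", threshold = 2, drift_gain = 0.4, noise_sd = 0.2)
  slow <- ddm_params("standard", threshold = 12, drift_gain = 0.4, noise_sd = 0.2)
  n_quick <- n_slow <- 0
  for (i in 1:5) {
    s <- build_session("S12", n_groups = 2, n_partners = 38)
    n_quick <- n_quick + nrow(simulate_participant_session(
      list(high_generosity = quick, low_generosity = quick), s))
    n_slow <- n_slow + nrow(simulate_participant_session(
      list(high_generosity = slow, low_generosity = slow), s))
  }
  expect_gt(n_quick, n_slow)
  expect_error(simulate_participant_session(list(high_generosity = quick), sess),
               "missing parameters")
})
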