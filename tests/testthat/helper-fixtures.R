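# shared lightweight fixtures and small helpers for the suite

# a deterministic partner trajectory with known proportions/credits
fixture_trajectory <- function(proportions = c(0.5, 0.4, 0.3, 0.2, 0.1),
                               credits = c(100, 80, 60, 40, 20),
                               interval = 3.5) {
  n <- length(proportions)
  structure(list(
    spec = structure(list(decay_rate = -0.125, fairness_class = "fair",
                          n_decisions = n, study_variant = "S12"),
                     class = "partner_spec"),
    decisions = data.frame(trial_index = seq_len(n) - 1L,
                           onset_time = (seq_len(n) - 1L) * interval,
                           proportion = proportions,
                           stake = ifelse(proportions > 0,
                                          credits / pmax(proportions, 1e-9), 500),
                           credit_value = credits,
                           credits_shared = ifelse(proportions > 0, credits, 0)),
    first_offer_bounds = c(0.475, 0.525)
  ), class = "partner_trajectory")
}

# random piecewise-constant signal with breakpoints on the dt grid
random_signal <- function(dt = 0.001, max_value = 0.53) {
  nseg <- sample(2:8, 1)
  brk <- c(0, sort(sample(seq(dt, 60, by = 0.5), nseg - 1)))
  ddm_signal(brk, stats::runif(nseg, 0, max_value), horizon = 80)
}

# leaving-time table fixture for the statistics stage: balanced two-by-two
# design with specified cell means (fair/unfair x high/low generosity)
fixture_trial_table <- function(cell_means = c(fair_high = 40, unfair_high = 30,
                                               fair_low = 25, unfair_low = 15),
                                n_per_cell = 4, n_participants = 6,
                                noise_sd = 0) {
  rows <- expand.grid(participant_id = sprintf("p%02d", seq_len(n_participants)),
                      rep = seq_len(n_per_cell),
                      decay_rate = c(-0.125, -0.2),
                      environment_type = c("high_generosity", "low_generosity"),
                      stringsAsFactors = FALSE)
  cls <- ifelse(rows$decay_rate == -0.125, "fair", "unfair")
  env <- ifelse(rows$environment_type == "high_generosity", "high", "low")
  rows$leaving_time <- cell_means[paste(cls, env, sep = "_")] +
    if (noise_sd > 0) stats::rnorm(nrow(rows), 0, noise_sd) else 0
  rows$censored <- FALSE
  rows$study_variant <- "S12"
  rows$rep <- NULL
  rows
}
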