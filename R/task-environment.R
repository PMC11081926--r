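#' Task configuration constants
#'
#' All fixed constants of the virtual partner-leaving task in one declarative
#' object: fairness floors, first-offer bounds, credit bounds, composition
#' ratios, timing, and the decay-rate sets that define fair and unfair
#' partners in each study variant.
#'
#' Study variants: `"S12"` (two decay rates, proportions below 0.05 replaced
#' by zero, generosity environments), `"S3"` (same decay rates, proportions
#' clamped at 0.05, effort environments), `"S4"` (17 decay rates, per-decision
#' trajectory noise, clamped at 0.05, generosity environments, jittered trial
#' timing).
#'
#' @return A named list of constants.
#' @export
task_config <- function() {
  list(
    n_decisions       = 30L,
    decision_interval = 3.5,    # seconds between sharing decisions (S12/S3)
    travel_delay      = 8,      # seconds between partners
    block_duration    = 300,    # seconds per group
    fairness_floor    = 0.05,
    start_proportion  = 0.5,
    first_offer_bounds = list(S12 = c(0.475, 0.525),
                              S3  = c(0.475, 0.525),
                              S4  = c(0.47, 0.53)),
    decay_rates_s12   = c(fair = -0.125, unfair = -0.2),
    decay_rates_s4_fair   = c(-0.075, -0.080, -0.085, -0.090, -0.095,
                              -0.100, -0.105, -0.110, -0.115),
    decay_rates_s4_unfair = c(-0.175, -0.170, -0.165, -0.160, -0.155,
                              -0.150, -0.145, -0.140),
    credit_bounds     = c(50, 200),
    credit_block_sum  = 500,
    credit_block_len  = 6L,
    zero_stake_bounds = c(200, 2000),
    s4_credit_mean    = 400,
    s4_credit_sd      = 30,
    s4_trajectory_noise_sd = 0.015,
    s4_display_time   = 1.0,    # seconds the sharing bar is on screen
    s4_jitter_bounds  = c(2.0, 3.0),  # uniform ISI jitter, mean 2.5 s
    groups_per_session = c(S12 = 8L, S3 = 8L, S4 = 10L),
    window_size       = 4L,     # partner-composition window
    effort_fractions  = c(low = 0.20, high = 0.90)
  )
}

.variants <- c("S12", "S3", "S4")

.check_variant <- function(study_variant) {
  if (!is.character(study_variant) || length(study_variant) != 1L ||
      !study_variant %in% .variants) {
    stop("`study_variant` must be one of ", paste(.variants, collapse = ", "))
  }
  study_variant
}

#' Exponential fairness decay
#'
#' Proportion shared on a given trial under pure exponential decay:
#' `s * exp(decay_rate * trial_index)`. No floor or zero rule is applied.
#'
#' @param s Starting proportion in (0, 1].
#' @param decay_rate Per-trial exponential decay rate (<= 0 for decay).
#' @param trial_index 0-based trial index (vectorised).
#' @return Proportion(s) shared.
#' @export
decay_proportion <- function(s, decay_rate, trial_index) {
  stopifnot(is.numeric(s), s > 0, s <= 1, is.numeric(decay_rate))
  if (any(trial_index < 0)) stop("`trial_index` must be non-negative")
  s * exp(decay_rate * trial_index)
}

#' Apply the study's fairness floor rule
#'
#' Proportions below 0.05 are either replaced with zero (the two-rate
#' variants, where receiving nothing signals it is time to leave) or clamped
#' at 0.05 (the variants that remove the economic-rationality confound).
#'
#' @param raw_proportions Non-negative numeric vector of raw proportions.
#' @param mode `"zero_replace"` or `"clamp"`.
#' @return Numeric vector with the rule applied.
#' @export
apply_fairness_rule <- function(raw_proportions, mode = c("zero_replace", "clamp")) {
  mode <- match.arg(mode)
  if (any(raw_proportions < 0)) stop("proportions must be non-negative")
  floor_ <- task_config()$fairness_floor
  below <- raw_proportions < floor_
  raw_proportions[below] <- if (mode == "zero_replace") 0 else floor_
  raw_proportions
}

#' First-offer proportion
#'
#' The first sharing decision is always an approximately equal split: a
#' uniform draw within variant-specific bounds around 0.5.
#'
#' @param study_variant `"S12"`, `"S3"` or `"S4"`.
#' @param n Number of draws.
#' @return Numeric vector of first-offer proportions.
#' @export
sample_first_offer <- function(study_variant, n = 1L) {
  b <- task_config()$first_offer_bounds[[.check_variant(study_variant)]]
  stats::runif(n, b[1], b[2])
}

#' Constrained credit blocks
#'
#' Credits shared per decision in the two-rate variants are uniform on
#' [50, 200] subject to every block of six decisions summing to exactly 500,
#' so the average offered reward is identical across partners and
#' environments. The sampler draws i.i.d. uniforms, rescales each block to
#' the target sum, repairs bound violations by clipping and redistributing
#' the residual over unclipped entries, then rounds to integers preserving
#' the total (largest-remainder).
#'
#' @param n_blocks Number of six-decision blocks.
#' @return Integer matrix, `n_blocks` x 6, each row summing to 500 with all
#'   entries in [50, 200].
#' @export
sample_credit_block <- function(n_blocks = 1L) {
  cfg <- task_config()
  lo <- cfg$credit_bounds[1]; hi <- cfg$credit_bounds[2]
  total <- cfg$credit_block_sum; k <- cfg$credit_block_len
  x <- matrix(stats::runif(n_blocks * k, lo, hi), nrow = n_blocks)
  x <- x * (total / rowSums(x))
  # clip-and-redistribute until all entries are inside the bounds
  for (iter in 1:50) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    clipped <- pmin(pmax(x, lo), hi)
    resid <- total - rowSums(clipped)
    free <- !bad
    nfree <- rowSums(free)
    # spread each row's residual equally over its unclipped entries
    adj <- ifelse(free, resid / pmax(nfree, 1L), 0)
    x <- clipped + adj
  }
  # integer rounding preserving the row sums
  fl <- floor(x)
  need <- total - rowSums(fl)
  rem <- x - fl
  out <- fl
  for (i in seq_len(n_blocks)) {
    if (need[i] > 0) {
      up <- order(rem[i, ], decreasing = TRUE)[seq_len(need[i])]
      out[i, up] <- out[i, up] + 1
    }
  }
  # rounding can nudge a boundary value outside [lo, hi]; repair by moving units
  for (i in seq_len(n_blocks)) {
    over <- out[i, ] > hi
    while (any(over)) {
      j <- which(over)[1]; tgt <- which.min(out[i, ])
      out[i, j] <- out[i, j] - 1; out[i, tgt] <- out[i, tgt] + 1
      over <- out[i, ] > hi
    }
    under <- out[i, ] < lo
    while (any(under)) {
      j <- which(under)[1]; src <- which.max(out[i, ])
      out[i, j] <- out[i, j] + 1; out[i, src] <- out[i, src] - 1
      under <- out[i, ] < lo
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Stake implied by credits and proportion
#'
#' Stake sizes are the quotient of the credits shared and the proportion
#' shared. When the fairness trajectory has dropped to zero (zero-replace
#' variants) the displayed stake is instead drawn uniformly from
#' [200, 2000] and the credits actually shared are zero.
#'
#' @param credits Credits intended to be shared (vectorised).
#' @param proportion Proportion shared on the decision (vectorised).
#' @return Stake size(s) in credits.
#' @export
stake_from_credits <- function(credits, proportion) {
  stopifnot(all(credits >= 0), all(proportion >= 0))
  n <- max(length(credits), length(proportion))
  credits <- rep_len(credits, n); proportion <- rep_len(proportion, n)
  z <- task_config()$zero_stake_bounds
  out <- numeric(n)
  zero <- proportion == 0
  out[!zero] <- credits[!zero] / proportion[!zero]
  out[zero] <- stats::runif(sum(zero), z[1], z[2])
  out
}

#' Credits shared per decision in the 17-rate variant
#'
#' Absolute credits shared on each decision are normally distributed with
#' mean 400 and standard deviation 30.
#'
#' @param n Number of draws.
#' @param sd Standard deviation override (default 30).
#' @return Numeric vector of credit values.
#' @export
sample_stake_s4 <- function(n = 1L, sd = task_config()$s4_credit_sd) {
  stats::rnorm(n, task_config()$s4_credit_mean, sd)
}

#' Trial duration in the 17-rate variant
#'
#' Each trial shows the sharing bar for 1 s followed by a blank interval
#' jittered uniformly on [2, 3] s (mean 2.5 s), so the average trial lasts
#' 3.5 s as in the fixed-schedule variants.
#'
#' @param n Number of draws.
#' @param jitter_width Width of the jitter interval (default 1 s; 0 gives a
#'   degenerate 3.5 s trial).
#' @return Trial durations in seconds.
#' @export
sample_trial_duration_s4 <- function(n = 1L, jitter_width = 1) {
  cfg <- task_config()
  mid <- mean(cfg$s4_jitter_bounds)
  jit <- stats::runif(n, mid - jitter_width / 2, mid + jitter_width / 2)
  cfg$s4_display_time + jit
}

#' Noisy decay trajectory for the 17-rate variant
#'
#' Per-trial proportions follow the exponential decay plus i.i.d. Gaussian
#' noise (sd 0.015) on trials 1..29, with the first offer drawn separately
#' and all values below 0.05 clamped at 0.05 after the noise.
#'
#' @param spec A [partner_spec()].
#' @param noise_sd Trajectory noise standard deviation (default 0.015).
#' @return Numeric vector of 30 proportions.
#' @export
noisy_trajectory_s4 <- function(spec, noise_sd = task_config()$s4_trajectory_noise_sd) {
  stopifnot(inherits(spec, "partner_spec"), spec$study_variant == "S4")
  cfg <- task_config()
  t_idx <- seq_len(cfg$n_decisions) - 1L
  p <- decay_proportion(cfg$start_proportion, spec$decay_rate, t_idx)
  p[1] <- sample_first_offer("S4")
  if (noise_sd > 0) {
    p[-1] <- p[-1] + stats::rnorm(cfg$n_decisions - 1L, 0, noise_sd)
  }
  p <- pmax(p, 0)
  apply_fairness_rule(p, "clamp")
}

#' Partner specification
#'
#' @param decay_rate Per-trial exponential decay rate; must belong to the
#'   variant's fair or unfair rate set.
#' @param study_variant `"S12"`, `"S3"` or `"S4"`.
#' @return An object of class `partner_spec` with the inferred fairness
#'   class.
#' @export
partner_spec <- function(decay_rate, study_variant) {
  .check_variant(study_variant)
  cfg <- task_config()
  if (study_variant %in% c("S12", "S3")) {
    cls <- names(cfg$decay_rates_s12)[match(decay_rate, cfg$decay_rates_s12)]
    if (is.na(cls)) stop("decay_rate must be -0.125 (fair) or -0.2 (unfair) for ",
                         study_variant)
  } else {
    near <- function(set) any(abs(set - decay_rate) < 1e-9)
    cls <- if (near(cfg$decay_rates_s4_fair)) "fair"
           else if (near(cfg$decay_rates_s4_unfair)) "unfair"
           else stop("decay_rate not in the S4 fair or unfair rate sets")
  }
  structure(list(decay_rate = decay_rate, fairness_class = cls,
                 n_decisions = cfg$n_decisions, study_variant = study_variant),
            class = "partner_spec")
}

#' Build one partner's sharing trajectory
#'
#' Produces the partner's 30 sharing decisions: proportions from the
#' exponential decay (plus trajectory noise for the 17-rate variant) with
#' first-offer replacement and the variant's floor rule; credits and stakes
#' from the variant's sampler; onsets on the 3.5 s grid, or the jittered
#' schedule for the 17-rate variant.
#'
#' @param spec A [partner_spec()].
#' @return An object of class `partner_trajectory`: list with `spec`,
#'   `decisions` (data frame: trial_index, onset_time, proportion, stake,
#'   credit_value, credits_shared), and `first_offer_bounds`.
#' @export
build_partner <- function(spec) {
  stopifnot(inherits(spec, "partner_spec"))
  cfg <- task_config()
  n <- cfg$n_decisions
  t_idx <- seq_len(n) - 1L
  if (spec$study_variant == "S4") {
    p <- noisy_trajectory_s4(spec)
    durations <- sample_trial_duration_s4(n)
    onset <- cumsum(c(0, durations[-n]))
    credit <- sample_stake_s4(n)
    stake <- credit / p
    shared <- credit
  } else {
    p <- decay_proportion(cfg$start_proportion, spec$decay_rate, t_idx)
    p[1] <- sample_first_offer(spec$study_variant)
    mode <- if (spec$study_variant == "S12") "zero_replace" else "clamp"
    p <- apply_fairness_rule(p, mode)
    onset <- t_idx * cfg$decision_interval
    credit <- as.numeric(t(sample_credit_block(n / cfg$credit_block_len)))
    stake <- stake_from_credits(credit, p)
    shared <- ifelse(p == 0, 0, credit)
  }
  structure(list(
    spec = spec,
    decisions = data.frame(trial_index = t_idx, onset_time = onset,
                           proportion = p, stake = stake,
                           credit_value = credit, credits_shared = shared),
    first_offer_bounds = cfg$first_offer_bounds[[spec$study_variant]]
  ), class = "partner_trajectory")
}

.env_types <- c("high_generosity", "low_generosity", "high_effort", "low_effort")

.sample_decay_rate <- function(class, study_variant, n = 1L) {
  cfg <- task_config()
  if (study_variant %in% c("S12", "S3")) {
    rep(cfg$decay_rates_s12[[class]], n)
  } else {
    set <- if (class == "fair") cfg$decay_rates_s4_fair else cfg$decay_rates_s4_unfair
    set[sample.int(length(set), n, replace = TRUE)]
  }
}

#' Partner-class sequence for a group
#'
#' Generosity environments: every consecutive non-overlapping window of four
#' partners holds three fair and one unfair partner (high generosity) or the
#' reverse (low generosity), randomly ordered within the window. Effort
#' environments: two fair and two unfair per window (1:1 overall).
#'
#' @param environment_type One of `"high_generosity"`, `"low_generosity"`,
#'   `"high_effort"`, `"low_effort"`.
#' @param n_partners Number of partners (multiple of 4 recommended).
#' @return Character vector of `"fair"` / `"unfair"`.
#' @export
partner_class_sequence <- function(environment_type, n_partners) {
  stopifnot(environment_type %in% .env_types)
  w <- task_config()$window_size
  n_fair_per_window <- switch(environment_type,
    high_generosity = 3L, low_generosity = 1L,
    high_effort = 2L, low_effort = 2L)
  n_windows <- ceiling(n_partners / w)
  cls <- unlist(lapply(seq_len(n_windows), function(i) {
    sample(c(rep("fair", n_fair_per_window), rep("unfair", w - n_fair_per_window)))
  }))
  cls[seq_len(n_partners)]
}

#' Build a group (one five-minute social environment block)
#'
#' Pre-builds enough partner trajectories to cover 300 s of continuous
#' interaction regardless of leaving behaviour; composition follows the
#' environment's windowed fair:unfair ratio.
#'
#' @param environment_type Environment type; generosity types for the
#'   generosity variants, effort types for `"S3"`.
#' @param study_variant `"S12"`, `"S3"` or `"S4"`.
#' @param n_partners Number of partners pre-built. The 8 s travel delay
#'   bounds the number of partners reachable in a 300 s block at
#'   `ceiling(300 / 8) = 38`, so the default always covers the block.
#' @return Object of class `group_spec`.
#' @export
build_group <- function(environment_type, study_variant, n_partners = 38L) {
  .check_variant(study_variant)
  stopifnot(environment_type %in% .env_types)
  gen_env <- environment_type %in% c("high_generosity", "low_generosity")
  if (study_variant %in% c("S12", "S4") && !gen_env) {
    stop("generosity variants use generosity environments")
  }
  if (study_variant == "S3" && gen_env) {
    stop("the effort variant uses effort environments")
  }
  cls <- partner_class_sequence(environment_type, n_partners)
  rates <- vapply(cls, function(cl) .sample_decay_rate(cl, study_variant),
                  numeric(1))
  partners <- .build_partner_batch(rates, study_variant)
  structure(list(environment_type = environment_type,
                 study_variant = study_variant,
                 partners = partners,
                 duration = task_config()$block_duration),
            class = "group_spec")
}

# vectorised construction of many partner trajectories at once; same
# sampling scheme as build_partner, row-per-partner matrix operations
.build_partner_batch <- function(decay_rates, study_variant) {
  cfg <- task_config()
  n <- length(decay_rates)
  nd <- cfg$n_decisions
  t_idx <- 0:(nd - 1L)
  prop <- cfg$start_proportion * exp(outer(decay_rates, t_idx))
  if (study_variant == "S4") {
    prop[, -1] <- prop[, -1] +
      matrix(stats::rnorm(n * (nd - 1L), 0, cfg$s4_trajectory_noise_sd),
             nrow = n)
    prop <- pmax(prop, 0)
  }
  prop[, 1] <- sample_first_offer(study_variant, n)
  floor_ <- cfg$fairness_floor
  if (study_variant == "S12") prop[prop < floor_] <- 0
  else prop[prop < floor_] <- floor_
  if (study_variant == "S4") {
    credit <- matrix(sample_stake_s4(n * nd), nrow = n)
    durations <- matrix(sample_trial_duration_s4(n * nd), nrow = n)
    onsets <- cbind(0, t(apply(durations[, -nd, drop = FALSE], 1, cumsum)))
    stake <- credit / prop
    shared <- credit
  } else {
    credit <- matrix(as.numeric(t(sample_credit_block(n * nd / cfg$credit_block_len))),
                     nrow = n, byrow = TRUE)
    onsets <- matrix(rep(t_idx * cfg$decision_interval, each = n), nrow = n)
    zero <- prop == 0
    stake <- matrix(0, n, nd)
    stake[!zero] <- credit[!zero] / prop[!zero]
    z <- cfg$zero_stake_bounds
    stake[zero] <- stats::runif(sum(zero), z[1], z[2])
    shared <- credit
    shared[zero] <- 0
  }
  bounds <- cfg$first_offer_bounds[[study_variant]]
  lapply(seq_len(n), function(i) {
    cls <- if (study_variant %in% c("S12", "S3")) {
      names(cfg$decay_rates_s12)[match(decay_rates[i], cfg$decay_rates_s12)]
    } else if (any(abs(cfg$decay_rates_s4_fair - decay_rates[i]) < 1e-9)) {
      "fair"
    } else "unfair"
    structure(list(
      spec = structure(list(decay_rate = decay_rates[i], fairness_class = cls,
                            n_decisions = nd, study_variant = study_variant),
                       class = "partner_spec"),
      decisions = data.frame(trial_index = t_idx, onset_time = onsets[i, ],
                             proportion = prop[i, ], stake = stake[i, ],
                             credit_value = credit[i, ],
                             credits_shared = shared[i, ]),
      first_offer_bounds = bounds
    ), class = "partner_trajectory")
  })
}

#' Build a full session
#'
#' Eight groups (four per environment type) for the two-rate variants, ten
#' (five per generosity level) for the 17-rate variant, in a uniformly random
#' order.
#'
#' @param study_variant `"S12"`, `"S3"` or `"S4"`.
#' @param n_groups Optional override of the number of groups (must be even).
#' @param n_partners Partners pre-built per group.
#' @return Object of class `session_spec`.
#' @export
build_session <- function(study_variant, n_groups = NULL, n_partners = 60L) {
  .check_variant(study_variant)
  cfg <- task_config()
  if (is.null(n_groups)) n_groups <- cfg$groups_per_session[[study_variant]]
  stopifnot(n_groups %% 2 == 0)
  types <- if (study_variant == "S3") c("high_effort", "low_effort")
           else c("high_generosity", "low_generosity")
  env_seq <- sample(rep(types, each = n_groups / 2))
  groups <- lapply(env_seq, build_group, study_variant = study_variant,
                   n_partners = n_partners)
  structure(list(study_variant = study_variant, groups = groups,
                 travel_delay = cfg$travel_delay,
                 decision_interval = cfg$decision_interval),
            class = "session_spec")
}

#' Effort calibration
#'
#' @param max_presses Participant's maximum number of key presses in 8 s.
#' @param low_fraction,high_fraction Fractions of maximum required in the
#'   low- and high-effort environments (defaults 0.20 and 0.90).
#' @return Object of class `effort_calibration`.
#' @export
effort_calibration <- function(max_presses,
                               low_fraction = task_config()$effort_fractions[["low"]],
                               high_fraction = task_config()$effort_fractions[["high"]]) {
  if (!is.numeric(max_presses) || max_presses <= 0) {
    stop("`max_presses` must be a positive number")
  }
  stopifnot(low_fraction > 0, low_fraction < high_fraction, high_fraction <= 1)
  structure(list(max_presses = max_presses, low_fraction = low_fraction,
                 high_fraction = high_fraction), class = "effort_calibration")
}

#' Required presses for an effort environment
#'
#' @param cal An [effort_calibration()].
#' @param environment_type `"low_effort"` or `"high_effort"`.
#' @return Integer number of required presses (rounded).
#' @export
effort_requirement <- function(cal, environment_type) {
  stopifnot(inherits(cal, "effort_calibration"))
  if (!environment_type %in% c("low_effort", "high_effort")) {
    stop("effort requirements apply only to effort environments")
  }
  frac <- if (environment_type == "low_effort") cal$low_fraction else cal$high_fraction
  as.integer(round(frac * cal$max_presses))
}

#' Session log table
#'
#' Flattens a session into one row per sharing decision, the CSV-ready form
#' of the generated stimuli.
#'
#' @param session A [build_session()] result.
#' @param participant_id Identifier copied into every row.
#' @return data.frame with columns participant_id, study_variant,
#'   group_index, environment_type, partner_index, decay_rate, trial_index,
#'   onset_s, proportion, stake, credit_value, credits_shared.
#' @export
session_log <- function(session, participant_id = "p1") {
  stopifnot(inherits(session, "session_spec"))
  rows <- lapply(seq_along(session$groups), function(g) {
    grp <- session$groups[[g]]
    do.call(rbind, lapply(seq_along(grp$partners), function(j) {
      tr <- grp$partners[[j]]
      data.frame(participant_id = participant_id,
                 study_variant = session$study_variant,
                 group_index = g,
                 environment_type = grp$environment_type,
                 partner_index = j,
                 decay_rate = tr$spec$decay_rate,
                 tr$decisions, row.names = NULL)
    }))
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "onset_time"] <- "onset_s"
  out
}
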