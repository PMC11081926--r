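#' Drift-diffusion model parameters
#'
#' Parameter set for the leaving-time accumulator. Evidence to leave
#' accumulates as `dEA = (drift_gain - X(t)) dt + noise`, clamped at zero,
#' starting from `start_bias`, and a leave is triggered when EA exceeds
#' `threshold`. The input `X(t)` is the partner's current fairness
#' (`variant = "fairness"`), the scaled reward (`"reward"`,
#' `X = reward_scale * credits`), or zero (`"standard"`).
#'
#' @param variant `"standard"`, `"reward"` or `"fairness"`.
#' @param threshold Decision threshold (> 0).
#' @param drift_gain Drift gain (the constant part of the net drift).
#' @param noise_sd Accumulation noise standard deviation (>= 0).
#' @param start_bias Starting evidence level (prior bias toward leaving);
#'   must be below the threshold.
#' @param dt Euler step in seconds (default 0.001).
#' @param reward_scale Multiplicative normaliser bringing credits into the
#'   range of fairness proportions (default 0.01; reward variant only).
#' @return Object of class `ddm_params`.
#' @export
ddm_params <- function(variant = c("fairness", "reward", "standard"),
                       threshold, drift_gain, noise_sd, start_bias = 0,
                       dt = 0.001, reward_scale = 0.01) {
  variant <- match.arg(variant)
  vals <- c(threshold, drift_gain, noise_sd, start_bias, dt, reward_scale)
  if (any(!is.finite(vals))) stop("all parameters must be finite")
  stopifnot(threshold > 0, noise_sd >= 0, start_bias >= 0, dt > 0,
            reward_scale > 0)
  if (start_bias >= threshold) stop("start_bias must be below threshold")
  structure(list(variant = variant, threshold = threshold,
                 drift_gain = drift_gain, noise_sd = noise_sd,
                 start_bias = start_bias, dt = dt,
                 reward_scale = reward_scale),
            class = "ddm_params")
}

.check_signal <- function(signal) {
  stopifnot(is.list(signal), length(signal$values) >= 1L,
            length(signal$breakpoints) == length(signal$values),
            signal$horizon > 0)
  signal
}

#' Piecewise-constant input signal
#'
#' @param breakpoints Segment onset times in seconds; first must be 0.
#' @param values Signal value on each segment (right-continuous step
#'   function).
#' @param horizon End of the signal's domain in seconds.
#' @return Object of class `ddm_signal`.
#' @export
ddm_signal <- function(breakpoints, values, horizon) {
  stopifnot(length(breakpoints) == length(values), breakpoints[1] == 0,
            !is.unsorted(breakpoints), horizon > max(breakpoints))
  structure(list(breakpoints = breakpoints, values = values,
                 horizon = horizon), class = "ddm_signal")
}

#' Evaluate a signal at given times
#' @param signal A [ddm_signal()].
#' @param t Times in seconds.
#' @return Signal values at `t`.
#' @export
signal_at <- function(signal, t) {
  .check_signal(signal)
  idx <- findInterval(t, signal$breakpoints)
  idx[idx < 1L] <- 1L
  signal$values[idx]
}

#' Fairness input signal from a partner trajectory
#'
#' `F(t)` equals the proportion of the most recently revealed sharing
#' decision; before the first decision is revealed it equals the first
#' offer (visible at connection). The horizon extends one decision interval
#' past the final onset.
#'
#' @param trajectory A [build_partner()] result.
#' @return A [ddm_signal()].
#' @export
fairness_signal <- function(trajectory) {
  stopifnot(inherits(trajectory, "partner_trajectory"))
  d <- trajectory$decisions
  if (nrow(d) < 1L) stop("trajectory has no decisions")
  interval <- if (nrow(d) > 1L) d$onset_time[nrow(d)] - d$onset_time[nrow(d) - 1L]
              else task_config()$decision_interval
  ddm_signal(d$onset_time, d$proportion, d$onset_time[nrow(d)] + interval)
}

#' Reward input signal from a partner trajectory
#'
#' Segment values are `reward_scale * credits_shared`, step semantics as in
#' [fairness_signal()].
#'
#' @param trajectory A [build_partner()] result.
#' @param reward_scale Positive scaling constant (default 0.01).
#' @return A [ddm_signal()].
#' @export
reward_signal <- function(trajectory, reward_scale = 0.01) {
  stopifnot(inherits(trajectory, "partner_trajectory"))
  if (!is.numeric(reward_scale) || reward_scale <= 0) {
    stop("`reward_scale` must be positive")
  }
  f <- fairness_signal(trajectory)
  ddm_signal(f$breakpoints, reward_scale * trajectory$decisions$credits_shared,
             f$horizon)
}

#' Simulate one leaving time
#'
#' Euler–Maruyama simulation of the clamped accumulator against a
#' piecewise-constant input. Per-step noise is `noise_sd * sqrt(dt)` under
#' the default `"euler"` scaling; `"literal"` adds `noise_sd` per step
#' verbatim (kept for comparison; at dt = 0.001 it integrates to far more
#' noise than any plausible threshold contains).
#'
#' @param params A [ddm_params()].
#' @param signal A [ddm_signal()]; ignored (treated as zero) for the
#'   standard variant.
#' @param trace If `TRUE`, also return the full evidence trace.
#' @param noise_scaling `"euler"` or `"literal"`.
#' @return List with `leaving_time` (seconds) and `censored`; with
#'   `trace = TRUE` also `times` and `ea`.
#' @export
simulate_leaving <- function(params, signal, trace = FALSE,
                             noise_scaling = c("euler", "literal")) {
  stopifnot(inherits(params, "ddm_params"))
  .check_signal(signal)
  noise_scaling <- match.arg(noise_scaling)
  vals <- if (params$variant == "standard") rep(0, length(signal$values))
          else signal$values
  if (trace) {
    res <- ddm_trace_cpp(vals, signal$breakpoints, signal$horizon,
                         params$threshold, params$drift_gain, params$noise_sd,
                         params$start_bias, params$dt,
                         noise_scaling == "literal")
    return(res)
  }
  res <- ddm_first_passage_batch(matrix(vals, nrow = 1L), signal$breakpoints,
                                 signal$horizon, params$threshold,
                                 params$drift_gain, params$noise_sd,
                                 params$start_bias, params$dt,
                                 noise_scaling == "literal")
  list(leaving_time = res$leaving_time[1], censored = res$censored[1])
}

#' Noiseless first-passage time (analytic oracle)
#'
#' Exact first-passage time of the clamped integral of
#' `(drift_gain - X(t))` over the piecewise-constant signal; analytic within
#' each constant segment. Used as the deterministic reference for the
#' stochastic simulator.
#'
#' @param params A [ddm_params()] (noise is treated as zero).
#' @param signal A [ddm_signal()].
#' @return List with `leaving_time` and `censored`.
#' @export
deterministic_leaving <- function(params, signal) {
  stopifnot(inherits(params, "ddm_params"))
  .check_signal(signal)
  vals <- if (params$variant == "standard") rep(0, length(signal$values))
          else signal$values
  ea <- params$start_bias
  th <- params$threshold
  starts <- signal$breakpoints
  ends <- c(starts[-1], signal$horizon)
  for (j in seq_along(vals)) {
    drift <- params$drift_gain - vals[j]
    len <- ends[j] - starts[j]
    if (len <= 0) next
    if (drift > 0 && ea + drift * len > th) {
      return(list(leaving_time = starts[j] + (th - ea) / drift,
                  censored = FALSE))
    }
    ea <- max(0, ea + drift * len)
  }
  list(leaving_time = signal$horizon, censored = TRUE)
}

# Build n partner-trajectory signal matrices for one environment's partner
# mixture, vectorised. Fixed 3.5 s onset grid (the fitting environments are
# the two-rate generosity task). Returns list(breaks, fairness, reward_credits,
# horizon, censor_value).
.environment_signal_batch <- function(environment_type, n,
                                      study_variant = "S12") {
  cfg <- task_config()
  p_fair <- switch(environment_type,
    high_generosity = 0.75, low_generosity = 0.25,
    high_effort = 0.5, low_effort = 0.5)
  n_dec <- cfg$n_decisions
  t_idx <- 0:(n_dec - 1L)
  fair <- stats::runif(n) < p_fair
  if (study_variant %in% c("S12", "S3")) {
    k <- ifelse(fair, cfg$decay_rates_s12[["fair"]], cfg$decay_rates_s12[["unfair"]])
  } else {
    kf <- cfg$decay_rates_s4_fair; ku <- cfg$decay_rates_s4_unfair
    k <- ifelse(fair, kf[sample.int(length(kf), n, replace = TRUE)],
                      ku[sample.int(length(ku), n, replace = TRUE)])
  }
  prop <- cfg$start_proportion * exp(outer(k, t_idx))
  if (study_variant == "S4") {
    prop[, -1] <- prop[, -1] +
      matrix(stats::rnorm(n * (n_dec - 1L), 0, cfg$s4_trajectory_noise_sd),
             nrow = n)
    prop <- pmax(prop, 0)
  }
  prop[, 1] <- sample_first_offer(study_variant, n)
  mode <- if (study_variant == "S12") "zero_replace" else "clamp"
  floor_ <- cfg$fairness_floor
  if (mode == "zero_replace") prop[prop < floor_] <- 0
  else prop[prop < floor_] <- floor_
  # credits shared per decision
  if (study_variant == "S4") {
    credits <- matrix(sample_stake_s4(n * n_dec), nrow = n)
  } else {
    blocks <- sample_credit_block(n * n_dec / cfg$credit_block_len)
    credits <- matrix(as.numeric(t(blocks)), nrow = n, byrow = TRUE)
    credits[prop == 0] <- 0
  }
  list(breaks = t_idx * cfg$decision_interval,
       fairness = prop, reward_credits = credits, decay_rate = k,
       horizon = n_dec * cfg$decision_interval,
       censor_value = (n_dec - 1L) * cfg$decision_interval)
}

#' Simulate a leaving-time distribution for an environment
#'
#' Each simulation draws a fresh partner trajectory from the environment's
#' fair:unfair mixture (3:1 high generosity, 1:3 low, 1:1 effort), builds
#' the variant's input signal (zero for the standard variant), and runs one
#' accumulation to threshold. Simulations that never cross are recorded at
#' the censoring value (the onset of the final sharing decision), matching
#' the treatment of non-leaves in the data.
#'
#' @param params A [ddm_params()].
#' @param environment_type Environment type (see [build_group()]), or a
#'   `group_spec`, whose type is used.
#' @param n_sims Number of simulated leaving times.
#' @param study_variant Task variant generating the trajectories.
#' @return data.frame with `leaving_time` and `censored`.
#' @export
simulate_lt_distribution <- function(params, environment_type, n_sims = 1000L,
                                     study_variant = "S12") {
  stopifnot(inherits(params, "ddm_params"), n_sims >= 1L)
  if (inherits(environment_type, "group_spec")) {
    study_variant <- environment_type$study_variant
    environment_type <- environment_type$environment_type
  }
  b <- .environment_signal_batch(environment_type, n_sims, study_variant)
  vals <- switch(params$variant,
    fairness = b$fairness,
    reward   = params$reward_scale * b$reward_credits,
    standard = matrix(0, nrow = n_sims, ncol = length(b$breaks)))
  res <- ddm_first_passage_batch(vals, b$breaks, b$horizon, params$threshold,
                                 params$drift_gain, params$noise_sd,
                                 params$start_bias, params$dt, FALSE)
  lt <- res$leaving_time
  lt[res$censored] <- b$censor_value
  data.frame(leaving_time = lt, censored = res$censored)
}

#' Simulate one participant's full session
#'
#' Walks the session timeline: interact with a partner until the
#' accumulator crosses threshold or all 30 decisions have been seen, then
#' travel 8 s to the next partner; a new partner is joined as long as the
#' 300 s block has time remaining. The accumulator restarts at the starting
#' bias with each partner. Censored interactions (no active leave) are
#' recorded at the onset of the final sharing decision.
#'
#' @param params_by_environment Named list of [ddm_params()], one entry per
#'   environment type present in the session.
#' @param session A [build_session()] result.
#' @param participant_id Identifier copied into the output.
#' @return data.frame with one row per interaction: participant_id,
#'   study_variant, group_index, environment_type, partner_index,
#'   decay_rate, leaving_time, censored, proportion_at_leaving,
#'   credits_earned.
#' @export
simulate_participant_session <- function(params_by_environment, session,
                                         participant_id = "p1") {
  stopifnot(inherits(session, "session_spec"))
  env_types <- unique(vapply(session$groups, `[[`, "", "environment_type"))
  missing <- setdiff(env_types, names(params_by_environment))
  if (length(missing)) {
    stop("missing parameters for environment(s): ", paste(missing, collapse = ", "))
  }
  col_g <- integer(); col_env <- character(); col_j <- integer()
  col_k <- numeric(); col_lt <- numeric(); col_cens <- logical()
  col_prop <- numeric(); col_cred <- numeric()
  for (g in seq_along(session$groups)) {
    grp <- session$groups[[g]]
    params <- params_by_environment[[grp$environment_type]]
    clock <- 0
    j <- 0L
    while (clock < grp$duration && j < length(grp$partners)) {
      j <- j + 1L
      tr <- grp$partners[[j]]
      sig <- switch(params$variant,
        fairness = fairness_signal(tr),
        reward   = reward_signal(tr, params$reward_scale),
        standard = fairness_signal(tr))  # values ignored for standard
      out <- simulate_leaving(params, sig)
      d <- tr$decisions
      censor_value <- d$onset_time[nrow(d)]
      lt <- if (out$censored) censor_value else out$leaving_time
      n <- length(col_g) + 1L
      col_g[n] <- g; col_env[n] <- grp$environment_type; col_j[n] <- j
      col_k[n] <- tr$spec$decay_rate; col_lt[n] <- lt
      col_cens[n] <- out$censored
      col_prop[n] <- .proportion_at(d, lt)
      col_cred[n] <- .credits_earned(d, lt, out$censored)
      elapsed <- if (out$censored) sig$horizon else out$leaving_time
      clock <- clock + elapsed + session$travel_delay
    }
  }
  data.frame(participant_id = participant_id,
             study_variant = session$study_variant,
             group_index = col_g, environment_type = col_env,
             partner_index = col_j, decay_rate = col_k,
             leaving_time = col_lt, censored = col_cens,
             proportion_at_leaving = col_prop, credits_earned = col_cred)
}

# proportion of the decision on screen at time lt
.proportion_at <- function(decisions, lt) {
  idx <- findInterval(lt, decisions$onset_time)
  idx <- min(max(idx, 1L), nrow(decisions))
  decisions$proportion[idx]
}

# credits from decisions fully shown before lt; censored gets all of them
.credits_earned <- function(decisions, lt, censored) {
  if (censored) return(sum(decisions$credits_shared))
  n <- nrow(decisions)
  interval <- c(diff(decisions$onset_time),
                if (n > 1L) decisions$onset_time[n] - decisions$onset_time[n - 1L]
                else task_config()$decision_interval)
  sum(decisions$credits_shared[decisions$onset_time + interval <= lt])
}
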