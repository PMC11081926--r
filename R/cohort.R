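# Truncated-normal helpers: the questionnaire scores are modelled as
# truncated normals on the instrument range whose *truncated* moments match
# the target mean/SD, so the underlying (mu, sigma) are solved numerically.

.truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  dal <- stats::dnorm(al); dbe <- stats::dnorm(be)
  m <- mu + sigma * (dal - dbe) / Z
  v <- sigma^2 * (1 + (al * dal - be * dbe) / Z - ((dal - dbe) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

.truncnorm_solve <- function(target_mean, target_sd, a, b) {
  obj <- function(par) {
    mom <- .truncnorm_moments(par[1], exp(par[2]), a, b)
    (mom[1] - target_mean)^2 + (mom[2] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), a = a, b = b)
}

# inverse-CDF sampling of the truncated normal from uniforms (copula-ready)
.truncnorm_q <- function(u, tn) {
  pa <- stats::pnorm((tn$a - tn$mu) / tn$sigma)
  pb <- stats::pnorm((tn$b - tn$mu) / tn$sigma)
  tn$mu + tn$sigma * stats::qnorm(pa + u * (pb - pa))
}

#' Cohort specification for synthetic participants
#'
#' Defines a cohort of simulated participants with heterogeneous
#' fairness-DDM parameters, an environment-dependent threshold (higher in
#' the poor environment), and depression / loneliness covariates that
#' modulate the drift gain in the low-generosity environment only. The
#' defaults are the package's standing study conditions for recovery and
#' calibration work.
#'
#' @param n_participants Cohort size.
#' @param base_params A [ddm_params()] giving the population-mean
#'   parameters.
#' @param threshold_shift_low_env Added to the threshold in the poor
#'   environment (default +2; the direction matches the higher threshold
#'   found in low-generosity environments).
#' @param between_sd Named numeric: between-subject SDs for threshold,
#'   drift_gain, noise_sd, start_bias.
#' @param covariate Which score modulates drift (`"depression"`,
#'   `"loneliness"`, `"none"`).
#' @param covariate_effect Drift-gain increase per SD of the (standardised)
#'   covariate score, applied in the low-generosity environment only.
#' @param score_cor Correlation between depression and loneliness scores
#'   (Gaussian copula).
#' @param attention_fail_rate Per-check probability of failing an attention
#'   check (scalar or length `n_participants`).
#' @param threshold_grid Optional set of threshold values sampled uniformly
#'   per participant instead of the normal draw (recovery studies generate
#'   from grid points so the fitted family contains the truth).
#' @param seed Integer seed used by [sample_cohort()].
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 20L,
                        base_params = ddm_params("fairness", threshold = 4,
                                                 drift_gain = 0.3,
                                                 noise_sd = 0.2,
                                                 start_bias = 0.4),
                        threshold_shift_low_env = 2,
                        between_sd = c(threshold = 1.5, drift_gain = 0.02,
                                       noise_sd = 0.03, start_bias = 0.05),
                        covariate = c("depression", "loneliness", "none"),
                        covariate_effect = 0.15,
                        score_cor = 0.5,
                        attention_fail_rate = 0.05,
                        threshold_grid = NULL,
                        seed = 1L) {
  covariate <- match.arg(covariate)
  stopifnot(n_participants >= 1L, inherits(base_params, "ddm_params"))
  structure(list(n_participants = as.integer(n_participants),
                 base_params = base_params,
                 threshold_shift_low_env = threshold_shift_low_env,
                 between_sd = between_sd,
                 covariate = covariate,
                 covariate_effect = covariate_effect,
                 score_cor = score_cor,
                 attention_fail_rate = attention_fail_rate,
                 threshold_grid = threshold_grid,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# parameter ranges representable on the fitting grid
.clip_params <- function(theta, drift, noise, bias) {
  list(threshold = pmin(pmax(theta, 1), 30),
       drift_gain = pmin(pmax(drift, 0.1), 1.5),
       noise_sd = pmin(pmax(noise, 0.1), 1),
       start_bias = pmin(pmax(bias, 0), 0.8))
}

#' Sample a synthetic cohort
#'
#' Draws per-participant DDM parameters (population mean plus normal
#' between-subject deviations, clipped to grid-representable ranges), adds
#' the low-environment threshold shift, draws correlated depression
#' (instrument range 0-42) and loneliness (0-6) scores as moment-matched
#' truncated normals, and applies the covariate modulation of drift gain in
#' the low-generosity environment.
#'
#' @param spec A [cohort_spec()].
#' @return List of participant profiles; each has `participant_id`,
#'   `params_by_environment`, `depression_score`, `loneliness_score`,
#'   `attention_fail_rate`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_participants
  bp <- spec$base_params
  sdv <- spec$between_sd
  theta <- if (!is.null(spec$threshold_grid)) {
    spec$threshold_grid[sample.int(length(spec$threshold_grid), n,
                                   replace = TRUE)]
  } else {
    bp$threshold + stats::rnorm(n, 0, sdv[["threshold"]])
  }
  drift <- bp$drift_gain + stats::rnorm(n, 0, sdv[["drift_gain"]])
  noise <- bp$noise_sd + stats::rnorm(n, 0, sdv[["noise_sd"]])
  bias <- bp$start_bias + stats::rnorm(n, 0, sdv[["start_bias"]])

  tn_dep <- .truncnorm_solve(6.2, 5.9, 0, 42)
  tn_lon <- .truncnorm_solve(3.4, 1.8, 0, 6)
  z1 <- stats::rnorm(n)
  z2 <- spec$score_cor * z1 + sqrt(1 - spec$score_cor^2) * stats::rnorm(n)
  dep <- .truncnorm_q(stats::pnorm(z1), tn_dep)
  lon <- .truncnorm_q(stats::pnorm(z2), tn_lon)

  score <- switch(spec$covariate, depression = dep, loneliness = lon,
                  none = rep(0, n))
  z_score <- if (spec$covariate == "none" || stats::sd(score) == 0) rep(0, n)
             else as.numeric(scale(score))

  fail <- rep_len(spec$attention_fail_rate, n)
  lapply(seq_len(n), function(i) {
    high <- .clip_params(theta[i], drift[i], noise[i], bias[i])
    low <- .clip_params(theta[i] + spec$threshold_shift_low_env,
                        drift[i] + spec$covariate_effect * z_score[i],
                        noise[i], bias[i])
    mk <- function(p) ddm_params(bp$variant, p$threshold, p$drift_gain,
                                 p$noise_sd,
                                 min(p$start_bias, p$threshold - 1e-6),
                                 dt = bp$dt, reward_scale = bp$reward_scale)
    list(participant_id = sprintf("p%03d", i),
         params_by_environment = list(high_generosity = mk(high),
                                      low_generosity = mk(low),
                                      low_effort = mk(high),
                                      high_effort = mk(low)),
         depression_score = dep[i],
         loneliness_score = lon[i],
         attention_fail_rate = fail[i])
  })
}

#' Generate full task behaviour for a cohort
#'
#' Builds a fresh session per participant and simulates their leaving
#' behaviour with their own DDM parameters; for the 17-rate variant it also
#' draws attention-check outcomes (three checked partners among the first
#' five of each group, pass/fail per the profile's fail rate).
#'
#' @param cohort Output of [sample_cohort()].
#' @param study_variant Task variant.
#' @param n_groups Groups per session (defaults to the variant's schedule;
#'   reduce for desk-scale replications).
#' @param seed Integer seed.
#' @return List with `lt` (leaving-time table, one row per interaction) and
#'   `scores` (participant_id, depression, loneliness,
#'   attention_fail_frac).
#' @export
generate_behaviour <- function(cohort, study_variant = "S12", n_groups = NULL,
                               seed = 1L) {
  stopifnot(length(cohort) >= 1L)
  set.seed(seed)
  lt <- list(); scores <- list()
  for (prof in cohort) {
    session <- build_session(study_variant, n_groups = n_groups)
    tab <- simulate_participant_session(prof$params_by_environment, session,
                                        participant_id = prof$participant_id)
    n_checks <- 0L; n_fail <- 0L
    if (study_variant == "S4") {
      # three checked partners among the first five of each group
      for (g in seq_along(session$groups)) {
        checked <- sample.int(5L, 3L)
        seen <- max(tab$partner_index[tab$group_index == g])
        n_here <- sum(checked <= seen)
        n_checks <- n_checks + n_here
        n_fail <- n_fail + stats::rbinom(1L, n_here, prof$attention_fail_rate)
      }
    }
    lt[[length(lt) + 1L]] <- tab
    scores[[length(scores) + 1L]] <- data.frame(
      participant_id = prof$participant_id,
      depression = prof$depression_score,
      loneliness = prof$loneliness_score,
      attention_fail_frac = if (n_checks > 0L) n_fail / n_checks else 0)
  }
  list(lt = do.call(rbind, lt), scores = do.call(rbind, scores))
}

#' Standing cohorts for the recovery studies
#'
#' `recovery_cohort_spec()` returns the generating cohort used in the
#' model-recovery study for a given variant: tight accumulation noise
#' (0.1), on-grid population parameters chosen so the three variants
#' produce structurally distinct leaving-time distributions (bimodal
#' partner mixture for the fairness model, reward-driven spread with
#' zero-fairness break points for the reward model, long tight unimodal
#' times for the standard model), between-subject variation in the
#' threshold only, and no environment shift (variant identity, not the
#' environment contrast, is what this study probes). The reward cohort's
#' low threshold keeps crossings ahead of the zero-fairness break points,
#' where its credit-noise-dominated spread is not mimicable by the other
#' variants under the reduced grid's noise cap.
#'
#' `parameter_recovery_spec()` returns the fairness-DDM cohort used for
#' threshold recovery: thresholds drawn from five grid values (2..18) so
#' the search family contains each truth, moderate accumulation noise
#' (0.3) so neighbouring grid points' distributions overlap enough for the
#' likelihood to order them, and a +4 (one grid step) threshold shift in
#' the poor environment.
#'
#' @param variant Generating DDM variant.
#' @param n_participants Cohort size (default 20).
#' @param seed Cohort seed (defaults fixed per variant).
#' @return A [cohort_spec()].
#' @export
recovery_cohort_spec <- function(variant = c("fairness", "reward", "standard"),
                                 n_participants = 20L, seed = NULL) {
  variant <- match.arg(variant)
  base <- switch(variant,
    fairness = ddm_params("fairness", threshold = 4, drift_gain = 0.3,
                          noise_sd = 0.1, start_bias = 0.4),
    reward   = ddm_params("reward", threshold = 6, drift_gain = 1.1,
                          noise_sd = 0.1, start_bias = 0.4),
    standard = ddm_params("standard", threshold = 14, drift_gain = 0.3,
                          noise_sd = 0.1, start_bias = 0.4))
  if (is.null(seed)) {
    seed <- switch(variant, fairness = 21L, reward = 22L, standard = 23L)
  }
  tgrid <- switch(variant, fairness = c(2, 6), reward = c(2, 6, 10),
                  standard = c(10, 14, 18))
  cohort_spec(n_participants = n_participants, base_params = base,
              threshold_shift_low_env = 0,
              between_sd = c(threshold = 0, drift_gain = 0, noise_sd = 0,
                             start_bias = 0),
              covariate_effect = 0, threshold_grid = tgrid, seed = seed)
}

#' @rdname recovery_cohort_spec
#' @export
parameter_recovery_spec <- function(n_participants = 20L, seed = 31L) {
  cohort_spec(n_participants = n_participants,
              base_params = ddm_params("fairness", threshold = 8,
                                       drift_gain = 0.5, noise_sd = 0.3,
                                       start_bias = 0.4),
              threshold_shift_low_env = 4,
              between_sd = c(threshold = 0, drift_gain = 0, noise_sd = 0,
                             start_bias = 0),
              covariate_effect = 0,
              threshold_grid = c(2, 6, 10, 14, 18), seed = seed)
}
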