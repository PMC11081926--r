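#' Two-sample Kolmogorov-Smirnov p-value
#'
#' Asymptotic two-sample KS test probability that two leaving-time samples
#' come from the same distribution: the D statistic evaluated through the
#' pooled empirical CDFs, converted to a probability with the Kolmogorov
#' series at `lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) * D`,
#' `ne = n1 n2 / (n1 + n2)` (the small-sample-corrected form used by the
#' common two-sample implementations). Ties, including heavy ties at the
#' censoring value, are handled by evaluating the CDF difference at distinct
#' pooled values only.
#'
#' @param sample_a,sample_b Non-empty numeric samples.
#' @return p-value in (0, 1].
#' @export
ks_pvalue <- function(sample_a, sample_b) {
  if (length(sample_a) < 1L || length(sample_b) < 1L) {
    stop("both samples must be non-empty")
  }
  .ks_p_sorted(sort(sample_a), sort(sample_b))
}

# two-sample KS on pre-sorted samples (hot path of the grid search)
.ks_p_sorted <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v <- c(a, b)
  D <- max(abs(findInterval(v, a) / n1 - findInterval(v, b) / n2))
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  if (lambda < 0.2) return(1)  # the series equals 1 to machine precision here
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' KS log-likelihood over conditions
#'
#' The fitting objective: the sum over conditions (social environments) of
#' the log KS p-value comparing the observed and model-simulated
#' leaving-time distributions. p-values are floored at `p_floor` before the
#' log so the objective stays finite.
#'
#' @param data_by_condition,model_by_condition Named lists of numeric
#'   samples with identical names.
#' @param p_floor Lower floor applied to each p-value (default 1e-300).
#' @return Log-likelihood (<= 0).
#' @export
ks_log_likelihood <- function(data_by_condition, model_by_condition,
                              p_floor = 1e-300) {
  kd <- names(data_by_condition); km <- names(model_by_condition)
  if (is.null(kd) || is.null(km) || !setequal(kd, km) ||
      length(kd) != length(km)) {
    stop("condition keys must match between data and model")
  }
  sum(vapply(kd, function(cond) {
    log(max(ks_pvalue(data_by_condition[[cond]], model_by_condition[[cond]]),
            p_floor))
  }, numeric(1)))
}

#' Parameter grid specification
#'
#' Defaults reproduce the full fitting grid: integer thresholds 1-30, drift
#' gain 0.1-1.5 by 0.1, noise 0.1-1 by 0.1, starting bias 0-0.8 by 0.2
#' (22,500 points). `grid_spec_reduced()` gives the desk-scale reduced grid
#' (8 x 8 x 5 x 3 = 960 points, 200 simulations per point, coarser Euler
#' step) used by the recovery studies.
#'
#' @param threshold_values,drift_gain_values,noise_sd_values,start_bias_values
#'   Grid values per parameter.
#' @param n_sims_per_point Simulated leaving times per grid point.
#' @param sim_dt Euler step used for the fitting simulations.
#' @param seed_policy `"common_random_numbers"` (same seed at every grid
#'   point, smoothing the likelihood surface and making the argmax
#'   reproducible) or `"independent"`.
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(threshold_values = 1:30,
                      drift_gain_values = seq(0.1, 1.5, by = 0.1),
                      noise_sd_values = seq(0.1, 1, by = 0.1),
                      start_bias_values = seq(0, 0.8, by = 0.2),
                      n_sims_per_point = 1000L,
                      sim_dt = 0.001,
                      seed_policy = c("common_random_numbers", "independent")) {
  seed_policy <- match.arg(seed_policy)
  structure(list(threshold_values = threshold_values,
                 drift_gain_values = drift_gain_values,
                 noise_sd_values = noise_sd_values,
                 start_bias_values = start_bias_values,
                 n_sims_per_point = as.integer(n_sims_per_point),
                 sim_dt = sim_dt, seed_policy = seed_policy),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @export
grid_spec_reduced <- function(n_sims_per_point = 200L, sim_dt = 0.02) {
  grid_spec(threshold_values = seq(2, 30, by = 4),
            drift_gain_values = seq(0.1, 1.5, by = 0.2),
            noise_sd_values = seq(0.1, 0.5, by = 0.1),
            start_bias_values = c(0, 0.4, 0.8),
            n_sims_per_point = n_sims_per_point, sim_dt = sim_dt)
}

#' Grid points as a data frame
#'
#' Lexicographic order (threshold, drift gain, noise, bias ascending); ties
#' in the likelihood are broken by this order.
#'
#' @param grid A [grid_spec()].
#' @return data.frame with columns threshold, drift_gain, noise_sd,
#'   start_bias.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  g <- expand.grid(start_bias = grid$start_bias_values,
                   noise_sd = grid$noise_sd_values,
                   drift_gain = grid$drift_gain_values,
                   threshold = grid$threshold_values)
  g[, c("threshold", "drift_gain", "noise_sd", "start_bias")]
}

#' Simulate model leaving-time samples over a grid
#'
#' The model's LT distribution at a grid point depends only on the variant,
#' the environment and the point itself, never on the participant, so the
#' fitter simulates each point once and scores every participant against
#' the cached sample. Under the common-random-numbers policy the RNG is
#' reseeded identically at every point, so all points see the same partner
#' trajectories.
#'
#' @param variant DDM variant.
#' @param grid A [grid_spec()].
#' @param environment_type Environment whose partner mixture generates the
#'   input signals.
#' @param seed Integer seed.
#' @param study_variant Task variant for the trajectories.
#' @return List of numeric LT samples, one per row of [grid_points()],
#'   censored values recorded at the censoring value.
#' @export
simulate_grid_lt <- function(variant, grid, environment_type, seed,
                             study_variant = "S12") {
  stopifnot(inherits(grid, "grid_spec"))
  pts <- grid_points(grid)
  if (grid$seed_policy == "common_random_numbers") {
    # identical seed at every point => identical partner trajectories; build
    # the signal batch once and reseed only the accumulator noise per point
    set.seed(seed)
    b <- .environment_signal_batch(environment_type, grid$n_sims_per_point,
                                   study_variant)
    vals <- switch(variant,
      fairness = b$fairness,
      reward   = 0.01 * b$reward_credits,
      standard = matrix(0, nrow = grid$n_sims_per_point,
                        ncol = length(b$breaks)))
    lapply(seq_len(nrow(pts)), function(i) {
      set.seed(seed)
      res <- ddm_first_passage_batch(vals, b$breaks, b$horizon,
                                     pts$threshold[i], pts$drift_gain[i],
                                     pts$noise_sd[i], pts$start_bias[i],
                                     grid$sim_dt, FALSE)
      lt <- res$leaving_time
      lt[res$censored] <- b$censor_value
      sort(lt)
    })
  } else {
    lapply(seq_len(nrow(pts)), function(i) {
      set.seed((seed + i) %% .Machine$integer.max)
      p <- ddm_params(variant, threshold = pts$threshold[i],
                      drift_gain = pts$drift_gain[i],
                      noise_sd = pts$noise_sd[i],
                      start_bias = pts$start_bias[i], dt = grid$sim_dt)
      sort(simulate_lt_distribution(p, environment_type,
                               n_sims = grid$n_sims_per_point,
                               study_variant = study_variant)$leaving_time)
    })
  }
}

#' Grid-search maximum-likelihood fit for one participant and environment
#'
#' Scores every grid point's cached model LT sample against the
#' participant's observed LTs in that environment with the KS log-likelihood
#' and returns the argmax (first point in lexicographic grid order on ties).
#' Participants with fewer than two observations are flagged unfittable
#' rather than raising an error.
#'
#' @param lt Observed leaving times (censored values already substituted).
#' @param grid A [grid_spec()].
#' @param grid_lt Cached model samples from [simulate_grid_lt()] for the
#'   same grid/environment/variant.
#' @return One-row data.frame: threshold, drift_gain, noise_sd, start_bias,
#'   ll, n_obs, fittable.
#' @export
grid_search_fit <- function(lt, grid, grid_lt) {
  pts <- grid_points(grid)
  stopifnot(length(grid_lt) == nrow(pts))
  n_obs <- length(lt)
  if (n_obs < 2L) {
    out <- pts[1, ]
    out[1, ] <- NA_real_
    out$ll <- NA_real_; out$n_obs <- n_obs; out$fittable <- FALSE
    rownames(out) <- NULL
    return(out)
  }
  lt_sorted <- sort(lt)
  ll <- vapply(grid_lt, function(m) {
    log(max(.ks_p_sorted(lt_sorted, sort(m)), 1e-300))
  }, numeric(1))
  best <- which.max(ll)  # first index on ties = lexicographic order
  out <- pts[best, ]
  out$ll <- ll[best]; out$n_obs <- n_obs; out$fittable <- TRUE
  rownames(out) <- NULL
  out
}

#' Bayesian Information Criterion
#'
#' @param log_likelihood Log-likelihood (<= 0 for the KS likelihood).
#' @param n_observations Number of observations (>= 1).
#' @param n_parameters Number of free parameters (4 per environment:
#'   threshold, drift gain, noise, bias).
#' @return BIC value `n_parameters * log(n_observations) - 2 * log_likelihood`.
#' @export
bic <- function(log_likelihood, n_observations, n_parameters = 4L) {
  stopifnot(n_observations >= 1L)
  n_parameters * log(n_observations) - 2 * log_likelihood
}

#' Fit one DDM variant to every participant in a leaving-time table
#'
#' Runs the per-environment grid search for each participant, sharing the
#' per-grid-point model simulations across participants (an exact
#' refactoring of participant-by-participant grid search under common
#' random numbers). Summed BIC per participant adds the two environments'
#' BICs with four parameters each.
#'
#' @param data Leaving-time table (as from
#'   [simulate_participant_session()] / [generate_behaviour()]): columns
#'   participant_id, environment_type, leaving_time.
#' @param variant DDM variant to fit.
#' @param grid A [grid_spec()].
#' @param seed Integer seed for the model simulations.
#' @param grid_cache Optional precomputed cache: named list
#'   (environment type -> [simulate_grid_lt()] output).
#' @param n_rescore Simulations used to re-estimate the log-likelihood at
#'   the selected grid point with a fresh sample (default 1000, the
#'   post-fit simulation count). Maximising a noisy simulated likelihood
#'   makes the achieved maximum optimistic; re-scoring the argmax on an
#'   independent simulation removes that selection optimism before the BIC
#'   is computed. Set to 0 to keep the raw grid-search maximum.
#' @return data.frame, one row per participant x environment, with the best
#'   grid point, ll (re-scored), ll_search (grid-search maximum), n_obs,
#'   bic, variant.
#' @export
fit_cohort_variant <- function(data, variant, grid, seed, grid_cache = NULL,
                               n_rescore = 1000L) {
  envs <- sort(unique(data$environment_type))
  sv <- if (!is.null(data$study_variant)) data$study_variant[1] else "S12"
  if (is.null(grid_cache)) {
    grid_cache <- lapply(stats::setNames(envs, envs), function(e) {
      simulate_grid_lt(variant, grid, e, seed, study_variant = sv)
    })
  }
  rescore_cache <- new.env(parent = emptyenv())
  ids <- unique(data$participant_id)
  rows <- list()
  for (id in ids) {
    for (e in envs) {
      lt <- data$leaving_time[data$participant_id == id &
                              data$environment_type == e]
      fit <- grid_search_fit(lt, grid, grid_cache[[e]])
      fit$participant_id <- id
      fit$environment_type <- e
      fit$variant <- variant
      fit$ll_search <- fit$ll
      if (fit$fittable && n_rescore > 0L) {
        key <- paste(e, fit$threshold, fit$drift_gain, fit$noise_sd,
                     fit$start_bias, sep = "_")
        if (is.null(rescore_cache[[key]])) {
          set.seed((seed + 104729L) %% .Machine$integer.max)
          p <- ddm_params(variant, fit$threshold, fit$drift_gain,
                          fit$noise_sd, fit$start_bias, dt = grid$sim_dt)
          rescore_cache[[key]] <- sort(simulate_lt_distribution(
            p, e, n_sims = n_rescore, study_variant = sv)$leaving_time)
        }
        fit$ll <- log(max(.ks_p_sorted(sort(lt), rescore_cache[[key]]),
                          1e-300))
      }
      fit$bic <- if (fit$fittable) bic(fit$ll, fit$n_obs) else NA_real_
      rows[[length(rows) + 1L]] <- fit
    }
  }
  do.call(rbind, rows)
}

#' Summed BIC per participant and variant
#'
#' @param fits Output of [fit_cohort_variant()] (possibly row-bound over
#'   variants).
#' @return data.frame: participant_id, variant, summed_bic, summed_ll.
#' @export
summed_bic <- function(fits) {
  agg <- stats::aggregate(cbind(bic, ll) ~ participant_id + variant,
                          data = fits, FUN = sum)
  names(agg)[names(agg) == "bic"] <- "summed_bic"
  names(agg)[names(agg) == "ll"] <- "summed_ll"
  agg
}

#' Compare fitted model variants
#'
#' Per-variant summed BIC over participants, per-participant winning
#' variant (lowest summed BIC) and winner proportions.
#'
#' @param fits Row-bound [fit_cohort_variant()] outputs covering every
#'   variant for every participant.
#' @param variants The variant set that must be present for every
#'   participant.
#' @return List with `variant_bic` (named total BIC), `winners`
#'   (data.frame participant_id, winner), and `winner_proportions`.
#' @export
compare_models <- function(fits,
                           variants = c("fairness", "reward", "standard")) {
  per <- summed_bic(fits)
  ids <- unique(per$participant_id)
  missing <- setdiff(variants, unique(per$variant))
  if (length(missing)) {
    stop("missing variant fit(s): ", paste(missing, collapse = ", "))
  }
  complete <- all(table(per$participant_id, per$variant) == 1L)
  if (!complete) stop("every participant needs a fit for every variant")
  variant_bic <- vapply(variants, function(v) {
    sum(per$summed_bic[per$variant == v])
  }, numeric(1))
  winners <- do.call(rbind, lapply(ids, function(id) {
    sub <- per[per$participant_id == id, ]
    data.frame(participant_id = id,
               winner = sub$variant[which.min(sub$summed_bic)])
  }))
  props <- vapply(variants, function(v) mean(winners$winner == v), numeric(1))
  list(variant_bic = variant_bic, winners = winners,
       winner_proportions = props)
}

#' Predicted vs observed mean leaving times
#'
#' Regenerates each participant's model LT distribution at the best-fit
#' parameters and correlates per-participant mean simulated LT with mean
#' observed LT (Spearman), per environment.
#'
#' @param fits Output of [fit_cohort_variant()] for one variant.
#' @param data The fitted leaving-time table.
#' @param n_sims Simulations per participant-environment (default 1000).
#' @param seed Integer seed.
#' @param sim_dt Euler step for the post-fit simulations.
#' @return data.frame: environment_type, spearman_rho, n_participants.
#' @export
predicted_vs_observed <- function(fits, data, n_sims = 1000L, seed = 1L,
                                  sim_dt = 0.02) {
  envs <- sort(unique(fits$environment_type))
  sv <- if (!is.null(data$study_variant)) data$study_variant[1] else "S12"
  set.seed(seed)
  out <- lapply(envs, function(e) {
    sub <- fits[fits$environment_type == e & fits$fittable, ]
    if (nrow(sub) < 3L) stop("need at least 3 fitted participants")
    pred <- vapply(seq_len(nrow(sub)), function(i) {
      p <- ddm_params(sub$variant[i], sub$threshold[i], sub$drift_gain[i],
                      sub$noise_sd[i], sub$start_bias[i], dt = sim_dt)
      mean(simulate_lt_distribution(p, e, n_sims, study_variant = sv)$leaving_time)
    }, numeric(1))
    obs <- vapply(sub$participant_id, function(id) {
      mean(data$leaving_time[data$participant_id == id &
                             data$environment_type == e])
    }, numeric(1))
    data.frame(environment_type = e,
               spearman_rho = stats::cor(pred, obs, method = "spearman"),
               n_participants = nrow(sub))
  })
  do.call(rbind, out)
}

#' Threshold contrast between environments
#'
#' Per-participant fitted-threshold difference (poor minus rich
#' environment) with a paired t-test; the poor (low-generosity /
#' high-effort) environment is expected to need a higher threshold.
#'
#' @param fits [fit_cohort_variant()] output for the fairness variant with
#'   both environments fitted per participant.
#' @param low_env,high_env Environment labels for the poor and rich
#'   environments.
#' @return List with `differences` (per participant), `mean_difference`,
#'   and `test` (paired t-test, or NULL for a single participant).
#' @export
threshold_environment_contrast <- function(fits,
                                           low_env = "low_generosity",
                                           high_env = "high_generosity") {
  wide <- merge(
    fits[fits$environment_type == low_env,
         c("participant_id", "threshold")],
    fits[fits$environment_type == high_env,
         c("participant_id", "threshold")],
    by = "participant_id", suffixes = c("_low", "_high"))
  d <- wide$threshold_low - wide$threshold_high
  test <- if (length(d) > 1L && stats::sd(d) > 0) {
    stats::t.test(d)
  } else NULL
  list(differences = stats::setNames(d, wide$participant_id),
       mean_difference = mean(d), test = test)
}
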