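#' Censoring rule for non-leaves
#'
#' When no active leave occurred, the leaving time is defined as the onset
#' of the final sharing decision (101.5 s on the 3.5 s / 30-decision
#' schedule). Idempotent: already-censored rows are left at the censoring
#' value; active leaves are untouched.
#'
#' @param records Leaving-time table with `leaving_time` and `censored`
#'   columns.
#' @param censor_value Onset of the final sharing decision (default
#'   29 * 3.5 s).
#' @return The table with censored rows' leaving times substituted.
#' @export
censor_nonleaves <- function(records, censor_value = 29 * 3.5) {
  stopifnot(all(c("leaving_time", "censored") %in% names(records)))
  records$leaving_time[records$censored] <- censor_value
  records
}

#' Participant-level exclusions
#'
#' Two-rate variants: participants must have at least as many active
#' (non-censored) leaves as there are environments (two). 17-rate variant:
#' participants failing more than 25% of attention checks are excluded
#' (strictly more; exactly 25% is retained). Comprehension failures, when a
#' `comprehension_fail` column is present in `scores`, are also excluded.
#'
#' @param table Leaving-time table.
#' @param study_variant `"S12"`, `"S3"` or `"S4"`.
#' @param scores For `"S4"`, the scores table carrying
#'   `attention_fail_frac`.
#' @return List with `table` (retained rows) and `report` (data.frame
#'   participant_id, reason).
#' @export
apply_exclusions <- function(table, study_variant, scores = NULL) {
  .check_variant(study_variant)
  excluded <- data.frame(participant_id = character(), reason = character())
  if (study_variant %in% c("S12", "S3")) {
    n_env <- length(unique(table$environment_type))
    active <- stats::aggregate(list(n_active = !table$censored),
                               by = list(participant_id = table$participant_id),
                               FUN = sum)
    bad <- active$participant_id[active$n_active < n_env]
    if (length(bad)) {
      excluded <- rbind(excluded,
                        data.frame(participant_id = bad,
                                   reason = "too_few_active_decisions"))
    }
  } else {
    if (is.null(scores) || is.null(scores$attention_fail_frac)) {
      stop("S4 exclusions need a scores table with `attention_fail_frac`")
    }
    bad <- scores$participant_id[scores$attention_fail_frac > 0.25]
    if (length(bad)) {
      excluded <- rbind(excluded,
                        data.frame(participant_id = bad,
                                   reason = "attention_fail"))
    }
  }
  if (!is.null(scores) && !is.null(scores$comprehension_fail)) {
    bad <- scores$participant_id[scores$comprehension_fail]
    bad <- setdiff(bad, excluded$participant_id)
    if (length(bad)) {
      excluded <- rbind(excluded,
                        data.frame(participant_id = bad,
                                   reason = "comprehension"))
    }
  }
  keep <- !table$participant_id %in% excluded$participant_id
  list(table = table[keep, , drop = FALSE], report = excluded)
}

#' Within-participant, within-condition outlier trimming
#'
#' Removes interactions whose leaving time lies more than 2.5 standard
#' deviations from the mean of their participant x partner x environment
#' cell; cells with fewer than two rows (or zero variance) are untouched.
#' Idempotent on re-application when nothing new is trimmed.
#'
#' @param table Leaving-time table with a `partner` condition column (see
#'   [prepare_trial_table()]).
#' @param sd_limit Trim limit in SD units (default 2.5).
#' @return List with `table` (retained rows) and `n_trimmed`.
#' @export
trim_outliers <- function(table, sd_limit = 2.5) {
  cond <- interaction(table$participant_id, table$partner,
                      table$environment_type, drop = TRUE)
  keep <- rep(TRUE, nrow(table))
  for (cell in levels(cond)) {
    idx <- which(cond == cell)
    if (length(idx) < 2L) next
    lt <- table$leaving_time[idx]
    s <- stats::sd(lt)
    if (is.na(s) || s == 0) next
    keep[idx] <- abs(lt - mean(lt)) <= sd_limit * s
  }
  list(table = table[keep, , drop = FALSE], n_trimmed = sum(!keep))
}

#' Derived outcomes from trajectories
#'
#' Adds (or recomputes) the fairness at the time of leaving — the
#' proportion of the sharing decision on screen at the leaving time — and
#' the credits earned in the interaction (credits of decisions fully shown
#' before leaving; censored interactions earn all 30 decisions' credits).
#'
#' @param table Leaving-time table whose rows map to partners in `session`.
#' @param session The [build_session()] object that generated the rows.
#' @return The table with `proportion_at_leaving` and `credits_earned`
#'   columns filled.
#' @export
derive_outcomes <- function(table, session) {
  stopifnot(inherits(session, "session_spec"))
  for (i in seq_len(nrow(table))) {
    d <- session$groups[[table$group_index[i]]]$partners[[table$partner_index[i]]]$decisions
    table$proportion_at_leaving[i] <- .proportion_at(d, table$leaving_time[i])
    table$credits_earned[i] <- .credits_earned(d, table$leaving_time[i],
                                               table$censored[i])
  }
  table
}

#' Prepare the trial table for mixed-effects analysis
#'
#' Joins scores, codes the partner condition (categorical fair/unfair for
#' the two-rate variants; z-scored decay rate for the 17-rate variant) and
#' effect-codes the design: with `coding = "half"` the two levels score
#' -0.5/+0.5 so each main-effect coefficient equals the level difference
#' averaged over the other factor; `"unit"` uses -1/+1 (coefficients are
#' half-differences). Environment is coded rich (-) vs poor (+): high
#' generosity / low effort are the rich, high-opportunity-cost-of-staying
#' environments.
#'
#' @param lt Leaving-time table.
#' @param scores Optional scores table to join (adds z-scored depression
#'   and loneliness).
#' @param coding `"half"` or `"unit"`.
#' @return The table with `partner`, `partner_code`, `env_code` (and
#'   z-scored covariates when scores are given).
#' @export
prepare_trial_table <- function(lt, scores = NULL, coding = c("half", "unit")) {
  coding <- match.arg(coding)
  unit <- if (coding == "half") 0.5 else 1
  sv <- lt$study_variant[1]
  if (sv %in% c("S12", "S3")) {
    lt$partner <- ifelse(lt$decay_rate == task_config()$decay_rates_s12[["fair"]],
                         "fair", "unfair")
    lt$partner_code <- ifelse(lt$partner == "fair", -unit, unit)
  } else {
    lt$partner <- as.numeric(scale(lt$decay_rate))
    lt$partner_code <- lt$partner
  }
  rich <- lt$environment_type %in% c("high_generosity", "low_effort")
  lt$env_code <- ifelse(rich, -unit, unit)
  if (!is.null(scores)) {
    lt <- merge(lt, scores, by = "participant_id", sort = FALSE)
    lt$depression_z <- as.numeric(scale(lt$depression))
    lt$loneliness_z <- as.numeric(scale(lt$loneliness))
  }
  lt
}

#' Mixed-effects model of leaving times
#'
#' Fits `outcome ~ partner_code * env_code + (1 + partner_code + env_code |
#' participant_id)` (plus a z-scored covariate and its interactions for the
#' depression / loneliness models), with sum-to-zero coded predictors, and
#' reports coefficients with Wald 95% CIs, Type II Wald chi-square tests,
#' and the model BIC. If the random-slopes model fails to converge the fit
#' falls back to a random intercept only, and the fallback is recorded.
#'
#' @param table Output of [prepare_trial_table()].
#' @param outcome Outcome column (default `"leaving_time"`).
#' @param covariate `"none"`, `"depression"` or `"loneliness"`.
#' @param reml Fit by REML (default FALSE so BICs are comparable across
#'   fixed-effect structures).
#' @return List of class `lmm_fit`: `model`, `coefficients` (term, beta,
#'   se, ci_lo, ci_hi), `wald` (term, chisq, df, p), `bic`,
#'   `random_structure` (`"slopes"` or `"intercept_only"`).
#' @export
fit_lmm <- function(table, outcome = "leaving_time",
                    covariate = c("none", "depression", "loneliness"),
                    reml = FALSE) {
  covariate <- match.arg(covariate)
  if (length(unique(table$environment_type)) < 2L) {
    stop("both environment levels must be present")
  }
  if (length(unique(table$participant_id)) < 2L) {
    stop("at least two participants are required")
  }
  cov_term <- switch(covariate, none = NULL, depression = "depression_z",
                     loneliness = "loneliness_z")
  fixed <- if (is.null(cov_term)) "partner_code * env_code"
           else paste("partner_code * env_code *", cov_term)
  f_slopes <- stats::as.formula(paste(
    outcome, "~", fixed, "+ (1 + partner_code + env_code | participant_id)"))
  f_int <- stats::as.formula(paste(
    outcome, "~", fixed, "+ (1 | participant_id)"))
  fit_one <- function(f) {
    suppressMessages(withCallingHandlers(
      lme4::lmer(f, data = table, REML = reml,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
      warning = function(w) invokeRestart("muffleWarning")))
  }
  # singular fits (a variance component estimated at zero) are retained;
  # only genuine convergence failures trigger the intercept-only fallback
  model <- NULL; structure_used <- "slopes"
  model <- tryCatch(fit_one(f_slopes), error = function(e) NULL)
  ok <- !is.null(model) &&
    length(unlist(model@optinfo$conv$lme4$messages)) == 0L
  if (!ok) {
    model <- fit_one(f_int)
    structure_used <- "intercept_only"
  }
  est <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  co <- data.frame(term = names(est), beta = unname(est), se = unname(se),
                   ci_lo = unname(est - 1.96 * se),
                   ci_hi = unname(est + 1.96 * se))
  an <- suppressMessages(car::Anova(model, type = "II"))
  wald <- data.frame(term = rownames(an), chisq = an$Chisq, df = an$Df,
                     p = an[["Pr(>Chisq)"]])
  structure(list(model = model, coefficients = co, wald = wald,
                 bic = stats::BIC(model),
                 random_structure = structure_used),
            class = "lmm_fit")
}

#' Simple effects (environment contrasts within partner levels)
#'
#' Environment contrasts at each partner level for the categorical design,
#' or at the moderator's mean plus / minus one SD for continuous partner or
#' covariate moderators (the plotting convention for the three-way
#' interaction).
#'
#' @param fit An [fit_lmm()] result.
#' @param partner_at Partner codes at which to evaluate (defaults to the
#'   two coded levels, or plus / minus 1 SD for the continuous predictor).
#' @param covariate_at Optional covariate z-values at which to condition
#'   (e.g. `c(-1, 1)`).
#' @return data.frame of environment contrasts (poor minus rich) with
#'   estimates, SEs and p-values.
#' @export
simple_effects <- function(fit, partner_at = NULL, covariate_at = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  model <- fit$model
  dat <- model@frame
  unit <- max(abs(dat$env_code))
  if (is.null(partner_at)) {
    pc <- sort(unique(dat$partner_code))
    partner_at <- if (length(pc) == 2L) pc else c(-1, 1) * stats::sd(dat$partner_code)
  }
  at <- list(partner_code = partner_at, env_code = c(-unit, unit))
  cov_name <- intersect(c("depression_z", "loneliness_z"), names(dat))
  if (!is.null(covariate_at) && length(cov_name)) {
    at[[cov_name[1]]] <- covariate_at
  }
  by <- "partner_code"
  if (!is.null(covariate_at) && length(cov_name)) by <- c(by, cov_name[1])
  emm <- emmeans::emmeans(model, stats::as.formula(paste(
    "~ env_code |", paste(by, collapse = "+"))), at = at,
    lmer.df = "asymptotic")
  out <- as.data.frame(emmeans::contrast(emm, method = "revpairwise"))
  out
}

#' Covariate model comparison by BIC
#'
#' Fits the depression-only, loneliness-only and joint covariate models
#' (maximum likelihood) and tabulates their BICs, supporting the
#' model-selection step that keeps the covariates in separate models.
#'
#' @param table Output of [prepare_trial_table()] with both scores joined.
#' @param outcome Outcome column.
#' @return data.frame: model, bic, ordered as fitted.
#' @export
compare_covariate_models <- function(table, outcome = "leaving_time") {
  stopifnot(all(c("depression_z", "loneliness_z") %in% names(table)))
  fits <- list(
    depression = fit_lmm(table, outcome, covariate = "depression"),
    loneliness = fit_lmm(table, outcome, covariate = "loneliness"))
  f_joint <- stats::as.formula(paste(
    outcome, "~ partner_code * env_code * depression_z +",
    "partner_code * env_code * loneliness_z +",
    "(1 + partner_code + env_code | participant_id)"))
  ctl <- lme4::lmerControl(calc.derivs = FALSE,
                           check.conv.singular = "ignore")
  joint <- tryCatch(
    suppressMessages(withCallingHandlers(
      lme4::lmer(f_joint, data = table, REML = FALSE, control = ctl),
      warning = function(w) invokeRestart("muffleWarning"))),
    error = function(e) NULL)
  if (is.null(joint)) {
    joint <- suppressMessages(withCallingHandlers(
      lme4::lmer(stats::as.formula(paste(
        outcome, "~ partner_code * env_code * depression_z +",
        "partner_code * env_code * loneliness_z + (1 | participant_id)")),
        data = table, REML = FALSE, control = ctl),
      warning = function(w) invokeRestart("muffleWarning")))
  }
  data.frame(model = c("depression", "loneliness", "joint"),
             bic = c(fits$depression$bic, fits$loneliness$bic,
                     stats::BIC(joint)))
}
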