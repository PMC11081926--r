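# Heavy shared computations for the recovery studies, memoised so the
# model-recovery and parameter-recovery tests reuse one set of grid caches.

.recovery_memo <- new.env(parent = emptyenv())

recovery_grid <- function() grid_spec_reduced()

recovery_caches <- function() {
  if (is.null(.recovery_memo$caches)) {
    g <- recovery_grid()
    envs <- c("high_generosity", "low_generosity")
    .recovery_memo$caches <- lapply(
      stats::setNames(c("fairness", "reward", "standard"),
                      c("fairness", "reward", "standard")),
      function(v) lapply(stats::setNames(envs, envs), function(e) {
        simulate_grid_lt(v, g, e, seed = 42)
      }))
  }
  .recovery_memo$caches
}

# model recovery: three 20-subject cohorts, one per generating variant,
# each fit with all three variants; returns summed BICs and winner counts
model_recovery_results <- function() {
  if (is.null(.recovery_memo$model)) {
    g <- recovery_grid()
    caches <- recovery_caches()
    variants <- c("fairness", "reward", "standard")
    conf <- bics <- matrix(0, 3, 3, dimnames = list(gen = variants,
                                                    fit = variants))
    for (gv in variants) {
      coh <- sample_cohort(recovery_cohort_spec(gv))
      beh <- generate_behaviour(coh, "S12", n_groups = 16,
                                seed = 100 + match(gv, variants))
      fits <- do.call(rbind, lapply(variants, function(fv) {
        fit_cohort_variant(beh$lt, fv, g, seed = 42,
                           grid_cache = caches[[fv]])
      }))
      cmp <- compare_models(fits)
      bics[gv, ] <- cmp$variant_bic[variants]
      conf[gv, ] <- vapply(variants,
                           function(v) sum(cmp$winners$winner == v), 0)
    }
    .recovery_memo$model <- list(bics = bics, confusion = conf)
  }
  .recovery_memo$model
}

# parameter recovery: 20-subject fairness cohort on the 17-rate task (the
# variant the models were fit to), grid-valued thresholds, +4 shift
parameter_recovery_results <- function() {
  if (is.null(.recovery_memo$param)) {
    g <- recovery_grid()
    envs <- c("high_generosity", "low_generosity")
    caches_s4 <- lapply(stats::setNames(envs, envs), function(e) {
      simulate_grid_lt("fairness", g, e, seed = 42, study_variant = "S4")
    })
    coh <- sample_cohort(parameter_recovery_spec())
    beh <- generate_behaviour(coh, "S4", n_groups = 16, seed = 131)
    fits <- fit_cohort_variant(beh$lt, "fairness", g, seed = 42,
                               grid_cache = caches_s4)
    true_hi <- vapply(coh, function(p)
      p$params_by_environment$high_generosity$threshold, 0)
    true_lo <- vapply(coh, function(p)
      p$params_by_environment$low_generosity$threshold, 0)
    rec_hi <- fits$threshold[fits$environment_type == "high_generosity"]
    rec_lo <- fits$threshold[fits$environment_type == "low_generosity"]
    .recovery_memo$param <- list(
      spearman = stats::cor(c(true_hi, true_lo), c(rec_hi, rec_lo),
                            method = "spearman"),
      contrast = threshold_environment_contrast(fits))
  }
  .recovery_memo$param
}
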