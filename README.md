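# socialforage

When do people decide to leave a social interaction? `socialforage`
treats that question as a patch-leaving problem: a participant receives
repeated shares of money pots from a virtual partner whose fairness — the
proportion of the pot shared — decays exponentially over time, and can
leave at any moment to travel (8 s) to a new partner. Social environments
differ in opportunity cost: the mixture of fair and unfair partners
("generosity"), or the physical effort required to travel. The package is
for computational cognitive scientists who want to simulate this task,
model leaving times with evidence-accumulation models, and validate the
full analysis pipeline against synthetic ground truth.

## What is inside

* **Task generator** — partner trajectories `p_t = s·e^(k·t)` (s = 0.5,
  variant-specific decay rates, floors and first-offer noise),
  reward-neutral stakes (six-decision credit blocks summing to 500, or
  N(400, 30) credits), windowed 3:1 / 1:3 / 1:1 group compositions,
  300 s blocks, full session schedules, for three task variants
  (`"S12"`, `"S3"` with effort environments, `"S4"` with 17 decay rates
  and trajectory noise).
* **Leaving-time models** — a drift-diffusion accumulator
  `dEA = (k_gain − X(t))dt + η`, clamped at zero, starting at a bias ε,
  leaving when EA exceeds a threshold θ. `X(t)` is the partner's current
  fairness (Fairness-DDM), scaled reward `a·R(t)` with a = 0.01
  (Reward-DDM), or zero (Standard-DDM). Compiled (Rcpp) Euler–Maruyama
  core plus an analytic noiseless first-passage oracle.
* **Fitting** — per-participant, per-environment maximum likelihood over a
  parameter grid (θ ∈ 1..30, drift 0.1..1.5, σ 0.1..1, ε 0..0.8 in the
  full grid), where the likelihood is the summed log p-value of two-sample
  Kolmogorov–Smirnov comparisons between observed and simulated
  leaving-time distributions; BIC model comparison, model/parameter
  recovery studies, predicted-vs-observed correlations.
* **Synthetic cohorts** — heterogeneous DDM agents with an
  environment-dependent threshold, correlated depression (DASS-21) and
  loneliness (DGLS) scores as moment-matched truncated normals, attention
  checks, and planted covariate effects.
* **Statistics stage** — censoring, exclusion and 2.5 SD trimming rules;
  effect-coded linear mixed models
  (`LT ~ partner * environment + (1 + partner + environment | ID)`) with
  Type II Wald chi-square tests, covariate models, BIC comparisons and
  simple effects via `emmeans`.

## Worked example

```r
library(socialforage)
set.seed(42)

# one unfair partner in the two-rate task
partner <- build_partner(partner_spec(-0.2, "S12"))
head(partner$decisions[, c("trial_index", "onset_time", "proportion",
                           "stake", "credits_shared")], 5)
#>   trial_index onset_time proportion    stake credits_shared
#> 1           0        0.0  0.5207403 203.5564            106
#> 2           1        3.5  0.4093654 217.4097             89
#> 3           2        7.0  0.3351600 259.5775             87
#> 4           3       10.5  0.2744058 397.2219            109
#> 5           4       14.0  0.2246645 222.5541             50

# a fairness-DDM agent watching this partner
params <- ddm_params("fairness", threshold = 4, drift_gain = 0.3,
                     noise_sd = 0.2, start_bias = 0.4)
simulate_leaving(params, fairness_signal(partner))
#> $leaving_time
#> [1] 29.469
#> $censored
#> [1] FALSE
```

The agent leaves this unfair partner after ~29 s, once the integrated
shortfall of fairness (`drift_gain − F(t)`) crosses the threshold. At
identical parameters the generous environment *holds* agents longer,
because its partners' fairness suppresses the drift for longer:

```r
set.seed(42)
mean(simulate_lt_distribution(params, "high_generosity", 1000)$leaving_time)
#> [1] 43.1
mean(simulate_lt_distribution(params, "low_generosity", 1000)$leaving_time)
#> [1] 38.4
```

The leave-sooner-in-rich-environments effect emerges through the higher
decision threshold agents carry in poor environments. A synthetic cohort
with that +2 threshold shift planted, analysed by the package's
mixed-model stage:

```r
spec <- cohort_spec(n_participants = 8, seed = 1)
beh <- generate_behaviour(sample_cohort(spec), "S12", n_groups = 4, seed = 2)
fit <- fit_lmm(prepare_trial_table(censor_nonleaves(beh$lt)))
fit$coefficients
#>                    term   beta   se   ci_lo ci_hi
#> 1           (Intercept)  47.02 3.32  40.514 53.53
#> 2          partner_code -10.56 1.42 -13.334 -7.78
#> 3              env_code  13.59 6.82   0.227 26.96
#> 4 partner_code:env_code  -1.64 1.85  -5.270  1.99
fit$wald
#>                    term  chisq df        p
#> 1          partner_code 55.136  1 1.12e-13
#> 2              env_code  3.953  1 4.68e-02
#> 3 partner_code:env_code  0.784  1 3.76e-01
```

The intercept is the grand mean leaving time (effect coding); the
negative `partner_code` coefficient says agents leave unfair partners
~10.6 s sooner, and the positive `env_code` coefficient says they stay
~13.6 s longer in the poor (low-generosity) environment — both planted
effects, recovered with Type II Wald tests alongside.

## Analysis workflow

The `analysis/` scripts run the pipeline end to end and write their
tables under `results/`:

1. `01_simulate_task.R` — generate and log sessions for all variants.
2. `02_fit_models.R` — fit the three DDMs to a synthetic cohort by KS
   likelihood grid search; compare by summed BIC.
3. `03_recovery.R` — threshold recovery and the environment threshold
   contrast.
4. `04_behavioural_stats.R` — exclusions, trimming, mixed models,
   covariate comparisons, simple effects.

The methods vignette (`vignettes/leaving-social-interactions.Rmd`)
documents the models, the numerical and design choices, and what the
synthetic validation does and does not establish.

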