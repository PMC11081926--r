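---
title: "Modelling decisions to leave social interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling decisions to leave social interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialforage)
```

## The problem

When do people walk away from a social interaction? `socialforage` treats
this as a patch-leaving problem from behavioural ecology: a participant is
"foraging" for fair treatment, each virtual partner is a patch whose value
(the proportion of a money pot the partner shares) decays over time, and
the opportunity cost of staying is set by the social environment — how
generous the other available partners are, or how much effort it takes to
travel to one. Opportunity-cost accounts predict leaving sooner when the
environment is rich, even at a direct monetary cost.

The package implements the full computational pipeline around that idea:

1. a generator for the virtual dictator-game task (partners, groups,
   sessions) in three variants;
2. three evidence-accumulation models of the leaving decision;
3. maximum-likelihood grid-search fitting of those models to leaving-time
   distributions via a Kolmogorov–Smirnov likelihood, with BIC model
   comparison and recovery studies;
4. a synthetic-cohort generator that stands in for human participants,
   with planted effects and depression/loneliness covariates;
5. the mixed-effects statistics stage (effect coding, Type II Wald tests,
   simple effects).

Because the cohorts are synthetic, every downstream statistic can be
validated against known ground truth; that validation is what the test
suite and `scripts/acceptance.R` run.

## The task generator

A partner's sharing proportion on trial $t$ (0-based) is
$p_t = s\,e^{kt}$ with starting value $s = 0.5$ and a per-trial decay rate
$k \le 0$. The first offer is replaced by a uniform draw close to an equal
split. Two-rate variants (`"S12"`, `"S3"`) use $k \in \{-0.125, -0.2\}$
("fair" / "unfair"); the 17-rate variant (`"S4"`) draws $k$ from nine fair
and eight unfair values and adds $N(0, 0.015)$ noise to every decision.
Proportions below $0.05$ are replaced by zero (`"S12"`) or clamped at
$0.05$ (`"S3"`, `"S4"`).

Offered credits are reward-neutral by construction: in the two-rate
variants every six consecutive decisions carry credits in $[50, 200]$
summing to exactly 500, so no partner or environment is economically
preferable; the 17-rate variant draws credits from $N(400, 30)$. Stakes are
`credits / proportion`. Decisions arrive every 3.5 s (the 17-rate variant
jitters a 2.5 s inter-stimulus interval after a 1 s display, keeping the
3.5 s mean). Groups last 300 s, travel between partners costs 8 s, and
every non-overlapping window of four partners holds fair:unfair 3:1 (high
generosity), 1:3 (low), or 2:2 (effort variant). We read the "every set of
four consecutive partners" rule as non-overlapping windows: a sliding
window would pin the unfair partner to a fixed periodic position, which
contradicts random ordering within the window.

```{r task}
set.seed(1)
p <- build_partner(partner_spec(-0.2, "S12"))
head(p$decisions, 4)
```

## The evidence-accumulation models

Evidence to leave accumulates as

$$\mathrm{d}EA = (k_{\text{gain}} - X(t))\,\mathrm{d}t + \eta, \qquad
EA(0) = \varepsilon, \qquad EA(t) \ge 0,$$

and the agent leaves when $EA$ exceeds a threshold $\theta$. The input
$X(t)$ is piecewise-constant over the partner's decision stream and defines
the three variants: the current fairness $F(t)$ (fairness model), scaled
reward $a R(t)$ with $a = 0.01$ normalising credits into the range of $F$
(reward model), or zero (standard model, blind to the task). Four free
parameters per environment: $\theta$, the drift gain, the noise SD
$\sigma$, and the starting bias $\varepsilon$.

Numerical choices:

* **Euler step.** The simulator integrates at `dt = 0.001` s by default.
  Grid fitting at desk scale uses `dt = 0.02` s; the noiseless
  first-passage time changes by at most one step under refinement (a tested
  invariant), and the stochastic distributions at the two steps are
  indistinguishable at the sample sizes involved.
* **Noise discretisation.** A literal per-step $N(0, \sigma)$ at
  `dt = 0.001` would integrate to a standard deviation of roughly
  $245\sigma$ over a minute, which no threshold in the grid could contain.
  The default is therefore standard Euler–Maruyama scaling (per-step SD
  $\sigma\sqrt{dt}$); `noise_scaling = "literal"` preserves the verbatim
  per-step reading for comparison.
* **Non-negativity** is enforced by clamping at zero after each step
  (truncation rather than reflection), and the crossing test `EA >`
  $\theta$ is applied after clamping.
* **Censoring.** Simulated non-leaves are recorded at the onset of the
  final sharing decision (101.5 s on the 3.5 s grid), the same value
  substituted for participants who never leave, keeping data and model
  distributions commensurable.
* **Signal start.** $F(t)$ before the first decision equals the first
  offer (visible at connection), and the accumulator restarts at
  $\varepsilon$ with each new partner.

At equal parameters, a generous environment (more slowly-decaying
partners) *lengthens* stays, because fairness input suppresses the drift
for longer. The observed leave-sooner-in-rich-environments effect is
carried by the fitted threshold difference between environments, not by
the partner mixture itself.

```{r ddm}
prm <- ddm_params("fairness", threshold = 4, drift_gain = 0.3,
                  noise_sd = 0.2, start_bias = 0.4)
sig <- fairness_signal(p)
simulate_leaving(prm, sig)
deterministic_leaving(prm, sig)  # noiseless analytic oracle
```

## Fitting: KS likelihood, grid search, BIC

For each participant and social environment the log-likelihood of a
parameter set is the log $p$-value of a two-sample Kolmogorov–Smirnov
comparison between the observed leaving times and a simulated sample,
summed over the two environments. `ks_pvalue()` implements the asymptotic
two-sample form (Kolmogorov series with the small-sample $\lambda$
correction); $p$-values are floored at $10^{-300}$ before the log. The
full search grid is $\theta \in \{1..30\}$, drift gain $0.1..1.5$ by
$0.1$, $\sigma \in 0.1..1$ by $0.1$, $\varepsilon \in 0..0.8$ by $0.2$
(22,500 points, 1000 simulations per point). The desk-scale reduced grid
(`grid_spec_reduced()`) is $8 \times 8 \times 5 \times 3 = 960$ points at
200 simulations per point, with $\sigma \le 0.5$ (see *Identifiability*).

Implementation decisions that matter:

* **Common random numbers.** Every grid point is simulated from the same
  seed, so all points see identical partner trajectories; this smooths the
  likelihood surface and makes the argmax reproducible. Because the model
  distribution at a grid point does not depend on the participant, each
  point is simulated once per variant and environment and scored against
  every participant.
* **Selection de-biasing.** Maximising a *simulated* likelihood over 960
  points makes the achieved maximum optimistic, which systematically
  favours more flexible model families. The BIC therefore uses the
  log-likelihood re-scored at the selected point on a fresh
  1000-simulation sample (the raw maximum is kept as `ll_search`). Without
  this, the fairness model — which can approximate any unimodal
  leaving-time distribution in its high-drift regime — spuriously beats
  the standard model on standard-generated data.
* **BIC bookkeeping.** $n$ is the number of (possibly censored) leaving
  times in the environment, four parameters per environment, summed over
  environments; ties in the argmax break lexicographically
  ($\theta$, drift, $\sigma$, $\varepsilon$ ascending).
* **Pooling.** Within an environment, leaving times are pooled across
  fair and unfair partners; the condition index in the likelihood is the
  environment only.

### Identifiability

The leaving-time distribution constrains the parameters only jointly:
high-$\theta$/high-drift/high-$\sigma$ points generate distributions whose
large-sample KS distance from low-parameter points is ~0.07, far below
what per-subject sample sizes can resolve. Two consequences are baked into
the recovery-study design. First, the reduced grid restricts
$\sigma \le 0.5$, cutting off the mimicry ridge. Second, recovery cohorts
use tight accumulation noise ($\sigma = 0.1$), on-grid generating
parameters, and extended 16-group sessions (the study's own online variant
added blocks precisely to support model fitting), because the KS test's
effective $n$ saturates at the per-subject observation count.

## Synthetic cohorts

`cohort_spec()` defines the standing study conditions: fairness-DDM agents
with population means $\theta = 4$, drift gain $0.3$, $\sigma = 0.2$,
$\varepsilon = 0.4$, normal between-subject variation (SDs 1.5, 0.02,
0.03, 0.05), a $+2$ threshold shift in the poor environment (the direction
the fitted thresholds show; the magnitude is a design choice), and
depression (DASS-21, range 0–42, mean 6.2, SD 5.9) and loneliness (DGLS,
range 0–6, mean 3.4, SD 1.8) scores drawn as moment-matched truncated
normals joined by a Gaussian copula (correlation 0.5; the instruments
correlate but no joint distribution is reported). A drift gain of 0.3 —
below the 0.5 first offer — makes the net drift negative early in every
interaction, so leaving is genuinely driven by the fairness decay; it
reproduces behavioural effect sizes of the order seen in the human data
(partner effect ≈ −11 s, environment effect ≈ +9 s on the half-coded
scale).

The covariate mechanism is one of several consistent with the reported
three-way interaction and is clearly a modelling choice: the score raises
the drift gain by $0.15$ per SD in the low-generosity environment only.
Raising the drift there compresses the fairness-decay slope, so the
planted three-way coefficient (decay × environment × score) is negative
under the package's coding. Which DDM parameter actually mediates the
human effect is not identified by the data the package emulates.

Attention checks follow the online variant's scheme (three of the first
five partners per group), with a per-profile failure probability; failure
fractions feed the exclusion rule.

## The statistics stage

Data preparation follows the study's rules in order: censored leaving
times are set to the final-decision onset; participants are excluded if
they made fewer active leaves than there are environments (two-rate
variants) or failed strictly more than 25% of attention checks (17-rate
variant); then leaving times beyond 2.5 SD of their participant × partner
× environment cell mean are trimmed. The ordering (exclusions, then
trimming, after censor substitution) is implicit in the source procedure
and fixed here.

The mixed model is
`LT ~ partner * environment + (1 + partner + environment | participant)`
with sum-to-zero coding. The default `"half"` coding scores levels
±0.5 so each main-effect coefficient equals the level difference averaged
over the other factor and the intercept is the grand mean; `"unit"`
(±1) halves the coefficients and is selectable because the original
contrast scaling cannot be determined. Partner is categorical
(fair/unfair) in the two-rate variants and the z-scored decay rate in the
17-rate variant. Fixed effects are tested with Type II Wald chi-square
tests; the interaction is excluded from the random structure, and
singular fits (a variance component at zero, routine in synthetic data
with small planted slopes) are retained — only genuine convergence
failures fall back to a random intercept, with the fallback recorded.
Covariate models add z-scored depression or loneliness with all
interactions; the joint model exists for the BIC comparison that favours
keeping them separate. Simple effects evaluate environment contrasts
within partner levels, or at ±1 SD of continuous moderators — the
plotting convention for the three-way interaction.

## Validation: what the tests do and do not show

The acceptance suite checks, at fixed seeds: exact generator contracts
(credit-block sums, composition windows, floors, bounds, moments); the
stochastic simulator against the analytic noiseless oracle over 100 random
signals; model recovery (summed BIC picks the generating variant for three
20-subject cohorts and the subject-level confusion matrix is diagonally
dominant); threshold recovery (Spearman ≥ 0.7 against planted values,
positive recovered environment shift); calibration of the environment
term's Type-I error on zero-effect cohorts ([0.01, 0.10] at nominal 0.05
over 100 replications) and sign recovery of planted partner, environment
and three-way effects (≥90/90/80% over 20 replications); and the exact
filtering rules. Problem sizes (20-subject cohorts, 960-point grids, 200
simulations per point, 16-group recovery sessions, 30-subject stats
replications with 4-group sessions) are the package's desk-scale choices.

The generator emulates the stimulus-side statistics of the task and a
specific generative account of behaviour. It does not emulate real
participants' non-stationarity (fatigue, learning), non-DDM strategies
(counting trials, leaving on the first zero offer), item-level
questionnaire structure, or the unknown true covariate mechanism. Passing
tests therefore show the pipeline is correct and well-calibrated — that
planted truths are recovered — not that the fairness-DDM is the true model
of human leaving decisions.

## Known limitations

* The KS likelihood uses the asymptotic $p$-value (as the original
  MATLAB-based procedure did); with ~20–50 observations per cell it is a
  coarse objective, and parameter recovery beyond the threshold ordering
  is weak — expected, given the identifiability ridge above.
* Model simulations draw partner trajectories from the environment's
  mixture rather than replaying each participant's experienced partners;
  the alternative is noted but not implemented, since the mixture is
  participant-independent and keeps the grid cache shared.
* The effort variant's behavioural consequence (effort as opportunity
  cost) enters only through environment-specific parameters; no effort
  cost is built into the accumulator itself.
* Effort requirement fractions follow the procedure section (20% / 90% of
  each participant's maximum); a conflicting 80% figure elsewhere in the
  source material was not used.
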