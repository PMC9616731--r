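---
title: "From maze to meadow: methods behind the foragecog pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From maze to meadow: methods behind the foragecog pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foragecog)
```

## The scientific problem

`foragecog` implements a lab-to-field analysis for bumblebee cognition: bees
are first assayed for short-term spatial memory in a radial arm maze (RAM),
then released to forage in the wild while RFID readers and a nest-entrance
balance record every trip. The question the pipeline addresses is whether
maze performance — a proxy for the seconds-to-minutes memory used to avoid
revisiting depleted flowers within a patch — predicts real-world foraging
efficiency, and whether that relationship changes across the season as
floral resources wax and wane.

The pipeline has five stages, each usable on its own:

1. **Maze scoring** (`score_bouts()`, `ram_scores()`): win-shift error
   counting and per-bee RAM scores.
2. **Movement-rule validation** (`ram_validation()`): Monte-Carlo nulls
   built from per-bee transition matrices.
3. **Trip processing** (`pair_events_to_trips()` and friends): RFID/scale
   event logs to per-trip nectar and pollen efficiency.
4. **Seasonal models** (`candidate_set()`, `fit_and_select()`): the
   information-theoretic selection protocol around mixed models.
5. **Synthetic data** (`simulate_*()`): generators that invert the model
   structure so every stage is testable without field data.

## Maze scoring

A RAM bout offers one reward per arm; optimal behaviour never revisits an
arm within a bout. `score_bout()` counts every visit to an already-visited
arm as an error, which reduces to the identity *errors = visits − distinct
arms*. Two conventions needed a decision:

* **Immediate re-landings count as errors.** The reward platform is
  replaced after every landing, so a re-landing is a revisit to a depleted
  location. A `count_immediate_repeats = FALSE` switch supports sensitivity
  analysis.
* **Early-terminated bouts are scored as-is.** In the live assay the nest
  shutter is sometimes opened before all arms are visited; such bouts score
  by the same rule and enter the test-bout mean unweighted. Nothing is
  imputed, and the package does not exclude them — a documented choice, as
  the assay description leaves it open.

The per-bee RAM score is the mean error count over the final test bouts
(3 of 12 in the main design, 10 of 20 in the eight-arm validation design,
both available through `ram_design()`). Downstream models use
`log(score + 1)`; the natural logarithm is used throughout.

## The movement-rule null

A bee can look clever in a maze by stereotypy alone — always moving to an
adjacent arm, say. The validation therefore rebuilds each bee as a
"simulant": a first-order Markov walker over its own empirical arm-to-arm
transition matrix, estimated from its test bouts with transitions never
counted across bout boundaries. Simulant cohorts preserve per-bee bout
counts and covariates but destroy within-bout memory. The observed cohort
statistic is located in the distribution of the same statistic over
simulant datasets, with the add-one percentile rule
`p = (1 + #{null ≤ obs}) / (N + 1)` so p is never exactly zero. A
random-matrix baseline (`random_transition_matrix()`, flat Dirichlet rows)
gives the "chance alone" comparison.

Decisions the source assay leaves open, and what this package does:

* **Bout termination for simulants** — simulate until all arms are visited
  or a visit cap of `12 × n_arms`, mirroring the real end condition (the
  bee is fed to repletion at the last fresh arm); capped bouts are flagged.
* **Start arm** — drawn from the bee's empirical first-arm distribution.
* **Statistic** — both a Poisson GLMM intercept (errors on size and age
  with a per-bee random intercept, via lme4) and the backend-free grand
  mean of per-bout errors are provided. The mean-error statistic is used in
  the package's own acceptance battery because it is orders of magnitude
  faster over thousands of replicates and, in the degenerate case checked
  by the unit tests, the GLMM intercept is simply the log of that mean.
* **Smoothing** — transition matrices default to raw frequencies
  (`pseudo_count = 0`) with a uniform fallback for unvisited rows;
  self-transitions are allowed wherever observed.

## Trip processing

Every trip is an out-read paired with the next in-read of the same tag
(greedy chronological pairing). Duplicate reads within a 5 s debounce
window collapse; weigh events attach to trip ends by nearest-time match
within 120 s (both configurable — the hardware description does not fix
them). The load arithmetic is: total pollen = twice the one-corbicula
mass; nectar = weight-in − weight-out − pollen. Negative nectar loads are
retained (bees can leave heavier than they return). Trips under 7 minutes
are excluded as likely orientation or waste flights; of the remainder,
trips with less than 3 mg of pollen are nectar trips and above it pollen
trips. A load of exactly 3 mg — undefined in the source convention — goes
to the pollen class by default (`boundary = "nectar"` flips it).
Efficiency is load per minute; foraging experience is days since the bee's
first recorded trip; weeks are ISO-8601. Survival is days from release to
last RFID read, with bees still active at colony euthanasia
administratively censored.

## Seasonal models and the selection protocol

**ORQ normalization.** Nectar efficiency is heteroscedastic, so models fit
it on an ordered-quantile scale: `z = Φ⁻¹(rank(x)/(n+1))` with average
ranks for ties, monotone linear interpolation for new data and linear tail
extrapolation, and an exact inverse on training data. The `r/(n+1)` offset
and tie rule are stated package conventions (rank-based inverse-normal
transforms differ between implementations).

**Weather.** Daily temperature, humidity and wind reduce to their first
principal component (sign fixed so the temperature loading is positive);
because weather tracks the season, the composite is residualized on an
ISO-week penalized-spline smooth (GCV; `mgcv`), so fitted "weather"
effects are those beyond the seasonal trend. With fewer than 8 distinct
weeks a cubic polynomial replaces the smooth. Note that penalized-spline
residuals are not exactly orthogonal to fitted values (OLS residuals are);
the tests assert near-orthogonality for the smooth and exact orthogonality
for the polynomial fallback.

**Candidate sets.** Every analysis compares exactly four models: null
(intercept + random terms), full covariates, covariates + RAM score, and
covariates + RAM score × week. Responses, families and random structures
follow the per-analysis conventions: Gaussian mixed model on the ORQ scale
with correlated bee intercept/experience slopes plus a colony intercept
for nectar; Gamma log-link with linear experience and uncorrelated slopes
for pollen; Cox proportional hazards with a colony frailty for survival; a
Poisson mixed model with an observation-level random effect for lifetime
trip counts; and a tested-vs-control treatment contrast replacing RAM
score in the control comparison. Week enters uncentred, so the fitted
score-by-week interaction directly yields a sign-reversal week at
`−β_RAM / β_int` (`interaction_profile()`, delta-method CIs).

**Selection.** Models compare on AIC, switching to AICc when
`n / k_max < 40` (the "depending on sample size" rule needed a concrete
threshold; at the study's n ≈ 1200 and k ≤ 15 the two are
indistinguishable). The lowest criterion wins; candidates within 2 of the
winner count as comparable, and the simplest of them (fewest parameters)
is selected. Models that fail to fit are excluded with a warning. For
penalized Cox frailty fits the parameter count is the effective degrees of
freedom reported by `survival`, falling back to the coefficient count when
the frailty variance collapses.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
tested; they are frozen defaults, not tuning knobs.

**Maze agents.** An agent holds a sliding window of the last `m` distinct
arms visited and chooses uniformly among arms outside the window; with
probability `lapse_rate`, or when the window is empty, it falls back to a
movement-bias matrix (default: uniform over the other arms). `m = 0` is
the memoryless Markov walker — on the four-arm maze its absorbing-chain
expectation is exactly 2.5 errors per completed bout — and `m = n − 1`
is a perfect win-shift forager. The window is a count of distinct arms,
not a time decay: the simplest mechanism consistent with a
seconds-to-minutes store. Note that with the default no-self bias, `m = 0`
and `m = 1` are behaviourally identical (both avoid only the current arm);
ordering tests that need every memory increment to matter use a
self-allowed bias.

**Field season.** The trip generator inverts the nectar analysis model:
latent efficiency = seasonal baseline (a cosine declining from a spring
peak of ~3.4 to a late-summer trough of ~1.0 mg/min) + RAM and RAM × week
effects + size, age, year, quadratic experience and weather effects +
correlated bee intercept/slope, colony, and residual noise. Defaults
emulate the study layout: 25 colonies over two years released two weeks
apart from ISO week 14, nine tested bees per colony with ~60% becoming
foragers, eight weigh days per colony, and trip counts calibrated so a
default season yields roughly 1200 analysable nectar trips by ~135 bees.
Durations are log-normal with ~4% of trips under the 7-minute filter, and
~28% of trips carry pollen, so both filters are exercised. Observed
efficiency passes through a monotone cubic warp
(`y = η + 0.001·η³`) so the ORQ step is non-trivial; the warp is kept
moderate so the linear mixed model remains the correct analysis to first
order. Weigh masses are reported to 0.01 mg and stored trip loads are
re-derived from those masses with exactly the parser's arithmetic, which
is what makes the RFID/scale round trip lossless.

**Effect-size calibration.** The generating interaction is
`beta_int = 0.18` latent mg/min per log-score unit per week with a
reversal at week 26, sized so the fitted interaction is comfortably above
four standard errors at the default season size — the regime the recovery
experiments are specified in. Because the analysis is on the ORQ scale,
the generating coefficient is compared on that scale as
`beta_int / sd(η)` over the analysed trips (the rank transform of an
approximately normal latent variable is its standardization); the
`truth` record of `simulate_season()` carries both values, and the
reversal week is scale-free.

**Weather generator.** Temperature follows a seasonal sinusoid with
day-to-day noise, humidity is negatively correlated with temperature, wind
is independent log-normal. The first principal component captures roughly
half the variance — enough structure for the composite and its
week-residualization to be meaningful.

**What the generators do not emulate.** Patch geometry and travel
distances, diurnal and weather-dependent activity scheduling, learning
within the maze (training bouts are statistically identical to test
bouts), senescence beyond the quadratic experience term, reader failures
and multi-day gaps, and pollen species composition. Passing tests
demonstrate that the pipeline recovers the structure it assumes, on data
that satisfy those assumptions — they do not validate the assumptions
against real bees.

## Numerical choices and problem sizes

* Monte-Carlo batteries in the test suite use: 10,000 bouts for the
  Markov-chain oracle; 20 validation experiments of 20 bees × 500 simulant
  replicates; 2000 calibration replicates against a 1999-draw null; and
  100 synthetic seasons each for the recovery and null-selection
  experiments — sizes chosen so each experiment's Monte-Carlo error is
  small relative to the property being asserted.
* Simulant streams are generated replicate-by-replicate (or batched per
  bee for the mean-error statistic) so memory stays flat at any replicate
  count.
* All stochastic entry points take explicit seeds; two runs with the same
  configuration produce byte-identical artifacts (the pipeline manifest
  records seed and config hash).
* Wald 95% intervals are reported throughout (`estimate ± 1.96·SE`).

## Known limitations

* The null-selection (type-I) behaviour of the ΔAIC-with-simplest-on-tie
  protocol on this design sits near 10% for the two RAM-containing models
  jointly — the protocol is anti-conservative relative to a single 5%
  test, which is a property of the selection rule itself, not of the
  implementation.
* The Cox frailty stage is contract-level: it fits, reports effective df
  and coefficients, and participates in selection, but no parameter
  recovery experiment is run for it.
* `model_intercept` as a validation statistic refits a GLMM per replicate
  and is slow at 10,000 replicates; the mean-error statistic is the
  practical default.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
cfg <- run_config(out_dir = "run1", seed = 1, n_bees = 10,
                  replicates = 200,
                  season = season_params(n_colonies = 6))
manifest <- run_pipeline(cfg)
names(manifest$stages)
#> [1] "simulate" "score" "validate" "trips" "analyze"
```
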