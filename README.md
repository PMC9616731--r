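# foragecog

Lab-to-field analysis of bumblebee short-term memory and foraging
efficiency.

Bumblebee workers can be assayed for short-term spatial memory in a radial
arm maze (RAM): every arm holds a single reward per foraging bout, so the
efficient strategy is win-shift — never revisit an arm within a bout. Each
revisit is an error, and a bee's **RAM score** is its mean error count over
the final test bouts (lower = better memory). After testing, bees forage
in the wild while RFID readers log every exit and entry and a nest-entrance
balance weighs them in passing. `foragecog` turns those raw records into
per-trip foraging efficiency and implements the statistical machinery for
asking whether maze memory predicts field performance, and how that
relationship moves across the foraging season.

The package provides, as separately usable stages:

- **Maze scoring** — win-shift error counting per bout
  (`errors = visits − distinct arms`) and per-bee RAM scores with the
  `log(score + 1)` transform used in models.
- **Movement-rule validation** — Monte-Carlo nulls in which each bee is
  replaced by a "simulant" moving under its own empirical arm-to-arm
  transition matrix (and a random-matrix chance baseline), with add-one
  percentile p-values: `p = (1 + #{null ≤ obs}) / (N + 1)`.
- **Trip processing** — RFID/scale event logs to trips: greedy out→in
  pairing with debounce, nectar = weight-in − weight-out − 2 × one-leg
  pollen, the 7-minute trip filter and 3-mg nectar/pollen split,
  efficiency in mg/min, survival and lifetime-effort summaries.
- **Seasonal models** — ordered-quantile (ORQ) normalization
  `z = Φ⁻¹(rank(x)/(n+1))`, a PCA weather composite residualized on a week
  smooth, the four-model candidate set {null, covariates, + RAM score,
  + RAM score × week}, ΔAIC/AICc selection with a cut-off of 2 and
  simplest-on-tie, and per-week interaction profiles with the sign-reversal
  week at `−β_RAM / β_int`.
- **Synthetic data** — generators that invert the analysis: maze agents
  with a sliding memory window of the last *m* distinct arms, a staggered
  two-year field season with a score-by-week interaction built in,
  week-correlated weather, and RFID/scale logs that round-trip losslessly
  through the trip parser.

Mixed models are fitted with `lme4`, smooths with `mgcv`, survival models
with `survival`; this package owns the scoring rules, null models,
transforms, candidate sets and selection protocol.

## Worked example

Simulate a cohort of memory-limited bees on the eight-arm validation maze,
score them, and ask whether they beat their own movement-rule nulls:

```r
library(foragecog)
set.seed(2)

coh <- simulate_cohort(n_bees = 20, design = "validation",
                       memory_capacities = 2, lapse_rate = 0.1)
head(ram_scores(coh$visits, design = "validation"), 3)
#>   bee_id ram_score ram_score_log1p n_test_bouts n_bouts
#> 1 bee001       8.6        2.261763           10      20
#> 2 bee002       7.4        2.128232           10      20
#> 3 bee003       8.9        2.292535           10      20

val <- ram_validation(coh$visits, coh$bees, design = "validation",
                      n_replicates = 500, seed = 3)
val
#> RAM validation (empirical null, 500 replicates)
#>   statistic: mean_errors
#>   observed: 8.2200
#>   null mean: 11.8515
#>   percentile p (lower tail): 0.001996
```

The memory-2 agents average ~8.2 errors per bout; simulants with the same
movement statistics but no memory average ~11.8, and the cohort sits below
all 500 null replicates (the add-one rule floors p at 1/501).

Run a full synthetic season through the trip parser and the selection
protocol:

```r
sp <- season_params()            # study-scale defaults, ~1200 nectar trips
bees <- simulate_bee_table(sp, seed = 4)
ss <- simulate_season(bees, sp, seed = 5)
logs <- simulate_rfid_scale_logs(ss$trips, duplicate_reads = TRUE)
trips <- classify_and_filter(derive_loads(
  pair_events_to_trips(logs$rfid, logs$weighs)))
dat <- build_analysis_data(efficiency_table(
  trips, bees = bees, weather_scores = ss$weather_scores))
sel <- fit_and_select(candidate_set("nectar"),
                      dat[dat$trip_type == "nectar", ])
sel
#> criterion: AIC (n = 1299, k_max = 15, n/k = 86.6)
#> covariates_ram_week    k=15   AIC=3344.21 delta=0.00
#> covariates             k=13   AIC=3403.74 delta=59.53
#> covariates_ram         k=14   AIC=3403.92 delta=59.71
#> null                   k=6    AIC=3493.18 delta=148.97
#> selected: covariates_ram_week (simplest within delta <= 2)

interaction_profile(sel$best_fit, weeks = 14:38)$reversal_week
#> [1] 27.15693
```

The selection protocol identifies the generating score-by-week interaction
by a wide AIC margin, and the estimated sign-reversal week (where the
score–efficiency slope flips from negative to positive) lands near the
generating value of week 26: bees with worse maze scores forage relatively
better late in the season, and vice versa in spring.

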