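# drinkdom

Social dominance hierarchies in dynamic dairy-cow groups, inferred from the
visit logs of electronic water and feed bins.

Modern barns record every bin visit automatically (cow ID, bin, start/end
time, intake). Because a bin holds one cow at a time, a very short gap
between one cow leaving and another entering the same bin marks an
**agonistic replacement** — a directed dominance interaction in which the
arriver displaced the occupant. `drinkdom` turns weeks of such logs into a
quantitative picture of the social hierarchy and of how dominance shapes
*when*, *how often*, and *how much* cows drink, including under heat stress.
It is aimed at precision-livestock and applied-ethology researchers working
with Insentec/RIC-style bin systems.

## What it computes

- **Replacement detection** (`detect_replacements`): adjacent-visit pairs at
  one bin with an exit-to-entry gap in `[0, threshold_s]` (default 26 s) and
  differing animals; actor = arriver (winner), reactor = displaced (loser).
- **Elo hierarchy** (`elo_run`, `elo_summary`): sequential Elo over a
  dynamic roster. After each event the winner gains `k·(1 − p)` points,
  where `p = 1/(1 + 10^(−(r_w − r_l)/scale))` is the expected win
  probability — upsets move ratings most. Dominance score = **summed
  winning probability** `S_i = Σ_{j≠i} p(r_i, r_j) ∈ [0, n−1]`;
  **hierarchy steepness** = |OLS slope| of sorted `S` against rank,
  in `[0, 1]` (0 egalitarian, 1 maximally despotic). Uncertainty from
  order-shuffle or bootstrap resampling of the event sequence.
- **Heat-load partition** (`thi_days`): THI =
  `(1.8T + 32) − (0.55 − 0.0055·RH)(1.8T − 26)`; days are *hot* when the
  3-day trailing mean of daily max THI is ≥ 72, else *normal*.
- **Drinking metrics** (`daily_behavior`, `block_shares`): per-cow daily
  visit counts / duration / intake over resident days, and 4-h diurnal
  block percentages per period.
- **Association statistics** (`assemble_comparisons`): Spearman
  correlations (dominance vs behaviour, hierarchy vs hierarchy), Welch's
  t-test on daily replacement counts hot vs normal, Benjamini–Hochberg
  adjustment within each block-correlation family.
- **Synthetic herd** (`simulate_herd`): an agent-based generator with a
  latent dominance order, diurnal visit peaks after milking/feeding,
  turnover, hot-day contest escalation, and planted ground-truth
  displacement events — so the whole pipeline is testable end to end
  without any farm data.

## Worked example

```r
library(drinkdom)

cfg <- herd_config(n_cows = 24, n_drinkers = 3, n_feeders = 8, n_days = 21,
                   feeder_visits_per_day = 12, hot_fraction = 0.5, seed = 11)
sim <- simulate_herd(cfg)                      # visits + climate + truth
ev  <- detect_replacements(sim$visits, threshold_s = 26)
table(ev$bin_type)
#> drinker  feeder
#>     245     981

elo_summary(ev[ev$bin_type == "drinker", ], n_rep = 500, seed = 11)
#> Dominance summary: 30 animals, 245 events
#>   steepness 0.601 (resampling mean 0.577, sd 0.017, 500 x shuffle)
#>   top ranks:
#>      1. cow009  S = 24.09 +/- 1.10 (22 interactions)
#>      2. cow011  S = 23.55 +/- 1.21 (21 interactions)
#>      ...
```

245 drinker replacements over 21 days rank 30 cows (24 resident at a time;
turnover brings extras through). `cow009` is expected to beat ~24 of her 29
potential opponents; steepness 0.60 indicates a clearly graded, fairly
despotic hierarchy. Against the simulator's latent order the estimated
scores achieve Spearman ρ = 0.84 here (`truth_report`), and detection
precision/recall on planted events is exactly 1.

Reproducing a published-style Welch comparison from printed summaries
(39 ± 10.5 replacements/d over 52 hot days vs 34 ± 10.0 over 60 normal
days):

```r
welch_t(39, 10.5, 52, 34, 10.0, 60)
#> $t 2.569  $df 106.05  $p 0.0116
```

The full pipeline, simulate-mode:

```r
res <- run_analysis("out", sim = herd_config(), seed = 1)
# writes replacements.csv, thi_days.csv, dominance_*.csv, steepness.json,
# behavior_means.csv, block_shares.csv, correlations.csv, welch.csv,
# manifest.json, ground_truth.json
```

A default-scale run (48 cows, 112 d, ~160k visits) takes well under a
minute on one CPU. The same driver accepts CSV paths
(`visits=`, `climate=`, `membership=`) for real bin exports; column naming
is adapted via `visit_dialect()` / `climate_dialect()`.

## Command line

```sh
Rscript inst/cli/drinkdom.R run-all --simulate --n-cows 48 --n-days 112 --out out
Rscript inst/cli/drinkdom.R detect --visits visits.csv --replacement-threshold-s 26 --out out
Rscript inst/cli/drinkdom.R recovery-study --seed 1 --out out
```

## Package layout

`R/` implementation · `tests/testthat/` unit, property and acceptance
suites (brute-force oracles in `helper-oracles.R`) ·
`vignettes/drinkdom-methods.Rmd` model/assumption notes ·
`inst/cli/drinkdom.R` CLI · `scripts/acceptance.R` acceptance report.
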