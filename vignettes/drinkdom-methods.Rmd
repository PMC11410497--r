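---
title: "Methods: dominance at the drinker from automated visit logs"
author: "drinkdom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominance at the drinker from automated visit logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drinkdom)
```

## The problem

Electronic feed and water bins record, for every visit, which cow occupied
which bin, when, and how much she consumed. Because each bin admits one cow
at a time, a very short gap between one cow leaving and another entering the
same bin is the signature of an *agonistic replacement*: the arriving cow
displaced the occupant. Accumulated over weeks, these directed win/loss
events let us score social dominance without human observation — even in
*dynamic* groups whose membership turns over every couple of weeks, which
breaks classical matrix-based dominance methods.

`drinkdom` implements that pipeline: replacement detection, sequential Elo
scoring over a changing roster, dominance summaries (summed winning
probabilities, hierarchy steepness) with resampling uncertainty, heat-load
partitioning of days by the temperature-humidity index (THI), daily and
diurnal drinking metrics, and the association statistics connecting them.
Because no suitable public dataset of this kind exists, the package also
ships an agent-based herd simulator that emits exactly the formats the
pipeline reads, with known ground truth; every claim a test makes is checked
against that ground truth or an independent brute-force oracle.

## Replacement detection

Visits are validated first (one cow per bin at a time; the later-starting of
two overlapping rows is rejected as sensor error; a visit belongs to the
calendar date of its start). A replacement is scored when the immediately
next visit at a bin starts within `threshold_s` seconds of the previous exit
and the animals differ; the arriver is the actor (winner). Only adjacent
visit pairs count and no cross-bin displacement is inferred.

The gap threshold is a property of the recording hardware and validation
literature, not of this method; it defaults to 26 s and is exposed
everywhere (`threshold_s`, `--replacement-threshold-s`). Event counts are
monotone in the threshold, which the suite checks as a property.

To compare hierarchies from unequally provisioned resources (30 feeders
generate far more events than 5 drinkers), `subsample_proportional()` draws
a feeder subsample of the drinker event count while preserving each actor's
share of events via largest-remainder apportionment — deterministic given a
seed, exact for proportional counts.

## Elo scoring and dominance summaries

Each event moves ratings by `k * (1 - p)`, where
`p = 1 / (1 + 10^(-(r_w - r_l)/scale))` is the winner's expected winning
probability beforehand: expected wins move little, upsets a lot. Defaults
are the chess-style constants (prior `r0 = 1000`, `k = 100`, `scale = 400`);
only rating *differences* matter, and the summed-winning-probability
transform below is invariant to the prior's location. Newcomers enter at the
prior mid-sequence while incumbents keep their accumulated ratings; departed
animals keep frozen ratings, so history carries across turnover.

Dominance is reported as the summed winning probability
`S_i = sum_{j != i} p(r_i, r_j)` over an opponent set — by default every
animal observed in the analysed events ("all potential opponents"), with a
co-residency-restricted option. `S_i` lies in `[0, n-1]` and totals
`n(n-1)/2`. *Steepness* is the absolute OLS slope of the descending-sorted
`S` against rank, clipped to `[0, 1]`: 0 egalitarian, 1 a maximally despotic
ladder. Sort ties break by animal id for determinism.

**Uncertainty.** Bayesian posterior machinery for Elo-based steepness exists
but drags in an MCMC toolchain. Since the quantity needed here is an SD band
on `S_i` and steepness, the package instead reruns the Elo pass over
`n_rep` replicates with the event order randomly permuted (default; Elo is
order-dependent, so this isolates sequence-ordering uncertainty) or with
events bootstrap-resampled (sampling uncertainty). These bands serve the
same role but are *not* posterior SDs, and numeric agreement with
Bayesian-method bands is not claimed. `n_rep` defaults to 1000 in
`elo_summary()`; the pipeline driver uses 300 by default to keep a
full-scale run fast — the bands change negligibly.

## THI and the hot/normal partition

`THI = (1.8*T + 32) - (0.55 - 0.0055*RH) * (1.8*T - 26)` — the NRC-style
dry-bulb form used throughout the dairy heat-stress literature (at 25 °C
and 50 % RH it gives ≈ 71.8, the conventional threshold neighbourhood).
Coefficients are configurable for other THI variants. Heat load per day is
the 3-day average of the daily *maximum* THI; we chose **trailing**
alignment (days d−2..d) — the alignment is rarely stated in field studies,
and trailing means a day's label never uses future weather. The first two
days are labelled `undefined` and excluded from period analyses, with
counts logged. A day is `hot` when the rolling value is ≥ 72, else
`normal`; the partition is exhaustive and classification is monotone in the
input.

## Drinking metrics

Daily behaviour (visit count, time at the drinker, intake) is summed per
cow-day, with explicit zero rows for resident days without visits, so
per-cow averages divide by resident days (from the membership table), not
visit days. Diurnal structure uses 4-h blocks anchored at midnight
(0000–0400 first); a visit belongs to the block containing its start time
(visits are short relative to 4 h, and not splitting keeps counts integral).
Shares are computed from period totals by default, so they sum to exactly
100 per animal/period/metric; a per-day-then-average mode is provided
because field reports rarely say which was used.

## Statistics

Spearman correlations use midranks with the t-approximation for p (target n
is ~40–90); an exact permutation p is available for n ≤ 8 and the suite
checks the approximation against it. Welch's t-test is computed from group
summary statistics so published summaries can be reproduced directly.
Benjamini–Hochberg adjustment is applied *within* each (metric × period)
family of 6 block correlations — the natural family for per-block tests —
while the three daily-metric correlations are unadjusted by default
(configurable), matching how such results are conventionally reported. All
tests are two-sided.

## The synthetic herd: what it emulates, and what it does not

The generator's stated world: 48 resident cows (held constant through
turnover of ~6 cows every ~16 d), 5 drinkers and 30 feeders, milking at
0500/1500 h and feed delivery at 0600/1500 h creating arrival peaks, ~46 %
hot days laid out as a contiguous heat block, and a latent dominance value
`d_i` per cow (uniform on [0, 1] with guaranteed spacing for the initial
cohort; entrants drawn fresh). An arriving cow targets an occupied bin with
a configured contest probability (raised by `hot_multiplier`, default 1.15,
on hot days at drinkers) and wins with probability
`plogis(beta * (d_i - d_j))`; `beta` is the despotism knob. A win truncates
the occupant's visit and plants a displacement with a gap below the
detection threshold, while benign same-bin successions are pushed beyond
it — so detector precision and recall against planted events are exactly 1
by construction, which is a *validation* device, not a realism claim.
Dominant cows visit drinkers somewhat less often but drink more per visit,
giving the signed dominance–behaviour correlations the association layer
looks for. The default drinker contest probability (0.38) is calibrated
once so the default herd yields ~36 drinker replacements/day, the magnitude
field systems report at this stocking density.

Not emulated: real gap distributions that straddle the detection threshold
(so green detector tests do not establish field precision/recall),
physiological heat responses beyond the contest-rate multiplier, feed-side
behaviour structure (feeder visits are dominance-neutral), parity/body-size
covariates of intake, and drifting group-level visit rates. Feeder event
volume is scaled to desk size (~10× the drinker volume rather than the ~20×
of a real 30-bin barn).

## Numerical and design choices

- Timestamps are fixed-offset local barn time at 1-s resolution; no DST.
- Degenerate inputs error loudly: < 2 animals for `S`/steepness, unsorted
  event times, negative thresholds, humidity outside [0, 100], empty
  climate logs, `n_target` above the event count.
- Zero-variance vectors give `rho = NA` with a warning rather than a value.
- Exact quotas in largest-remainder apportionment are protected against
  floating-point round-down with a 1e-9 guard.
- Every random stage takes `seed` (the pipeline derives per-stage seeds as
  `seed + offset`), so stages are independently reproducible.

## Limitations

Order-shuffle SDs understate total uncertainty relative to a full posterior
treatment when event counts are small. Steepness from summed winning
probabilities depends on the opponent-set choice in groups with heavy
turnover; both all-observed (default) and co-resident opponent sets are
exposed. The simulator is a minimal mechanism for testing estimators — its
parameter values are stated-world conventions, not fitted to any barn.
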