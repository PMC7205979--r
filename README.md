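# compassnull

Analysis of satellite-telemetry **displacement experiments** on solitary
bird migrants: track processing, circular-statistical group comparisons,
and a **clock-and-compass resampling null model** that classifies
individual displaced birds as compensating outliers.

## The problem

When migrating birds are translocated far off their normal route, two
navigation programmes predict opposite outcomes. A **clock-and-compass**
(vector-orientation) migrant holds an innate heading for an innate
duration and ends up displaced by the full longitude gap; a
**goal-navigating** migrant determines its position from unfamiliar
territory and converges back on the species route. Deciding between the
two from sparse, duty-cycled Argos tracks of a few birds per cohort needs
careful small-sample machinery:

* **Circular statistics.** For bearings $\theta_i$ with mean resultant
  length $r$ and mean direction $\mu$, the Rayleigh statistic
  $Z = nr^2$ tests directedness, and the two-sample Watson–Williams test
  $$F = g\,(N-2)\,\frac{R_1 + R_2 - R}{N - R_1 - R_2}, \qquad
    g = 1 + \tfrac{3}{8\hat\kappa}$$
  compares group mean directions ($R_i = n_i r_i$, $R$ the length of the
  summed group resultants, $\hat\kappa$ estimated from the weighted mean
  resultant length). Both are provided in raw-angle and
  summary-statistic-only form, so published $(n, \mu, r)$ triples can be
  re-analysed directly.
* **Endpoint displacement.** Endpoint longitude minus release longitude
  (west negative), compared between displaced and control cohorts with a
  pooled two-sample t-test, with a longitude-as-angle Watson–Williams
  cross-check.
* **The null model.** Every observed between-fix movement longer than
  100 km is one clock-and-compass "step" (Δlon, Δlat). For each step
  count $k = 1..15$ the model sums $k$ steps resampled with replacement
  (1,000 tracks per $k$, 15,000 endpoints). A displaced bird whose
  longitudinal displacement is a two-sided empirical outlier (0.05 /
  0.001) *in the direction of compensation* is classified as
  compensating.

A synthetic-cohort generator with known per-bird strategies
(clock-and-compass, goal navigation, partial mixes) emulates the study
design — two release sites ~1,750 km apart at 55° N, 58-h Argos duty
cycle, class-dependent position noise — so the entire pipeline is
testable without any tracking-data download.

## Worked example

Re-analysing published group summaries needs only the summary-form
tests:

```r
library(compassnull)

rayleigh_test(4, 0.992)
#> Rayleigh test: n = 4, r = 0.9920, Z = 3.936, p = 0.008003

watson_williams_from_summaries(data.frame(
  n = c(4, 8), mu_deg = c(178.5, 202.7), r = c(0.992, 0.976)))
#> Watson-Williams test: F(1, 10) = 10.570, p = 0.008704

summary_ttest(-10.7, 7.1, 8, 0.0, 5.9, 4)
#> Pooled two-sample t-test: t(10) = -2.584, p = 0.02724
```

The first says four control-bird endpoint bearings with $r = 0.992$ are
far too concentrated for a uniform circle (p ≈ 0.008); the second that
the control and displaced mean directions (178.5° vs 202.7°) differ
significantly; the third that displaced endpoints lie significantly
west of control endpoints (−10.7° vs 0.0° mean longitudinal
displacement, p ≈ 0.027).

The full pipeline on a synthetic cohort (4 control young, 8 displaced
young of which 2 true goal-navigators):

```r
report <- run_all(pipeline_config(seed = 42))
report$calls[, c("bird_id", "dlon", "p", "level", "compensating")]
#> # A tibble: 8 × 5
#>   bird_id                 dlon       p level  compensating
#> 1 displaced_juvenile_01  -7.08 0.766   ns     FALSE
#> 2 displaced_juvenile_02  -6.31 0.685   ns     FALSE
#> 3 displaced_juvenile_03  -7.98 0.860   ns     FALSE
#> 4 displaced_juvenile_04  -6.84 0.741   ns     FALSE
#> 5 displaced_juvenile_05 -13.8  0.567   ns     FALSE
#> 6 displaced_juvenile_06 -15.7  0.409   ns     FALSE
#> 7 displaced_juvenile_07 -24.1  0.0525  ns     FALSE
#> 8 displaced_juvenile_08 -30.7  0.00653 p<0.05 TRUE
```

Birds 07 and 08 are the true goal-navigators
(`report$truth$strategy == "goal_navigation"`): 08 is flagged as a
compensating outlier; 07, at p = 0.053, just misses the 0.05 level in
this replicate — with n = 8 displaced birds per cohort, borderline calls
like this are exactly what the recovery tests quantify (at least one of
the two true compensators is flagged in at least 80 % of replicates,
while clock-and-compass birds are flagged at well below the 10 % bound
the suite enforces).

`plot_endpoint_cloud(report$cloud, observed = report$calls)` draws the
null cloud with its 0.05 / 0.001 longitudinal envelopes and the observed
endpoints.

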