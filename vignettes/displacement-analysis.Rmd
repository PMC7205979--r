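---
title: "Analysing displacement experiments with a clock-and-compass null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing displacement experiments with a clock-and-compass null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compassnull)
```

## The scientific problem

A displacement experiment moves migrating animals far off their normal
route and asks whether their subsequent movement corrects for the
displacement. Two competing programmes make opposite predictions:

* **Clock-and-compass (vector orientation).** The bird holds an innate
  heading for an innately controlled period. After an eastward
  displacement it simply migrates parallel to the normal route, ending
  displaced by the same longitude gap.
* **Goal navigation.** The bird can determine its position relative to
  the species route or goal area even from unfamiliar territory and heads
  back toward it; displaced birds converge on the control birds' route.

`compassnull` implements the complete analysis chain for satellite-tracked
displacement experiments of this design: two release sites roughly
1,750 km apart at about 55° N (a control/trapping site and an eastern
displacement site), juvenile and adult cohorts, intermittent Argos/GPS
sampling, and a per-bird classification of compensation against a
resampling null.

## Track processing

Raw fixes arrive as Movebank-dialect CSV. Processing is deliberately
minimal and explicit:

1. **Class-Z rejection** (`filter_quality()`). Argos class Z marks a
   failed estimate and is dropped; all other classes, including the
   unbounded A and B, are kept.
2. **Duty-cycle reduction** (`select_duty_cycle_positions()`). Solar
   tags transmit 10 h on / 48 h off, so fixes cluster in bursts every
   58 h. Within each 58-h window (anchored at the first retained fix) one
   analysis position is kept: the highest location class wins
   (GPS > 3 > 2 > 1 > 0 > A > B), and among equals the fix closest to
   12:00 UTC. Quality is the primary criterion and noon proximity only a
   tie-break, because a sharp position hours from noon localises the bird
   better than a kilometres-wide estimate at noon. "Noon" is 12:00 UTC:
   the study region spans two hours of solar time, a distinction that is
   immaterial next to the 58-h sampling grain, and UTC keeps the rule
   deterministic.
3. **Migration onset** (`detect_migration_onset()`). Released birds often
   wander near the release site before departing. Onset is the first fix
   from which `k_consecutive = 2` successive between-fix movements of at
   least 50 km all head within ±90° of south. The published account of
   this step is qualitative ("consistent directions"), so the rule is
   explicit configuration rather than a constant.
4. **Cohort inclusion** (`started_migration()`): tracked beyond 500 km
   from release or south of 50° N.

All geometry is spherical with radius 6371 km (`gc_distance()`,
`initial_bearing()`, `destination_point()`, via **geosphere** with the
flattening set to zero); at the precision of duty-cycled Argos tracking
the sub-0.5 % ellipsoidal correction is irrelevant. Distance-threshold
crossings (`crossing_event()`, at 500 and 1,000 km) use the *first
retained fix beyond the threshold*, not an interpolated crossing point —
with fixes ~2.4 days apart, interpolation would fabricate precision. The
crossing bearing is measured from the release site, so milestone bearings
and endpoint bearings share one frame. Longitudes live in (−180, 180]
throughout, and endpoint longitudinal displacement (endpoint longitude
minus release longitude, wrapped, west negative) is the main compensation
metric: near the wintering latitudes even large distances correspond to
small bearing differences, so bearings alone understate compensation.

## Circular statistics

For a sample of bearings $\theta_i$, with $\bar C$ and $\bar S$ the mean
cosine and sine, the mean resultant length is
$r = \sqrt{\bar C^2 + \bar S^2}$ and the mean direction
$\mu = \operatorname{atan2}(\bar S, \bar C)$. Dispersion is reported as
the circular standard deviation $\sqrt{-2\ln r}$ (the angular deviation
$\sqrt{2(1-r)}$ is also computed, since software differs in which one it
prints).

**Rayleigh test** (`rayleigh_test()`): $Z = n r^2$ tests uniformity. Two
closed-form small-sample approximations to the p-value are implemented:
the series expansion
$e^{-Z}\!\left[1 + \frac{2Z - Z^2}{4n} - \frac{24Z - 132Z^2 + 76Z^3 - 9Z^4}{288 n^2}\right]$
used by the standard circular-statistics packages, and the uniformly
stable form $\exp\!\big(\sqrt{1 + 4n + 4(n^2 - R^2)} - (1 + 2n)\big)$
with $R = nr$. The truncated series is the more accurate at moderate $Z$
but can leave $[0,1]$ for highly concentrated small samples (it goes
negative at e.g. $n = 8$, $r = 0.976$); the default `method = "auto"`
therefore uses the series wherever it lands in $(0, 1]$ and falls back to
the stable form in the far tail. This combination reproduces the
behaviour of the circular-statistics software used in the movement
literature across the whole input range.

**Watson–Williams test** (`watson_williams()`,
`watson_williams_from_summaries()`): the two-sample F-type test of a
common mean direction,
$$F = g\,(N-2)\,\frac{R_1 + R_2 - R}{N - R_1 - R_2},\qquad
  g = 1 + \frac{3}{8\hat\kappa},$$
where $R$ is the length of the vector sum of the group resultants and
$\hat\kappa$ is estimated from the weighted mean resultant length
$r_w = (R_1 + R_2)/N$ by Fisher's piecewise approximation
($2r + r^3 + 5r^5/6$ for $r < 0.53$; $-0.4 + 1.39r + 0.43/(1-r)$ for
$0.53 \le r < 0.85$; $1/(r^3 - 4r^2 + 3r)$ above). The published sources
for such analyses rarely name their $\hat\kappa$ estimator; any
ML-consistent choice reproduces $F$ within the precision of rounded
summary inputs, which is why the summary-only variant documents its
residual (a few percent) rather than promising exact agreement. The test
assumes high concentration; results carry a flag when $r_w < 0.75$. Only
the two-group form is provided. The summary-statistic variants matter in
practice: published work often prints only $(n, \mu, r)$ per group, and
re-analysis must run from exactly those numbers.

**Linear comparisons**: endpoint longitudinal displacement and milestone
timing use Student's pooled-variance two-sample t-test
(`summary_ttest()`), which back-solving published p-values identifies as
the form used in this literature (Welch would give visibly different
values at these sample sizes). Longitude treated as linear is justified
when the data span well under a tenth of the circle; the
longitude-as-angle Watson–Williams cross-check is attached to every
displacement comparison so the agreement is auditable per dataset. The
two-factor age × displacement screen (`two_way_screen()`) is an additive
linear-model ANOVA; with the near-balanced designs it serves, sequential
and marginal sums of squares coincide or nearly so. No multiple-testing
correction is applied — the comparison report lists every p-value so
users can apply their own.

## The clock-and-compass resampling null

The null model asks: *if displaced birds simply flew their innate
programme, where could their endpoints plausibly lie?* It is built
entirely from observed movements:

1. **Steps** (`extract_steps()`): every movement between consecutive
   retained fixes whose great-circle length strictly exceeds 100 km
   contributes one step, recorded as the (Δlon, Δlat) it traversed.
2. **Simulation** (`simulate_endpoints()`): for each total step count
   $k = 1, \dots, 15$, 1,000 synthetic tracks are formed by summing $k$
   steps drawn uniformly *with replacement*, giving 15,000 endpoints from
   the origin. Steps are drawn as joint (Δlon, Δlat) pairs by default:
   pairing preserves the directional correlation of real flights and is
   the conservative reading of resampling "longitudes/latitudes" from a
   step set. Independent per-axis resampling is available
   (`pair_axes = FALSE`) as a sensitivity variant. The summation is
   planar in coordinate space — the null this classification is defined
   against is itself rooted in a plane rather than a sphere, a known
   limitation inherited by design.
3. **Classification** (`classify_compensation()`): each displaced bird's
   release-relative endpoint longitude is placed in the null distribution
   by its two-sided empirical quantile; significance levels 0.05 and
   0.001 mark outliers, and an outlier is *compensating* only when its
   deviation lies in the direction of compensation (westward after an
   eastward displacement). By default the comparison is against the
   pooled 15,000-endpoint cloud: conditioning on a latitude band
   (`lat_band_deg`) is available but opt-in, because with ~1,000
   endpoints per step count the pooled comparison is the better-calibrated
   default, and the per-latitude structure is served separately by
   `null_contours()` for plotting envelope contours.

Seeding is single-point: one integer seed makes the whole cloud
bit-reproducible; draws for successive $k$ follow sequentially from that
one stream.

Degenerate inputs are handled explicitly: a one-step set yields the exact
lattice $k \cdot s$; an empty latitude band falls back to the pooled
cloud with a warning; contour bins holding fewer than 20 endpoints are
flagged unreliable.

## The synthetic cohort generator

`gen_cohort()` produces telemetry with known ground truth so every stage
is testable without any data download. Its defaults are fixed study
conditions, not tuning knobs:

* cohorts released at the two study sites (about 1,750 km apart at
  ~55° N), default design 4 control young plus 8 displaced young of which
  2 are goal-navigators;
* an innate heading of 195° (between the two published group mean
  directions) with von Mises concentration κ = 15, whose circular SD
  (~15°) matches the published dispersion of juvenile 500-km bearings;
* gamma step lengths (shape 2.5, scale 100 km; mean 250 km per movement)
  and 8–15 migration steps per bird;
* 0–5 days of sub-50-km pre-departure wandering, exercising onset
  detection;
* Argos observation: 58-h duty cycle, 1–3 fixes per 10-h on-window,
  location classes drawn from a mix including 2 % class Z, isotropic
  position noise with class-dependent SD (0.25/0.5/1.5/3 km for classes
  3/2/1/0, nominal 5/10/50 km for A/B/Z which have no published error
  bound, 30 m for GPS).

One generated movement step spans one duty cycle. This is a deliberate
modelling decision: the movement unit the analysis can resolve — and the
unit both `extract_steps()` and the null's step counts $k \le 15$ operate
on — is the between-fix displacement, not the single night's flight.
Generating finer-grained (e.g. daily) steps under a 58-h duty cycle would
make each observed track an aggregate of only ~4–6 extractable steps, so
a null allowed up to 15 steps would mechanically dwarf every observed
endpoint and no bird could ever be an outlier; aligning the generative
and analytical step scales keeps the generator's truth labels meaningful
for recovery tests.

Goal-navigators head for (30° N, 13° E) by default: the waypoint of the
*uncompensated control route* at the cohort's expected migration distance
(~2,900 km along 195° from the control site), not the distant wintering
grounds. A navigating bird on a track that ends mid-migration is heading
for where the species route is at its current progress; aiming at the
final goal area instead would close only part of the longitude gap within
a truncated track. Partial compensation (`strategy = "partial"`) mixes
the two pure strategies bird-day by bird-day with weight `mix_c`, which
reduces exactly to the pure strategies at 0 and 1.

What the generator does *not* emulate: wind, stopover ecology,
energetics, tag failure patterns correlated with behaviour, or
non-Gaussian Argos error tails. Passing recovery tests therefore shows
the *pipeline* is sound — that true goal-navigators of the configured
effect size are detected and vector-orientation birds are not falsely
implicated — not that any particular real bird was correctly classified.

## Problem sizes and runtime choices

The shipped tests run the null machinery at its full default size
(15,000 endpoints), calibrate the outlier test's type-I error on 2,000
null-process birds, and measure recovery over 100 seeded cohort
replicates (12 birds each); the enumeration cross-check compares
simulated endpoint frequencies with the exact $|S|^k$ distribution for
step sets of ≤3 and $k \le 3$. These sizes give Monte-Carlo standard
errors comfortably below the tolerances asserted while keeping the whole
suite under a minute on one CPU.

## Known limitations

* The null sums steps in planar (lon, lat) coordinates; at large
  latitudinal spans the longitude-degree metric changes along the track.
* The Watson–Williams test is only trustworthy for concentrated samples;
  the `low_concentration` flag should be respected, not overridden.
* Endpoints of prematurely-ended tracks underestimate full compensation;
  the classification speaks about the tracked segment only.
* `read_tracks()` consumes already-estimated positions; no Doppler
  re-processing or state-space smoothing is attempted, and none should be
  inferred.
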