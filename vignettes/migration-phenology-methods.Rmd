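---
title: "Methods: segmenting spring migration and estimating ancestry effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting spring migration and estimating ancestry effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`migphen` turns raw GPS fix tables of wintering mallards into per-track
spring-migration metrics and estimates how each metric responds to the
bird's game-farm ancestry fraction. This vignette documents the models,
rules and numerical choices, which defaults matter, and what the
package's validation does and does not establish.

## Geometry

All distances are great-circle (haversine) on a sphere of mean radius
6371.0088 km. The data source never pins down a distance metric; a
spherical earth is accurate to ~0.5% at continental scale, is exactly
reproducible, and makes brute-force test oracles trivial. Coordinates
are WGS84 decimal degrees, longitude first; timestamps are parsed as
UTC (the fix schedule of the transmitters is not standardised, so fixes
are accepted at irregular intervals and never resampled). Day-of-year
values are computed in UTC.

## Segmentation rules

All thresholds live in `segmentation_rules()` and are configurable; the
defaults encode the study design.

* **Step classes.** Steps < 0.25 km are within-wetland movement,
  0.25–50 km local-regional, ≥ 50 km migration events. Both lower
  bounds are inclusive, following the printed inequalities ("< 0.25",
  "0.25–50", "≥ 50"). `log_step_density_breaks()` estimates a
  Gaussian-kernel density (Silverman bandwidth) of log10 step lengths
  and returns its interior minima as a *diagnostic* for whether the
  modes are separated; classification always uses the fixed thresholds.
* **Departure** is the first fix whose latitude *strictly* exceeds the
  capture state's threshold (35.904°N Arkansas, 36.982°N Tennessee, the
  northernmost January positions per state). Departures dated outside
  1 Feb – 31 May of the migration year are excluded; both endpoints are
  legal departure dates, and the window is evaluated against the
  departure fix's UTC date.
* **Residency** is anchored at the earliest fix above 43°N such that
  every fix in the following 10 days stays within 25 km of the anchor —
  a "50-km-diameter" circle read as radius 25 km. The record must
  actually extend 10 days past the anchor: a track cut short by
  transmitter failure returns `no_residency` rather than a guess. The
  circle is centred on the anchor fix, not a recomputed centroid;
  anchored circles are deterministic, independent of later fixes, and
  verifiable by exhaustive enumeration.
* **Stopovers** are dwells of ≥ 24 h within 25 km of an anchor fix,
  strictly between departure and residency. The wording of the source
  rules is ambiguous between radius and diameter for the stopover
  buffer; 25 km radius was chosen for internal consistency with the
  residency buffer, and the radius is configurable. The scan is
  greedy-forward with earliest-anchor precedence: a candidate opens at
  the first unconsumed fix, extends over consecutive in-radius fixes,
  and is emitted if the elapsed first-to-last time reaches the minimum;
  otherwise the scan advances one fix. Stopover duration is elapsed
  time between the first and last member fix; tracks with no stopover
  get an imputed zero total duration.
* Whether "exceeded 43°N" must hold for every residency fix or only
  the anchor is unspecified upstream; anchor-only is implemented (the
  dwell constraint keeps all fixes within 25 km of it anyway).

Monotonicity (shrinking the residency radius can never move the anchor
earlier; raising the stopover dwell minimum can never increase the
count), idempotence, and exact agreement with brute-force anchor
enumeration on 1,000 random tracks are asserted in the test suite.

## Urban distance

Distance from the arrival fix to the nearest urban area is vector
geodesic: zero inside any polygon, else the minimum great-circle
distance to polygon boundaries densified to ≤ 1 km vertex spacing. This
replaces a 30-m raster Euclidean-distance surface from a GIS workflow:
the discretisation difference (tens of metres) is orders of magnitude
below the effect scales of interest (tens of km), and the vector version
is dependency-light and exactly testable. Polygons come from GeoJSON;
self-intersecting rings are rejected with a warning.
`synthetic_urban_areas()` provides invented demo "cities" spanning
typical breeding latitudes — it is a synthetic stand-in, not a
land-cover extract.

## The ancestry models

Eight univariate models, one per response: departure day-of-year,
arrival day-of-year, arrival latitude, stopover count, total stopover
duration, urban distance, total migration distance, migration duration.
The single predictor is the game-farm ancestry fraction standardized by
subtracting its mean and dividing by **two** standard deviations
(sample SD, n − 1), so the slope compares like a binary-predictor
coefficient; responses stay on their natural scales (the day-scale
effect sizes of interest are of order 2 days). Individual and
migration-year random intercepts absorb repeated tracks per bird and
annual conditions. Stopover count is Poisson and stopover duration
negative-binomial (both log link); the remaining six are gaussian. The
upstream description calls these "logistic" regressions while listing
gaussian/Poisson/negative-binomial response families; the family list
is followed and "logistic" treated as a misnomer.

Sampling is MCMC via JAGS with per-chain seeded Mersenne–Twister RNGs:
identical seeds give byte-identical draws. The reference layout is 4
chains × 10,000 iterations with 4,000 burn-in; tests and the acceptance
script use shorter, documented layouts. Two reparameterizations keep
Gibbs mixing healthy without changing the model: year intercepts are
hierarchically centred on the grand intercept, and individual
intercepts use parameter expansion (`u_j = ξ e_j` with a Gamma(3/2, 3/2)
mixing precision), which induces *exactly* the intended half-Student-t
prior on the individual SD while letting the sampler cross zero when
the SD is small.

Priors are weakly informative and fixed (the original analysis used
package defaults, which are not portable across samplers): intercept
and slope get Normal(0, (10 sd(y))²) for gaussian responses — scaling
by sd(y) keeps the prior effectively flat for km-scale responses whose
slopes are of order 10² — and Normal(0, 10²) under a log link; the
random-effect and residual SDs get half-Student-t(3, 0, 2.5 sd(y))
(2.5 under a log link); the negative-binomial dispersion gets
Gamma(0.01, 0.01).

Summaries per model: posterior mean β and SD, equal-tailed 90% credible
interval, probability of direction (share of draws on the dominant side
of zero, zeros split evenly), and rank-normalized split-R̂ for every
monitored parameter; any R̂ ≥ 1.1 flags the fit. Effect classes follow
the published decision rules: CrI excluding zero is a supported effect
("meaningful" when pd ≥ 95 — the value an equal-tailed 90% interval
excluding zero implies — "moderate" otherwise); CrI straddling zero
with pd < 89 is "none"; CrI straddling zero with pd ≥ 89 falls between
the two rules and is reported as "indeterminate" with both facts — the
published arrival-latitude row (CrI −0.73–0.07, pd 91.33) is exactly
this case, and the classifier deliberately refuses to resolve it.
A derived "% change per +10% ancestry" column is available as
100·β·Δz/ȳ with Δz = 0.10/(2 s_x), since no conversion formula is
stated upstream.

## The synthetic cohort generator

`simulate_cohort()` is the validation instrument: it emits GPS cohorts
with *known* coefficients. Its defaults are the study conditions — 296
birds of which 41 contribute two springs (337 tracks), ~32% Arkansas
captures, ~10% hybrids with game-farm fractions on (0.02, 0.23] (the
most admixed bird observed was 77% wild), and ancestry effects equal to
the published point estimates: +1.62 d departure, +2.02 d arrival,
−0.33° arrival latitude, −70.77 km migration distance per standardized
unit. Stopover count/duration and urban distance carry no generative
ancestry effect, matching the null findings. Standardization inside the
generator uses the same 2-SD rule as the models, so generated and
fitted coefficients share a scale and recovery tests are direct.

Remaining generator defaults are invented plausible values, chosen once
and exposed in `simulation_truth()`: departure baseline DOY 65, arrival
baseline DOY 95, arrival latitude 47°N, migration distance 1600 km,
residual SDs of 8 d / 8 d / 1.2° / 120 km, individual and year
intercept SDs of 2 d and 1 d shared by the two timing responses (a late
bird is late at both ends; latitude and distance carry independent
noise), Poisson(1.5) stopovers with 24–96 h dwells, a 2-h fix interval,
6 wintering days and 12 residency days. Nothing in the acceptance
checks depends on these choices.

Emission is laid out so segmentation recovers the latent values
*exactly* at fix resolution: the departure fix is the first flight fix
beyond the state threshold, placed at 08:00 UTC on the latent departure
day; flight legs (each ≥ 50 km) follow exact latitude waypoints with
alternating east–west offsets solved so each leg has exactly the
planned length and the path terminates exactly at the latent arrival
latitude; stopovers are placed below 42.5°N so no dwell can trigger
early residency; sub-24-h rests between legs absorb schedule slack. The
latent arrival time and stopover count are renegotiated in the rare
infeasible cases (e.g. a drawn arrival earlier than the minimum travel
time, or a zero Poisson draw with a large departure–arrival gap when
stopovers are enabled), and the *realized* values are recorded as
truth, so self-consistency is exact and the regression consumes
realized responses. `simulate_phenology()` draws the same latent
structure without emitting fixes; parameter-recovery studies use it so
that hundreds of replicate cohorts stay cheap, with the
emission/segmentation equivalence established separately.

What the generator does *not* emulate: GPS position error, duty-cycle
gaps and transmitter failure, wind and habitat effects on routes,
fall/molt migration, and any nonlinearity in the ancestry-behavior
relationship. Passing recovery tests therefore shows the pipeline is
correct and well calibrated under the assumed linear data-generating
process at the study's scale — not that field data meet those
assumptions.

## Validation sizes and numerical choices

The test suite checks, among others: haversine against closed-form arc
lengths and metric properties; segmentation against brute-force anchor
enumeration on 1,000 random tracks of ≤ 200 fixes; generator/segmenter
self-consistency on a 200-track cohort; the no-random-effects gaussian
fit against OLS within 3 Monte-Carlo SEs and the known-sigma fit
against the conjugate normal posterior; R̂ against an independent
application of the formula; and CrI coverage of β_true ∈ {0, 1.6, 2.0,
−70} over 20 replicate cohorts of ~300 tracks each at 2 chains × 2,000
kept draws (coverage ≥ 80% per setting, null false-positive rate
≤ 25%). These sizes are the package's chosen validation scale; the
reference MCMC layout remains 4 × 10,000.

Tie-breaks and degenerate inputs: duplicate timestamps keep the first
fix; a read fails if more than 10% of rows are invalid; zero steps are
dropped (with a warning) before the log-density diagnostic, which also
refuses fewer than 100 positive steps; a constant ancestry predictor is
an error; all-identical MCMC draws return R̂ = 1 with a warning rather
than NaN; random effects collapse with a warning when a grouping factor
has fewer than two levels; count responses are rounded to integers
before Poisson/negative-binomial fitting.

## Known limitations

* Ancestry enters as a point estimate per bird; assignment uncertainty
  from the upstream genomic analysis is not propagated.
* The stopover buffer's radius-vs-diameter ambiguity is resolved by
  configuration, not evidence.
* Singleton individual random effects (most birds have one track) make
  the individual SD only weakly identified; it is retained for
  structural fidelity, and the slope posterior is insensitive to it.
* Arrival latitude, distance and timing are generated (and in real
  birds, surely are) correlated; the eight univariate models ignore
  that correlation by design, as did the original analysis.
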