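# migphen

Spring migration phenology from GPS telemetry, and how domestic
("game-farm") ancestry shifts it.

Wild mallard populations in eastern North America hybridize extensively
with released captive-reared game-farm mallards. For birds tagged with
GPS-GSM transmitters on the wintering grounds, the question is whether a
bird's genomic game-farm ancestry fraction shifts its spring migration
behavior: when it departs, when and where it settles to breed, how far it
flies, and how it uses stopovers. `migphen` implements that analysis as a
reusable, fully tested pipeline for movement ecologists:

1. **Track segmentation.** Irregular GPS fix tables are split into
   wintering, migration, stopover and residency phases. Steps are
   classed as within-wetland (< 0.25 km), local-regional (0.25–50 km) or
   migration (≥ 50 km) movements; departure is the first fix whose
   latitude strictly exceeds a capture-state threshold (35.904°N for
   Arkansas, 36.982°N for Tennessee) inside the 1 Feb – 31 May window;
   residency is the earliest fix above 43°N whose following 10 days stay
   inside a 50-km-diameter circle; stopovers are ≥ 24-h dwells in a
   50-km circular buffer strictly between departure and residency.
2. **Phenology metrics.** Eight responses per track: departure and
   arrival day-of-year, arrival latitude, number of stopovers, total
   stopover duration (zero imputed when a bird never stops), distance
   from the arrival location to the nearest urban area, total migration
   distance (sum of step lengths) and migration duration.
3. **Ancestry models.** Eight univariate Bayesian regressions of each
   metric on the game-farm ancestry fraction, standardized by
   subtracting the mean and dividing by *two* standard deviations, with
   individual and migration-year random intercepts:

   y_i = α + β·x*_i + u_ind(i) + v_year(i) + ε_i,&nbsp;&nbsp; x* = (x − x̄)/(2 s_x)

   Gaussian responses use an identity link; stopover count is Poisson and
   stopover duration negative-binomial, both with a log link. Models are
   sampled by seeded MCMC (JAGS) and summarised by the posterior mean β,
   its SD, an equal-tailed 90% credible interval, the probability of
   direction (pd), and rank-normalized split-R̂ convergence diagnostics.
   Effects are classed by the CrI/pd rules (CrI excluding zero ⇒
   supported effect; CrI straddling zero with pd < 89% ⇒ no effect).
4. **Synthetic cohorts.** A track generator emits GPS cohorts with known
   ancestry effect sizes whose segmentation output matches the latent
   truth exactly at fix resolution, so the entire pipeline is validated
   by parameter recovery rather than by fixtures.

## Worked example

```r
library(migphen)

truth  <- simulation_truth(n_individuals = 40, seed = 7)
cohort <- simulate_cohort(truth)          # 46 tracks from 40 birds
seg    <- segment_cohort(cohort$tracks, cohort$ancestry,
                         urban = synthetic_urban_areas())
fit    <- fit_ancestry_model(seg$phenology, "migration_distance_km",
                             chains = 2, iter = 3000, burn_in = 1000,
                             seed = 5)
fit
#> <ancestry_fit> migration_distance_km (gaussian), n = 46 tracks
#>   beta = -63.438 (SE 31.743), 90% CrI [-114.435, -10.078], pd = 97.60%
#>   max R-hat 1.018 (converged), effect: meaningful
```

The coefficient is the change in total migration distance (km) per
2-SD increase in game-farm ancestry: here a supported shortening, with
the 90% credible interval below zero and a 97.6% probability the effect
is negative — consistent with the generator's true −70.77 km. `plot(fit)` draws the marginal effect with
its credible band; `summary(fit)` returns the table row.

The one-call pipeline runs simulate → segment → fit → report, writing
plain CSV/JSON stage artifacts plus a manifest with checksums:

```r
run <- run_pipeline(list(out_dir = "demo_run", seed = 42,
                         simulate = list(n_individuals = 30),
                         models = list(chains = 2, iter = 2000,
                                       burn_in = 500)))
writeLines(run$report)
```

Existing field data can be supplied instead of a simulated cohort via
`tracks_csv`/`ancestry_csv` config entries (Movebank-style fix CSV plus a
two-column ancestry table).

## Scope

No fall or molt migration, no behavioral-state HMMs, no GPS error
smoothing, and no ancestry estimation: ancestry fractions are consumed
as an input column (one minus the wild assignment probability from an
upstream population-genetic analysis).
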