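# sealforage

Foraging inference from Satellite Relay Data Logger (SRDL) telemetry of
deep-diving marine mammals, built around the hooded-seal style deployment:
Argos surface positions, on-board-compressed dive profiles (four at-depth
inflection points plus the two surface endpoints), 17-point CTD casts and
haul-out records. The package implements three complementary daily foraging
indexes, the track and dive preprocessing they require, environmental
covariate attachment, and additive mixed habitat models — plus a synthetic
SRDL generator with full ground truth, so every stage is testable without
access to raw telemetry.

## The three foraging indexes

**First passage time (FPT).** For a track point *p* and radius *r*, FPT(*p*,
*r*) is the time the animal needs to cross the circle of radius *r* centred
at *p*. Tracks are first resampled to equidistant 5-km steps along the
path-line (removing the fix-density bias toward slow movement), and the
area-restricted-search (ARS) scale is the radius *r** maximizing
Var[log FPT(*r*)] over 5–100 km in 1-km steps. Daily mean FPT at *r** is the
horizontal search-effort index; values within *r** of a haul-out are
excluded first.

**Depth-weighted transit-rate index.** Descent rate (first profile leg) and
ascent rate (last leg) are standardized and combined by PCA; the first axis,
oriented so both loadings are positive, scores "fast transit both ways" =
feeding at depth. Because lung air dominates buoyancy above ~100 m, each
score is multiplied by a weight w(d) on the mean transit depth d (mean of
the depth where descent ended and ascent began): w(0) = 0 rising
nonlinearly — quadratic ramp (d/100)² by default — to w(100 m and deeper)
= 1. Weighted scores are averaged per animal-day.

**Drift-rate change (body condition).** Drift dives contain a passive
segment whose vertical rate (m/s, negative = sinking) reflects buoyancy and
hence lipid stores. Candidate segments (interior profile segments spanning
>= 30% of the dive at 0.01–1.2 m/s) are scored by a random forest trained on
simulator-labelled dives; rare positive (floating) drifts need clustered
corroboration or are excluded. Per trip (kept only with >= 1 segment / 2
days), a weighted, range-constrained penalized B-spline — weights = depth
weight x classification probability, smoothing by GCV — yields daily drift
rates, whose first derivative is the daily condition-change index (positive
= fattening = foraging success).

The daily indexes are joined with daily bathymetry, sea ice, CTD-derived SST
and mean maximum dive depth into one modelling table, then regressed on
standardized covariates with penalized-spline GAMMs (animal and trip random
intercepts); all term combinations are ranked by AIC with a
fewest-parameters rule among candidates within ΔAIC < 2.

## Worked example

The `analysis/` scripts run the whole study on a simulated 6-animal, 60-day
deployment (`Rscript analysis/01_simulate.R` through `05_foraging_behavior.R`;
tables land in `results/`). Highlights of that run:

```
Common ARS scale: 35 km (true patch radius: 30 km)
Transit-rate PCA axis 1 explains 95% of the variance
Drift segments retained: 650 | trips with spline fits: 15
Daily modelling table: 203 rows
Trips summarized: 16 ( 12 complete )
Rayleigh R-bar = 0.93, p = 6.2e-09 -> directed migration
Max depth, pup vs female: U = 6515378, p = 8.6e-211
75% daily-FPT quantile: 60.99 hr (2.54 days); 51 of 203 days flagged
pup     foraging days: mean max depth 110 m, depth/bathymetry 0.14
male    foraging days: mean max depth 281 m, depth/bathymetry 0.24
```

The FPT variance maximization recovers the simulated patch scale to within
5 km; the Rayleigh test detects the southeasterly migration built into the
generator; pups dive significantly shallower than adults; and flagged
foraging days show class-specific depth-use ratios (pelagic pups vs
deeper-foraging adults).

A minimal programmatic run:

```r
library(sealforage)
res <- run_pipeline(sim_config(n_animals = 3, duration_days = 30, seed = 1))
head(res$daily)        # animal-day table: indexes + environment
res$ars$selected_radius_km
```

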