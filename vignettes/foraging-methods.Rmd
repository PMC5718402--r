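---
title: "Methods: three foraging indexes from SRDL telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three foraging indexes from SRDL telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sealforage)
```

This vignette documents the models and procedures implemented by
`sealforage`, the assumptions behind them, the tunable parameters that
matter, and the design decisions taken where the methodology left genuine
choices open. It states no empirical result beyond what the package's tests
and `scripts/acceptance.R` compute themselves.

## The data model

SRDL tags transmit (a) Argos surface positions with a location class
(LC 3, 2, 1, 0, A, B, or the invalid Z), (b) dive profiles compressed
on-board to six time–depth points — start and end at the surface plus four
at-depth inflection points — with maximum depth, duration and post-dive
surface time, (c) one 17-point CTD cast per 6-hour window, and (d) haul-out
start/end times. All timestamps are UTC and every "daily" quantity uses UTC
calendar days. Distances are great-circle (haversine) kilometres on a
sphere of radius 6371.009 km.

## Track preprocessing

**SDA filter** (`sda_filter`). LC Z fixes are dropped outright. A fix whose
implied swimming speed to *both* neighbours exceeds 2 m/s is removed (worst
offender per pass), then spike fixes — internal turning angle below 15° or
25° with both legs longer than 2.5 km or 5 km respectively — are removed,
iterating to a fixed point. Iterating to convergence is what makes the
filter idempotent, a property the tests check exactly. Endpoints are never
removed (the both-neighbour rule is undefined there).

**State-space smoothing** (`smooth_track`). A continuous-time correlated
random walk — position plus Ornstein–Uhlenbeck velocity per axis — in a
local azimuthal-equidistant projection recentred per animal. Velocity
autocorrelation β and diffusion σ are estimated per animal by maximizing the
Kalman innovations likelihood (Nelder–Mead on the log scale, bounded to
β ∈ [10⁻⁴, 100] hr⁻¹, falling back to the moment start values if the
optimizer fails). Measurement SDs per LC default to
{3: 0.25, 2: 0.5, 1: 1.5, 0: 5, A: 8, B: 15} km — plausible published
magnitudes for Argos classes; published class-accuracy studies vary widely, so
they are configuration, shared with the simulator's observation model.
Classes outside this table get the largest listed SD, and a 0.05 km
measurement floor keeps the filter well-posed when fixes coincide. Across
haul-out intervals the transition matrix pins velocity to zero and process
noise to near zero, so the track stops on the ice and a stray displaced fix
cannot move it. Gaps longer than `max_gap_hr` (48 h) split the record into
independently smoothed segments. The output grid interval defaults to 1 h;
no claim is made that these match any particular historical analysis — the
smoothing interval and CRW parameterization are deliberately exposed as
configuration because published descriptions do not state them.

**Seasons and trips** (`segment_seasons`, `segment_trips`). Records start in
the breeding period (tags are deployed at breeding). The post-breeding
season ends at the first haul-out after the molt rule date (adults: July 1;
pups, which do not molt in their first year: June 15), and the post-molting
season ends at the first haul-out after February 15. A missing qualifying
haul-out makes the boundary fall back to the record end, flagged. Adult
trips are maximal excursions beyond 250 km of the deployment centre
(complete if the animal re-enters the disc); pup trips are delimited by the
season boundaries regardless of the disc. Whether very short adult trips
should be discarded is not settled in published practice; we keep all trips
with at least two points and leave filtering to the caller.

## Dive processing

Descent rate is Δdepth/Δtime over the first profile leg; ascent rate
likewise over the last leg, sign-flipped so both are positive. A profile
whose descent leg runs upward (or has a zero-duration leg) is excluded with
a message. The mean transit depth is (d₁ + d₄)/2 — the depth where descent
ended and ascent began. Dives are geolocated by great-circle interpolation
along the smoothed track at the dive *start* time (the anchor instant is a
package choice; published usage says only that dives are located along the track). A
configurable minimum dive depth (default 10 m) reflects the usual shallow
cutoff of SRDL dive records.

## First passage time

FPT at a point is the interpolated time between the last backward entry
into, and the first forward exit from, the circle of radius *r* centred
there; points whose circle is never crossed on one side (track ends) are
missing, not censored. Tracks are resampled to 5-km equidistant steps
first. The ARS scale maximizes the FPT variance across all points of all
supplied trips over radii 5–100 km in 1-km steps.

*Design decision.* The variance is taken on **log FPT** by default. We
found — and the package's tests document — that the raw-FPT variance is
monotonically increasing in radius on directed tracks, so a raw-basis
maximization always selects the largest tested radius and can recover no
interior scale; the originating FPT-variance method log-transforms for
exactly this reason. Both curves are always computed and returned, and
`on = "raw"` is available.

FPT values within the selected scale of any haul-out position are removed
before daily averaging (their dwell reflects ice time, not search). Days
above the 75% type-7 quantile of daily FPT (strict inequality, pooled
across animals by default; per-animal pooling is the caller's choice of
input) are flagged as important foraging days.

## Transit-rate index

PCA on standardized (descent, ascent) pairs, axis 1 oriented so the descent
loading is positive (both loadings are positive whenever the rates correlate
positively, which holds on real and simulated dives). The depth weight is
w(d) = min{(d/100)², 1}: the two endpoint constraints — 0 at 0 m, 1 at
100 m and deeper — are fixed; the quadratic ramp is the
simplest smooth monotone curve through them, and both the exponent and a
fully custom curve are accepted because no single nonlinear form is
canonical. The weight multiplies the PC1 *score* (not the
raw rates before PCA — the score is "the foraging index" that the weighting
language refers to). Daily aggregation divides Σwᵢsᵢ by the dive count by
default; dividing by Σwᵢ is a documented variant since either divisor is
defensible. A day whose weights all vanish yields index 0 under
the default and NA under the weighted variant.

## Drift-rate change

Sign convention: drift rate < 0 = sinking (lean), > 0 = floating (fat);
depth is positive-down. Candidate segments are the three interior profile
segments (never the first descent or final ascent leg) spanning at least
30% of the dive with |rate| in [0.01, 1.2] m/s — thresholds from the
drift-dive literature, exposed in configuration and sensitivity-tested,
since no canonical values exist. The classifier is a random forest on
per-dive features (best candidate's duration fraction and |rate|, the SD of
interior-segment rates, depth span, dive duration, maximum depth), trained
"semi-supervised" on simulator-labelled dives plus any user-labelled
examples; a dive with no candidate has probability 0 by definition.
Isolated positive drifts are excluded unless ≥ 2 other positive segments
from the same animal fall within ±5 days; all positives are flagged for
manual review regardless.

Trips with fewer than one retained segment per two days are excluded. The
per-trip smoother is a cubic P-spline (knots ≈ every 5 days, capped by the
number of distinct segment times) fitted by weighted penalized least squares
with GCV-chosen smoothness, weights = depth weight × classification
probability. "Constrained" is interpreted as range-bounding: predictions
are clipped to the observed drift-rate envelope ± 0.05 m/s (the cited
constrained-spline methodology supports several constraint types and the
source does not say which; the constraint type is a config enum). Daily
rates are evaluated at UTC-day midpoints; the daily change is the central
finite difference (one-sided at the ends), so interior changes telescope to
the endpoint rate difference — a property the tests verify.

## Environmental covariates

Gridded bathymetry and ice are looked up nearest-cell (bilinear optional);
time-indexed grids match the nearest date. SST per dive comes from the
shallowest CTD point — nominally 6 m; the implementation takes the
minimum-depth point whatever its exact depth — directly when a cast lies
within 3 h, otherwise by time-linear interpolation between bracketing
casts' shallowest-point temperatures (linear-in-time is the least-assuming
choice and is flagged per dive via `sst_source`). Beyond the first/last
cast the nearest cast's value is used and flagged. Daily environmental
values are plain means over each animal-day.

## Habitat models

Each daily index is modelled as a Gaussian additive model with
penalized-regression-spline smooths (basis dimension 5 by default) of
standardized bathymetry and SST — per age/sex class when more than one
class is present — plus random intercepts for animal and trip (`bs = "re"`
in mgcv). Fitting uses maximum likelihood, not REML, so AICs are
comparable across different fixed-effect structures; the AIC reported is
mgcv's (conditional on the estimated smoothness), which we state explicitly
because mixed-model AIC definitions vary. Random slopes are not included
(random slopes are rarely identifiable at these sample sizes). A Gaussian response is used for
all three indexes; an FPT log-transform is available via the caller since
positivity might suggest it, but is not the default. All 2^k combinations
of the smooth terms are enumerated; candidates within ΔAIC < 2 are reduced
by fewest model terms (intercept + class effect + smooths), ties broken by
lower AIC then lexicographic term order.

## The synthetic SRDL generator

The generator is first-class, tested code: it emulates a deployment of
pups, adult females and adult males (default mix 0.40/0.45/0.15, the
approximate composition of a realistic hooded-seal tagging campaign) from a
colony at 13.50° E, 73.86° N, alternating haul-outs with trips to offshore
patches. Movement is mechanistic — transit is fast and directed (1.1 m/s,
15° heading noise), in-patch search is slower (0.6× transit) and tortuous
(60° heading noise per hour) with reflection at the patch boundary — so ARS
detection is genuine inference, never a label lookup. The in-patch walk
parameters were calibrated once so the realized search area fills the
nominal patch disc; the patch radius is thereby the generator's true ARS
scale. Patch dwell time is `dwell_factor` × the patch crossing time.

Argos errors are isotropic Gaussian per LC with the SD table above; LC Z
fixes (2%) and 40-km spikes (1%) are injected deliberately as filter
artifacts, recorded in the ground truth. Dive depths and durations are
lognormal per class, spanning typical pup (median ≈ 75 m, ≈ 4.5 min) vs
adult (≈ 230–250 m, ≈ 12–13 min) envelopes, capped by local bathymetry;
dives inside patches get a 1-SD elevation of both transit rates (the
foraging signal). With probability `drift_dive_prob`, a dive carries a
passive drift segment (35–45% of the dive) whose rate is the animal's
current condition trajectory plus N(0, 0.02 m/s) noise; by default the
trajectory itself declines at 0.004 m/s·day⁻¹ while transiting and rises at
0.006 m/s·day⁻¹ inside patches from a start of −0.25 m/s, clamped to
[−1.2, +0.3] m/s — creating the detectable derivative signal the condition
index targets. A fraction of non-drift dives (8%) contain slow gliding
mid-segments as hard classifier negatives. CTD casts carry exactly 17
points from 6 m down; the 6-m temperature equals the synthetic SST field
plus N(0, 0.1 °C).

Synthetic bathymetry, monthly SST and ice fields are smooth analytic
surfaces over 30° W–40° E, 55–85° N with realistic ranges (shelf-to-basin
depths, −1.9 to ~11 °C, ice increasing to the northwest with a winter
maximum). What the generator does **not** emulate: Argos error ellipses and
temporal clustering of fixes, prey-driven patch dynamics, physiological
dive mechanics, ocean circulation, and transmission dropout. Passing
recovery tests on this generator therefore demonstrates the inference
machinery is correct and unbiased under its stated error model — not that
any particular field dataset satisfies that model.

## Numerical choices and degenerate inputs

Fewer than 3 fixes skip SDA filtering (warned); trips shorter than one
resampling interval collapse to a single flagged point; an all-equal FPT
variance curve is flagged non-informative; PCA refuses zero-variance rates
naming the degenerate variable; the drift spline requires 4 positively
weighted segments and reduces its basis on singularities; standardization
refuses constant columns; class-specific smooths refuse single-class
tables; fully tied rank comparisons return p = 1 with a warning. Quantiles
are type 7 with strict exceedance. Ties for the most distant trip point go
to the earliest time; azimuths follow the navigation convention (clockwise
from north, cos = N–S, sin = E–W).

## Problem sizes

The shipped analyses and tests use deliberately modest problem sizes — a
6-animal, 60-day deployment for the worked example, and 12–30-day
single-animal simulations repeated over 20 seeds for the recovery
experiments — chosen so the full suite re-runs in minutes on a laptop while
keeping every estimate's sampling error well inside the asserted margins.

## Known limitations

The CTCRW smoother estimates a single (β, σ) per track segment and no Argos
error ellipses; the FPT implementation interpolates crossing times linearly
within 5-km steps (sub-interval excursions are invisible); the classifier's
labels come from the generator, so its field performance depends on how
well candidate features transfer; the range constraint on the drift spline
is a projection (clip), not a constrained basis; and model-selection AIC on
penalized smooths is conditional on the estimated smoothness.
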