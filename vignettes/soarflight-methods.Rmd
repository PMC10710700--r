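---
title: "Methods: flight-mode classification, weather annotation and crossing models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flight-mode classification, weather annotation and crossing models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soarflight)
```

This vignette is the package's own account of its methods: the sorting
rules, the geometry, the weather derivations and the statistical layer, the
assumptions behind each, and the design decisions taken where the procedure
was genuinely open.

## The data model

The atomic record is a *fix*: bird identifier, UTC timestamp at 1 s
resolution, WGS84 longitude/latitude, altitude above mean sea level (m),
ground speed (km/h) and, when the logger collects them, the accelerometer
z-axis sample in milli-g and the magnetometer x-axis sample in milliGauss.
Loggers duty-cycle: a 5-minute burst at 1 fix/s followed by a 10–15-minute
pause. All timestamps are treated as UTC; analyses that need local clock
time (the morning decision window) apply a configurable UTC offset,
default +2 h (Central European Summer Time), because logger time bases are
not always documented.

## Behaviour sorting

1. **Roost filter.** Fixes with recorded speed *lower than* 1 km/h are
   omitted; the boundary value 1.0 is kept.
2. **Burst segmentation.** Maximal runs of consecutive fixes exactly 1 s
   apart; runs need more than 10 points to be usable (`min_len = 11`).
3. **Active/passive split (accelerometer).** Passive flight keeps acc-z
   smooth inside the 800–1400 milli-g band. "Strong oscillation" is not a
   quantified notion, so it is operationalised with two config-exposed
   thresholds: a burst is passive iff at least 90% of its acc-z samples lie
   in the band *and* the median peak-to-peak amplitude over 10 s rolling
   windows stays under 300 milli-g (the band's width is 600 milli-g, so a
   flapping signal that traverses the band still fails the smoothness
   test). The median across windows, rather than the maximum, makes the
   call robust to a single noisy window. Widening the band can only move
   bursts from active to passive, never the reverse.
4. **Soaring/gliding split (magnetometer).** A circling bird's heading
   rotates through the Earth's field, so mag-x oscillates with the turn
   period; a gliding bird's mag-x is smooth. A passive burst is soaring iff
   the dominant non-DC periodogram peak of the linearly detrended mag-x
   (summed over a 3-bin neighbourhood, the standard allowance for spectral
   leakage) carries at least 30% of total power, and the detrended signal
   crosses zero at least twice per 60 s. Pure noise spreads its power over
   all bins and fails the first test; slow calibration drift fails it after
   detrending.

Classification granularity is per burst: the field's sorting descriptions
mix per-burst and per-fix views, and a burst is the natural unit of the
duty-cycled logger. Every retained burst receives exactly one of
{flapping, gliding, soaring}.

**Climb rate** is the difference between a segment's maximal and minimal
altitude divided by the elapsed time between those two extrema, signed
positive when the maximum comes later. Dividing by the extrema interval
(not burst length) is our choice; the quantity is reported in m/s and a
height difference alone has no rate unit.

## Soaring-pattern geometry

Headings are initial great-circle bearings between consecutive fixes.
Signed heading changes, wrapped to (−180°, 180°], are accumulated; each
crossing of ±360° emits a *full turn* and reduces the accumulator by 360°,
so residual rotation carries into the next turn. Segments without any full
turn are **s-shape**. Otherwise each turn is typed by its fitted diameter —
**spiral** below 10 m, **staircase** at or above — and the segment takes the
more frequent turn type. Two tie-breaks are fixed and documented: a
diameter of exactly 10 m is staircase (the "at or above" branch), and a
tied turn count is staircase.

The turn diameter uses a least-squares circle (Kåsa algebraic fit) in a
local tangent plane (equirectangular about the segment centroid; distortion
over burst-scale extents of a few km is far below 1%). Two corrections
matter in practice:

* **Drift compensation.** A bird circling in a thermal drifts with the
  wind, and over one full turn the start-to-end displacement equals exactly
  the accumulated drift. A linear ramp matching that displacement is
  removed before fitting; otherwise a 7 m circle in a 2 m/s wind fits as a
  ~16 m circle. For a closed, drift-free turn the compensation is a no-op.
  How turn "diameter" was measured in the field literature is not
  specified; the drift-compensated circle fit is this package's definition.
* **Noise-bias correction.** Algebraic circle fits satisfy
  `E[r̂²] ≈ r² + 2σ²` under isotropic position noise, so the fit's residual
  mean square (with a 3-degree-of-freedom correction) is doubled and
  subtracted in r² space. Monte-Carlo bias is within ±3% for radii 2–50 m
  at σ ≤ 1 m; the uncorrected fit is ~22% high at r = 2 m. The correction
  vanishes on noiseless input and is floored at half the raw radius for
  pathological residuals.

Collinear points make the fit degenerate; the fit errors rather than
returning an arbitrary circle, and turn-level failures become `NA`
diameters that the majority vote ignores.

## Weather annotation

Wind `u`, `v` are the ERA5-convention "toward" components: the compass
azimuth of the flow is `atan2(u, v)`. With travel azimuth θ,

* wind support (tailwind) = `u sin θ + v cos θ` (signed; negative is
  headwind),
* side wind = `|u cos θ − v sin θ|` (a magnitude, as the decision models
  use it),

so `tailwind² + sidewind² = u² + v²` holds identically — a property the
test suite checks to 10⁻⁹. Getting the to/from convention wrong flips every
tailwind sign; the decomposition is documented and anchored by aligned- and
opposed-flow tests.

ΔT = T_surface − T_air at flight altitude is the thermal proxy: positive
when the surface is warmer than the air aloft (convective uplift), negative
in sinking air.

Grid interpolation follows the usual annotation practice: bilinear in
lon/lat for wind at the two bracketing hours, then linear in time (the
temporal rule is unstated in annotation services; linear is our choice);
nearest node and nearest hour for temperatures, cloud cover and
precipitation. The pressure level per fix defaults to an automatic rule —
925 mb over land or for birds whose mean flight altitude exceeds 400 m,
1000 mb otherwise — with a per-bird override for individuals that cross
unusually high. `isa_altitude_m()` gives the International Standard
Atmosphere altitude of a pressure level (925 hPa ≈ 762 m); reanalysis
geopotential heights can differ from ISA near the surface, which is why the
function is provided as a check, not as a data source. Temperatures are
degrees Celsius internally; Kelvin grids are converted on read. When a bird
yields several fixes within one clock hour, weather variables are averaged
per bird-hour and the temporally middle fix supplies the representative
position.

The travel azimuth is configurable per track: for sea crossings the bearing
between the first and last over-water fix (`crossing_azimuth()`), for land
legs a fixed breeding-site-to-coast bearing, or the consecutive-fix bearing
when no larger-scale direction is meaningful.

## Crossings and the departure dataset

A *crossing* is a maximal run of consecutive over-water fixes (point not in
any land polygon) whose over-water route exceeds 20 km — a conservative,
configurable floor that separates true transits (the study system's
crossings are on the order of 190 km) from near-shore loops. Route length
is the sum of haversine legs (Earth radius 6371.0088 km), duration the
first-to-last fix interval, and mean speed their ratio, so
`speed × duration = length` holds by construction.

The departure dataset compares the weather a bird experienced on coastal
*resting days* against the *crossing day*. Records are hourly averages in
the 6:00–13:00 local window. Resting days walk back from the crossing day
as long as fixes exist in the window, and at least two such days are
required (configurable), matching the study design of birds that staged by
the shore. On the crossing day, records run from the window start until the
bird's distance from the nearest shore first exceeds 10 km; birds that
venture a few km offshore and return therefore still count as resting.
"Distance from shore" is the great-circle distance to the nearest point of
any land-polygon boundary (densified at ~1 km); whether the original
threshold meant the departure shore specifically is unknowable, and nearest
shore is the implemented reading.

## The statistical layer

Predictors are standardized (mean 0, SD 1, n−1 denominator) so
coefficients are comparable; the scaling record is kept for
back-transformation, and constant columns are an error. Predictor pairs
with |Pearson r| ≥ 0.6 are screened: the lower-priority member of each
offending pair is dropped iteratively (priority defaults to the column
order; in the study system this is how cloud cover leaves the soaring
models, being strongly correlated with ΔT). 1 Hz behavioural data are
thinned to one record per 30 s — response taken at the block's first fix,
covariates averaged over the block, incomplete blocks dropped entirely
(conservative; no partial averages) — because full-rate responses leave
heavy lag-1 autocorrelation in model residuals, which the test suite shows
the thinning reduces.

Models are binomial logit fits: `lme4::glmer` with a per-bird random
intercept (Laplace approximation), or `stats::glm` for model families
specified without one (the pattern models, which have too few birds per
class to support a random intercept). Convergence failures are flagged and
excluded from averaging with a warning; a singular fit (random-effect
variance estimated at zero) is a valid boundary optimum, not a failure.

`dredge_average()` fits every fixed-term subset respecting marginality —
polynomial terms are atomic units, and an interaction enters only alongside
both parent variables (whether dredging should keep poly pairs together is
undocumented in the field workflow; keeping them together is our choice) —
ranks by AIC or AICc (AICc for the departure family, whose effective sample
is small; AIC elsewhere), and averages the models within Δ < 2 of the best
using Akaike weights renormalised over that set. *Full* (zero-substituted)
averaging is the default, because the averaged tables this workflow mirrors
report a z and p for every term; conditional averaging is a switch.
Averaged standard errors use the usual
`Σ w √(SE² + (β − β̄)²)` form. Orthogonal polynomials come from `poly()`
on the standardized covariate; a raw-polynomial spelling is available.

`nakagawa_r2()` implements the variance-partition R² for logit models:
R²m = σ²_fixed / (σ²_fixed + σ²_RE + π²/3), with R²c adding σ²_RE to the
numerator. `kfold_accuracy()` partitions rows into 10 folds stratified by
the response (the fold seed is recorded), refits on each training set and
scores held-out responses at a 0.5 probability cutoff. The field's
"predictive accuracy" measure for binomial mixed models is not precisely
defined; proportion-correct at 0.5 is the stated operationalisation here.
Group comparisons use Shapiro–Wilk normality checks, two-sided
Mann–Whitney U tests for continuous metrics and chi-square (no continuity
correction) for count ratios.

## What the generator emulates — and what it does not

`simulate_flight()` works in kinematic space (headings, airspeeds, climb
rates in a local tangent plane, back-projected to lon/lat), while the
classifier works in sensor space; truth labels and classifier features are
therefore decoupled. Per mode:

* *flapping*: near-straight path, climb ≈ 0, acc-z as 1 Hz samples of a
  high-variance process (σ ≈ 300 milli-g about 1100) — wingbeats at 3–6 Hz
  cannot be resolved at 1 Hz, so only their aliased variance is modelled;
* *gliding*: straight descending path (0.5–1.5 m/s sink), smooth acc-z
  (σ ≈ 40 milli-g) and mag-x;
* *spiral*: a tight circle (diameter 5–9 m) whose centre drifts with the
  wind, climbing 0.3–1.5 m/s; turn periods are drawn at 8–12 s because
  1 Hz sampling cannot resolve faster rotation — a deliberate
  resolvability choice, not an aerodynamic claim;
* *staircase*: alternating blocks of two wide turns (diameter 20–40 m) and
  straight runs, climbing in the turns;
* *s_shape*: heading oscillation of amplitude 40–80° with net climb and no
  cumulative full turn.

mag-x is modelled as `400·cos(heading + phase) + noise` — only its
oscillation matters, not magnetometer calibration. Ground velocity is air
velocity plus the configured wind, and ground speed is reported from the
true velocity. Defaults: GPS σ = 1 m, airspeeds 8–12 (soaring), 12–18
(gliding), 10–14 (flapping) m/s — plausible for a ~950 g kite and stated
as assumptions, since airspeed distributions for the study system are not
published. Identical seeds reproduce output bit-for-bit.

The decision-table generators draw standardized covariates and Bernoulli
responses from logistic models with per-bird normal random intercepts
(SD 0.5 by default); the soaring model's default coefficients are the
sea-soaring effect sizes (1.51, 1.65, 1.97, interaction 1.65) and the
departure model's the wind-support effect (0.99 with intercept −1.97), so
parameter-recovery tests run against published-scale effects.

What the generator does **not** contain: aerodynamic forces, boundary-layer
or large-eddy structure (thermals exist only through prescribed climb rates
and ΔT covariates), correlated GPS error, logger dropout, or behaviour that
switches within a burst. Passing the recovery tests therefore shows the
pipeline recovers the generator's world, not that real tracks are this
clean; on real data the sorting thresholds (passive band, smoothness,
oscillation power fraction) are the knobs to revisit, and all are exposed
as arguments.

## Problem sizes and numerical choices

The shipped tests use 600 bursts (200 per behaviour class) for
classification recall, 150 segments per noise case for pattern agreement,
10⁵ draws for the wind identity, 100 simulated replicates of n = 2000 /
10 birds for GLMM coefficient recovery and null calibration, and a
constructed 189 km, 58 km/h transit for the crossing metrics — sizes chosen
so the full suite runs in a few minutes on one CPU while keeping
Monte-Carlo error well inside the asserted margins. Floating-point
identities are asserted at 10⁻⁹, hand-computed averaging oracles at 10⁻⁹,
and geometric examples at the tolerance their construction supports.

## Known limitations

* The spectral soaring test assumes the magnetometer x-axis sees heading
  rotation; a logger mounted so that the x-axis aligns with the rotation
  axis would defeat it.
* Pattern classification needs turn periods of roughly ≥ 8 s at 1 Hz;
  faster real spirals alias and would be read as s-shape.
* The departure-dataset builder assumes one coastal staging period per
  crossing and walks back day by day; multi-leg staging with gaps in the
  decision window truncates the resting series.
* `read_weather_grid()` reads long-format CSV only; NetCDF sources must be
  exported to CSV first.
* Distances to shore are polyline-vertex distances after ~1 km
  densification — adequate for 10 km thresholds, not for sub-km work.
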