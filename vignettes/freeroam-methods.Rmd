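---
title: "Movement models and estimators in freeroam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement models and estimators in freeroam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`freeroam` analyses motion-triggered GPS collar data from free-roaming
domestic dogs: cleaning, movement metrics, movement-based home ranges, and
mixed-model risk-factor analysis, plus a simulator that generates such
data with known ground truth. This vignette records the models, the
parameter choices, and the reasoning behind decisions that were genuinely
open.

## The data-generating setting

The loggers this pipeline targets record one fix per minute *while the
collar is in motion* and nothing while the dog rests. Gaps are therefore
informative — they are rests at the last seen location, not missing data —
and observed fix rates fall well below the nominal 60/h (typically a
median around 20/h). Deployments last around five days; dogs are sampled
in clusters (study sites), which motivates the random-intercept models of
the final stage.

## Trajectory simulator

The simulator is a first-class, tested module: it defines the conditions
under which every downstream estimator is validated.

**Movement model.** A two-state continuous-time process, integrated at
`sim_dt` (5 s) resolution. The dog alternates *resting* bouts (perfectly
stationary, exponential duration, mean `rest_mean_s` = 1700 s) and
*travelling* bouts (exponential, mean `travel_mean_s` = 1300 s). At the
start of each travelling bout a target is drawn — the household (weight
`home_weight` = 0.55) or one of the attraction sites (weights ≈ 0.35–0.45)
— and the position follows an Ornstein–Uhlenbeck pull towards it:
`dX = k (target − X) dt + √(2D) dW`, with rate `k` = 0.01 /s and diffusion
`D` = 0.5 m²/s. The stationary spread around a reached target is
`√(D/k)` ≈ 7 m, i.e. dogs settle clearly *inside* the 20 m household disc
used by the occupancy metric; with a looser hold the disc boundary cuts
through the dwell cloud and whole rest bouts flip in or out of the
occupancy count, which is both behaviourally implausible (dogs rest inside
compounds, not straddling their fence line) and numerically noisy.

**Fix emission.** At each nominal interval (`fix_interval` = 60 s) a fix
is emitted only if the displacement over the preceding interval, divided
by the interval, is at least `move_speed_threshold` = 0.12 m/s; emitted
positions get isotropic Gaussian GPS noise (`gps_noise_sd` = 1.5 m).
Resting bouts therefore emit nothing, and the realized fix rate lands
around 17–20/h for the default configuration — the same regime as the
field loggers the model emulates.

**Ground truth.** Computed from the noise-free path:
`true_fraction_at_household` is the time-weighted fraction of the
deployment spent within 20 m of the household, and per-site visit
fractions likewise. `true_total_path_m` is the length of the *noise-free
polyline sampled at the emitted fix times* — i.e. what a perfect logger on
the same schedule would have measured. A dense-path length would not be a
usable reference: a diffusive path's length grows without bound as the
sampling interval shrinks, so "distance travelled" is only well-defined
relative to a sampling schedule.

**On the noise default.** Summed step lengths overestimate true distance
by roughly `σ_d²/(2L)` per step (σ_d the noise sd of a step difference,
L the step length). With ~30 m median steps this bias is ~7% at a 5 m
noise sd and ~1% at 1.5 m. The default of 1.5 m models only the random
open-sky jitter relevant to step-length inflation; it is deliberately at
the optimistic end so that the distance estimator's *own* error is
visible against the noise floor.

**Cohort generation.** `simulate_cohort()` assigns dogs to sites and
draws per-dog heterogeneity: lognormal site-level multipliers on roaming
propensity (sd 0.35 on the log scale, applied to `D` and travel-bout
length) and on household attachment (sd 0.22, applied to `home_weight`),
plus dog-level variation (sd 0.25/0.3). The site-level components induce
intracluster correlation of the movement outcomes of the same order as
field cohorts show; the attachment multiplier also reproduces the large
between-site spread in household time. Deployments are mostly 4–6 days
with a minority shorter, and `n_short` dogs can be forced under 24 h to
exercise the dog-level exclusion.

**What the simulator does not emulate.** Diel activity cycles, social
interaction between dogs, terrain and road effects, satellite-geometry
dropouts, and systematic (autocorrelated) GPS drift. Tests passing under
the simulator therefore validate the estimators' bookkeeping and
statistical calibration, not their robustness to every field artefact.

## Projection

No projection library is assumed: the package carries its own transverse
Mercator forward/inverse transform (6th-order Krüger series on WGS84),
configurable by UTM zone (default 36N, covering the reference region).
Round-trip error is below 1e-9 degrees and planar distances agree with
ellipsoid geodesics to well under 0.1% for tracks spanning a few
kilometres. Timestamps are interpreted in East Africa Time by default;
the logger dialect (column names, time format, timezone) is configuration,
not code.

## Cleaning

Two rules. (1) *Speed filter*: the average speed between every two
consecutive fixes is computed; while any step exceeds 20 km/h, the
**later** fix of the first offending step is removed and speeds are
recomputed. Removing the later fix treats the jump as the error, is
deterministic, and terminates (each pass deletes one fix); the filter is
idempotent. The threshold is exactly reproduced as "strictly greater
than". (2) *Short recordings*: dogs whose span between first and last fix
is strictly under 24 h are excluded. "Hours of data" is read as elapsed
span, the simplest reading consistent with how recording periods are
reported for such cohorts. Zero-duration steps are flagged invalid rather
than producing infinite speeds; duplicate timestamps are collapsed to the
first occurrence at ingestion.

No DOP/horizontal-error filtering is attempted — the speed rule is the
only positional screen, mirroring the standard practice for these
loggers, which do not export error estimates reliably.

## Movement metrics

*Daily distance* is total summed step length rescaled by
`24 / recording_hours` — robust to partial first/last days; a
per-calendar-day breakdown is available as an option. *Household
occupancy* attributes each inter-fix interval to the location of its
earlier fix (LOCF) and reports the percentage of the recording span whose
attributed location lies within the 20 m household disc. LOCF is the
faithful attribution under motion-triggered logging, where a gap means
the dog stayed where it was last seen. A fix-count weighting and a
maximum-gap cap are provided for sensitivity analysis only; time
weighting with no cap is the default because gaps are informative rests,
not missingness.

## Biased-random-bridge utilization distribution

Each step of duration `T` and length `L` deposits kernel mass along the
straight segment between its fixes. At interpolation fraction
`p ∈ (0,1)` (midpoints of `n_substeps` = 10 equal subintervals) the
kernel is an isotropic Gaussian with variance

`σ²(p) = hmin² + 4 · D · T · p · (1 − p)`

— zero bridge spread at the fixes (where position is known up to GPS
error, floored by `hmin`) and maximal mid-step, the Brownian-bridge
scaling. Each deposit carries weight `T / n_substeps`, so the UD is
time-weighted. Steps longer than `Tmax` (default 3× the track's median
fix interval) are not bridged — interpolation across a long resting gap
is not credible — and steps shorter than `Lmin` = 5 m are treated as
resting; both deposit their time weight at their endpoints with variance
`hmin²`. A single-fix track degenerates to one Gaussian of sd `hmin`.

`D` defaults to the plug-in estimate `mean(L²/(4T))` over qualifying
steps. This is biased low under strong mean reversion and high under
advective transit; it sets the smoothing scale adequately (the validation
suite only requires factor-2 recovery on weakly-reverting tracks), and a
fixed `D` can be supplied instead.

**Numerical choices.** Kernels are evaluated exactly at cell centres
(separable 1-D Gaussian products) and truncated at 8σ, where the
remaining tail is below 1e-14 of a kernel's mass — the builder matches a
no-truncation brute-force oracle to 1e-10 per cell. Mass is normalized to
sum to 1 on the grid; the grid covers the track's bounding box plus
`extent_pad` = 200 m at `cell_size` = 10 m, with a configurable cell-count
guard. Defaults `hmin` = 25 m (GPS error scale of cheap collars) and the
rest are config-exposed and embedded in output metadata.

**Isopleths.** The `level`% isopleth is the smallest set of cells whose
cumulative mass reaches `level`/100, taking cells in descending mass
order with ties broken in row-major order for determinism. Selected cells
are merged into polygons under 4-connectivity (diagonal-touching cells
stay separate — conservative for centroid counts); areas are cell counts
× cell area (1 ha = 10⁴ m²); each polygon's centroid is the unweighted
mean of its member-cell centres, reported in planar and geographic
coordinates. Isopleths nest by construction. Boundary rings (for GeoJSON
export) are traced by chaining unshared cell edges, outer rings
counter-clockwise and holes clockwise; at diagonal pinch points the
sharpest right turn is taken so rings stay simple.

For a stationary track the UD is a single Gaussian, for which the
closed-form contour area is `2π σ² ln(1/(1−p))`; the validation suite
checks the 95%/50% area ratio `ln 20 / ln 2 ≈ 4.32` at
`cell_size ≤ hmin/5` within 5%, and grid-refinement stability (halving
the cell size moves areas by <5%).

**Scale of the resulting home ranges.** Core/extended areas depend
strongly on `hmin`: with `hmin` = 25 m, a single dwell cluster already
occupies ~0.3 ha at the 50% level of its own mass, so cohorts whose dogs
split time across a household plus two or three sites produce core HRs
around 1–2 ha and extended HRs around 10–20 ha. Field analyses that
report substantially smaller cores imply smaller effective smoothing;
since those parameter values are generally unreported, cross-study
comparison of absolute hectare values should be treated as
order-of-magnitude.

## Risk-factor models

The four outcomes (daily distance, core HR, extended HR, % household
time) are screened for pairwise collinearity (|Pearson r| ≥ 0.7 flags a
pair; all four are kept as separate outcomes otherwise). Core HR is
square-root transformed and extended HR log transformed before modelling.
Age is dichotomized (<1 yr vs ≥1 yr, referent <1 yr) and sex × neuter
status uses intact male as referent.

Models are REML random-intercept fits (`lme4`), site as the grouping
factor. Coefficient p-values use the large-sample Wald z convention and
categorical terms get joint Wald chi-square tests — matching the
reporting conventions of the general-purpose mixed-model software used in
field epidemiology. Significance is declared at p ≤ 0.1 (a deliberate
type-II guard at n ≈ 70); no multiple-testing correction is applied, by
design. The intracluster correlation is `σ²_b / (σ²_b + σ²_w)`. A
boundary fit (zero between-site variance) is reported as ICC 0, not an
error, and the fixed effects then coincide with ordinary least squares; a
single-site table falls back to OLS with a warning. Influence is assessed
by leave-one-site-out refits (coefficient sign stability) and
standardized residuals beyond |z| = 3.

The calibration suite verifies, at the field design size (73 dogs, 8
sites): ~95% CI coverage under the null, recovery of a planted
coefficient β = 3 to within 10% over 200 replicates, mean ICC recovery
within 0.08 of a true 0.2, and near-uniform null p-values.

## Reporting

Per-site and overall medians of the four outcomes; a centroid inventory
at the 10/50/90% levels (the levels a ground-truthing walk would visit)
with an empty free-text label column — the package tabulates labels, it
never infers land use; and cross-dog overlap flags for centroid pairs
within 50 m (a configurable default — "same location" has no canonical
distance). Outputs are plain CSV, ESRI ASCII grid (UD rasters), and
GeoJSON (isopleths and centroids, WGS84).

## Problem sizes used in validation

The shipped validation suite runs the brute-force oracle on ≤5-fix
tracks over ≤400-cell grids; simulator-truth recovery on a 50-dog
cohort (occupancy within ±5 points, distance within 2%, home-pinned 50%
centroids within 2 cells of the household); and 200-replicate
mixed-model calibration studies. The acceptance script analyses a
74-dog, 8-site cohort end to end. These sizes were chosen to match the
field design they emulate while keeping a full run in minutes on one
core.

## Known limitations

- LOCF occupancy inherits the logger's motion gate: a dog that rests just
  outside its compound after a slow approach can be mis-attributed for
  that bout; with realistic settle behaviour the per-dog error stays
  within a few percentage points.
- The plug-in diffusion estimate conflates advection and diffusion;
  bridge widths mid-step are approximate.
- Isopleth areas are cell-counting areas; very small cores are quantized
  to the cell size.
- The Wald z convention is mildly anti-conservative versus
  degrees-of-freedom-corrected tests at 8 clusters; with the p ≤ 0.1
  screening convention this is immaterial, but exact small-sample
  inference is out of scope.
- The simulator's realism envelope is documented above; it is a
  validation instrument, not a behavioural model of record.
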