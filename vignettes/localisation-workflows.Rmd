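---
title: "Localisation workflows for automated radio telemetry grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localisation workflows for automated radio telemetry grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridloc)
```

## The problem

Automated radio telemetry systems (ARTS) track small animals — here,
high-Andean hummingbirds — with a grid of fixed receiver nodes that log
the identity and received signal strength (RSS, in dB) of tag
transmissions. RSS decays with distance, so a calibrated RSS–distance
curve turns each node's reading into a rough range, and ranges from
three or more nodes can be combined into a position estimate. Every step
of that chain involves analytical choices, and the choices interact:
which RSS summary to use per relocation, whether and how to smooth the
signal series, at what scope to calibrate the decay curve, how to select
nodes and combine ranges, and whether to smooth the resulting track.
`gridloc` implements the full decision factorial — 2 RSS types × 3
signal smoothers × 3 model scopes × 4 localisation methods × 3 track
smoothers = 216 workflows — together with error evaluation against
ground-truth tracks, random-track nulls, spatial covariates of error,
and a synthetic scene generator so the whole pipeline can be exercised
and validated without field data.

## Signal preparation

Raw detections are matched to the ground-truth relocation with the
nearest timestamp; matches farther than `max_gap = 10` s are discarded
(the window absorbs reception delays and GPS/node clock mismatch; the
comparison is strict, a tie goes to the earlier fix). Per relocation and
node, the maximum RSS is taken over all contributing reads — maxima are
robust to signal bouncing and multipathing — while the average RSS is
recomputed after a single outlier pass that removes reads at least
`outlier_db = 4.33` dB away from the plain mean (a calibration-derived
default: 95% of the original grid's reads fell within 4.33 dB of their
average; it is data-specific and exposed as a parameter). The pass is
deliberately single, not iterative, and if it would remove every read,
the plain mean is kept.

## Smoothing

Both RSS series (per trial × node, never pooled across nodes) and
coordinate series (per track × axis) can be smoothed two ways:

* **Cubic smoothing splines** (`stats::smooth.spline`) with the penalty
  chosen by generalised cross-validation. Series with fewer than 5
  observed points pass through unchanged, flagged unsmoothed.
* **A local-level state-space model**: a random-walk latent level plus
  white observation noise, put on a regular grid at the tag's nominal
  emission interval (2 s solar tags, 60 s battery tags — the natural
  sampling rate). The two variances are estimated by maximum likelihood
  on the log scale (so a quasi-Newton BFGS search is unconstrained while
  the variances stay non-negative), with a diffuse prior on the level
  and method-of-moments starting values from first differences. The
  fixed-interval Kalman smoother then yields posterior means, missing
  slots included, and values are read back at the original observation
  times (nearest grid slot). Series under 2 observed points pass
  through; optimiser failure falls back to the starting values, flagged
  degraded.

When two observations collide in one regular-grid slot, the stronger
value wins for RSS (consistent with max-selection) and the first wins
for coordinates. The likelihood drops the first (diffuse) prediction, so
it is comparable across variance values; the implementation is checked
against `stats::StructTS` in the tests.

## Decay calibration

The RSS–distance relationship is modelled as exponential decay

RSS = a·exp(−S·d) + K

with intercept `a` (dB above the asymptote), decay factor `S` (1/m) and
horizontal asymptote `K` (dB): the curve starts at `a + K` at the node
and flattens to `K`, the level at which a read carries no distance
information. Starting values follow a self-starting asymptotic
regression heuristic — `K₀` = minimum RSS, `a₀` = range, `S₀` from a
log-linearised regression of `log(RSS − K₀ + 0.5)` on distance, the
0.5 dB offset only guarding the logarithm — refined by nonlinear least
squares (port algorithm, Levenberg–Marquardt fallback). Calibration is
two-step: a pooled fit first, then per-node or per-tag refits started at
the pooled estimates, with all three parameters free; groups under 10
points (3 parameters need headroom) or failed refits fall back to the
pooled model, flagged. Uncertainty comes from a case-resampling
bootstrap with percentile intervals; residual autocorrelation along
tracks is acknowledged but not modelled. Least squares is unweighted; a
weighting hook is left off by default.

## Localisation

Inverting the fitted curve gives `d = −ln((RSS − K)/a)/S`. Reads at or
below `K` are excluded; reads above `a + K` (negative solutions) are
clamped to 0 m — the tag is essentially at the node. Relocations with
fewer than 3 valid nodes are skipped. Four methods then produce a
position:

1. **all_nodes** — nonlinear least squares over every valid node,
   minimising Σ(d̂ᵢ − ‖p − nᵢ‖)² from the inverse-distance-weighted
   centroid (weights 1/(d̂+1 m)); objective tolerance 1e-8 m, 200
   iterations, with an exhaustive 1 m grid search over the padded node
   box as a flagged fallback. Residuals are in distance space, not RSS
   space. Collinear subsets are attempted but flagged.
2. **strongest3** — trilateration with the three strongest-RSS nodes
   (the workflow's active RSS type; boundary ties broken by node id and
   counted).
3. **nearest3** — trilateration with the three smallest estimated
   distances. Under a single pooled model this is identical to
   strongest3 (the inversion is monotone); the two only diverge under
   per-node or per-tag models.
4. **grouped_kmeans** — consensus: every subset of size ≥ 3 of the ≤ 7
   strongest nodes is multilaterated (99 candidates at 7 nodes), the
   candidate cloud is clustered by k-means (k scanned 1–5, 10 restarts,
   seeded), and the centroid of the largest cluster is returned, ties
   going to the tighter cluster. k is picked by a fixed elbow rule —
   the smallest k whose incremental within-cluster sum-of-squares
   reduction from k−1 is below 10% of the k = 1 total — because "reduce
   the within-cluster sum of squares" needs a deterministic, testable
   form; coincident candidates collapse to k = 1.

## Track post-processing and evaluation

Estimated coordinate sequences can be smoothed per axis with the same
two smoothers, and speed-filtered: step speeds above a threshold (the
0.95 quantile of the track set's speeds, or a hard cap such as the
25 m/s used for hummingbird tracks) mark the terminating fix for
removal, re-checking after each pass since one teleporting fix inflates
two steps. The filter removes the later fix to preserve the track start,
and runs before smoothing by default (both points are configurable; the
order is not dictated by the data).

Error is the planar Euclidean distance between estimate and truth in the
working CRS. `run_workflows()` executes the full factorial and emits a
long table (one row per relocation × workflow) ready for external
mixed-model/AICc analysis — fitting those models is deliberately out of
scope. Random-track nulls resample each trial's step lengths and turning
angles with replacement (start at the trial centroid, clipped to the
padded node box), preserving duration, fix count and step-speed
distribution; the observed per-trial median error is paired with the
mean surrogate median in a Wilcoxon signed-rank test. This
step-resampling surrogate stands in for continuous-time movement-model
simulation: it is self-contained and matches the speed distribution by
construction. Spatial covariates per relocation: terrain ruggedness (sd
of DEM cells whose centres fall within a 100 m buffer — cell-centre
inclusion, no partial weighting), flight height (GPS elevation minus
bilinear DEM), dominant vegetation class within 100 m (ties resolved
grassland > paramo > dense > builtup), and membership in / signed
distance to the convex hull of the nodes — the hull because "inside the
grid" needs a deterministic polygon.

## Geospatial plumbing

All distances are metric: coordinates are projected into the UTM zone of
the node-registry centroid (override available). The transverse-Mercator
forward/inverse series are implemented in the package and verified
against a geodesic oracle to far below the 0.1% distortion budget at
grid scale. Rasters live in a small single-band container serialised as
plain-text ESRI ASCII grids; vegetation polygons arrive as GeoJSON and
are rasterised by cell-centre inclusion. Truth tracks read from GPX 1.1
or CSV; detection tables from the canonical CSV schema
(`tag_id,node_id,timestamp_utc,rss_db`) or CTT SensorStation exports via
a declarative column map.

## The synthetic generator

`simulate_scene()` builds what a calibration campaign produces: a
rectangular node lattice (150 m default spacing; dropouts emulate failed
nodes, e.g. 49 − 3 = 46), correlated-random-walk trial tracks with
lognormal steps matched to the trial speeds reported for drone flights,
mid-level walks and ground walks (3.57, 0.44, 0.31 m/s; flight heights
≈ 39, 1, 0 m agl), a smooth DEM and a blocky vegetation raster, and RSS
detections from the known decay law (defaults a = 68, S = 0.01 /m,
K = −105 dB) plus per-node offsets, an emitter-position vegetation
penalty, and per-node AR(1) noise (default ρ = 0.6 — autocorrelated
noise is precisely what the smoothing axis exists to exploit). Reads
below the −115 dB detection floor are never emitted, reproducing the
censoring of a real grid, and emission timestamps are jittered up to 1 s
to exercise the matching step. All randomness derives from one scene
seed through named substreams; noise is drawn as standard innovations
scaled by `noise_sd`, so scenes differing only in noise level share the
same noise shape — this is what makes error-vs-noise monotonicity
checks sharp.

What the generator does **not** emulate: multipath interference and
antenna gain patterns, path-integrated vegetation attenuation (the
penalty uses the class at the emitter only), clock drift between nodes,
and the heavy-tailed outliers of real receivers. Passing tests on
synthetic scenes therefore validate the pipeline's logic and its
statistical behaviour under the stated noise model, not field accuracy.

## Numerical choices and problem sizes

Test and acceptance runs use 5×5 grids, trials of 60–120 s, and
bootstrap sizes of 199 (scaled down from the 999 used for real
calibrations), which keep every check well under desk-scale compute
while preserving the behaviours being asserted. Multilateration is run
unweighted; ties everywhere (matching, ranking, vegetation classes,
cluster sizes) have declared deterministic rules so reruns are
bit-reproducible under a fixed seed.

Known limitations: with unweighted distance residuals, far nodes whose
reads sit just above the asymptote can dominate the all-nodes objective
in synthetic scenes, so the field observation that nearest-node
trilateration is the worst method is asserted as a seeded trend against
strongest-node trilateration (the contrast the decision actually
changes), not as a universal ordering. The low-flight trial height is
taken as ~1 m (waist level); 2-D localisation treats height only as a
covariate, never as a state variable.

## A worked example

```{r example, eval = FALSE}
library(gridloc)

cfg <- scene_config(n_rows = 5, n_cols = 5, noise_sd = 2, seed = 7)
scene <- simulate_scene(cfg)

obs <- prep_observations(scene$detections$high1, scene$tracks$high1,
                         trial_id = "high1")
pts <- calibration_points(obs, scene$tracks$high1, scene$nodes, "max")
model <- fit_decay(pts)
est <- localise_trial(obs, scene$nodes, model, "grouped_kmeans", "max")
err <- compute_error(est, scene$tracks$high1)
median(err$error_m)
```
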