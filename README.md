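# gridloc

Localisation workflows for automated radio telemetry system (ARTS)
grids: from raw node detections of tag radio-signal strength (RSS) to
estimated animal locations, with error evaluation against ground truth.

ARTS grids — fixed receiver nodes that continuously log tag id, RSS and
a timestamp — can track animals too small for GPS tags, such as
hummingbirds, but turning RSS into positions involves a chain of
analytical decisions whose consequences for accuracy are rarely
examined together. `gridloc` implements the full comparative workflow
for researchers calibrating such grids:

* **Signal preparation** — match detections to ground-truth relocations
  (nearest timestamp within 10 s), aggregate per relocation × node into
  maximum and outlier-filtered average RSS (4.33 dB single-pass rule).
* **Signal smoothing** — cubic smoothing splines (GCV penalty) or a
  local-level state-space model with maximum-likelihood variances and
  fixed-interval Kalman smoothing, per trial × node.
* **Decay calibration** — two-step nonlinear least squares fit of

  ```
  RSS = a · exp(−S · d) + K
  ```

  (intercept `a`, decay factor `S`, horizontal asymptote `K`), pooled
  and then per node or per tag, with case-resampling bootstrap
  confidence intervals.
* **Localisation** — distance inversion with asymptote exclusion and
  zero clamping, then one of four methods: multilateration over all
  detecting nodes, strongest-three or nearest-three trilateration, or
  grouped k-means consensus (multilaterate all ≥3-node subsets of the
  ≤7 strongest nodes — 99 candidates at 7 — cluster, return the largest
  cluster's centroid).
* **Track post-processing** — per-axis coordinate smoothing and
  iterative speed filtering (quantile or hard cap, e.g. 25 m/s).
* **Evaluation** — error against truth across the full decision
  factorial (2 × 3 × 3 × 4 × 3 = 216 workflows, exported as a long
  table for mixed-model analysis), step-resampling random-track nulls
  with a paired signed-rank test, and spatial covariates (terrain
  ruggedness, flight height, dominant vegetation, grid membership).
* **Synthetic scenes** — node lattices, correlated-random-walk trials
  at realistic speeds, DEM/vegetation rasters and RSS emission from a
  known decay law with per-node offsets, vegetation attenuation, AR(1)
  noise and a detection floor, so everything above is testable without
  field data.

## Worked example

Simulate a 5 × 5 grid scene with 2 dB AR(1) noise, calibrate the decay
curve from the high-flight trial, and localise it by grouped k-means
consensus:

```r
library(gridloc)

cfg <- scene_config(n_rows = 5, n_cols = 5, noise_sd = 2, seed = 7)
scene <- simulate_scene(cfg)

obs <- prep_observations(scene$detections$high1, scene$tracks$high1,
                         trial_id = "high1")
pts <- calibration_points(obs, scene$tracks$high1, scene$nodes, "max")
model <- fit_decay(pts)
model
#> decay_model [general]: RSS = 68.191 * exp(-0.01013 * d) + -106.945  (n = 3775, resid SE = 2.013 dB)

est <- localise_trial(obs, scene$nodes, model, "grouped_kmeans", "max")
err <- compute_error(est, scene$tracks$high1)
nrow(err)          # 151 of 151 relocations localised
median(err$error_m)
#> 12.7
```

The fitted curve recovers the scene's generating parameters (a = 68,
S = 0.01 /m, K = −105 dB) to within the noise, and the consensus method
places the median relocation about 13 m from the truth under 2 dB of
autocorrelated RSS noise. `run_workflows(scene)` repeats this over all
216 workflow combinations and returns the long error table.

A thin command-line front-end over the same functions lives at
`inst/cli/gridloc.R` (`simulate`, `prep`, `calibrate`, `localise`,
`evaluate` subcommands).

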