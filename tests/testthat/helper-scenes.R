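# Shared fixture builders: everything is generated in code at test time.

# small clean scene: 5x5 grid at 150 m, configurable noise
make_test_scene <- function(noise_sd = 0, seed = 11, node_offset_sd = 0,
                            noise_ar1 = 0.6, duration = 80, fix_interval = 8,
                            n_trials = 2, with_landscape = FALSE) {
  cfg <- scene_config(n_rows = 5, n_cols = 5, noise_sd = noise_sd,
                      node_offset_sd = node_offset_sd,
                      noise_ar1 = noise_ar1,
                      veg_attenuation = c(grassland = 0, paramo = 0,
                                          dense = 0, builtup = 0),
                      seed = seed)
  modes <- c("high_flight", "ground", "low_flight")
  trials <- data.frame(
    trial_id = paste0("tr", seq_len(n_trials)),
    mode = modes[(seq_len(n_trials) - 1) %% 3 + 1],
    duration = duration, fix_interval = fix_interval,
    tag_id = paste0("T", seq_len(n_trials)),
    nominal_interval = 2, stringsAsFactors = FALSE)
  simulate_scene(cfg, trials = trials, with_landscape = with_landscape)
}

# independent brute-force multilateration oracle: coarse-to-exact grid
# scan of the distance-residual objective at `res` metres
grid_oracle <- function(nx, ny, d, pad = 100, res = 1) {
  gx <- seq(min(nx) - pad, max(nx) + pad, by = res)
  gy <- seq(min(ny) - pad, max(ny) + pad, by = res)
  obj <- matrix(0, length(gx), length(gy))
  for (k in seq_along(d)) {
    dist_k <- sqrt(outer((gx - nx[k])^2, (gy - ny[k])^2, `+`))
    obj <- obj + (d[k] - dist_k)^2
  }
  i <- arrayInd(which.min(obj), dim(obj))
  c(gx[i[1]], gy[i[2]])
}

# noiseless/noisy calibration points straight from the decay law
make_decay_points <- function(a = 68, S = 0.01, K = -105, n = 200,
                              d_max = 600, sd = 0, seed = 1) {
  set.seed(seed)
  d <- stats::runif(n, 0, d_max)
  data.frame(distance = d,
             rss = a * exp(-S * d) + K + stats::rnorm(n, 0, sd))
}

# canonical detection data.frame constructor
det_df <- function(tag, node, t, rss,
                   t0 = as.POSIXct("2026-01-15 12:00:00", tz = "UTC")) {
  data.frame(tag_id = tag, node_id = node, timestamp_utc = t0 + t,
             rss_db = rss, stringsAsFactors = FALSE)
}

# minimal relocation track at given seconds/positions
reloc_df <- function(t, x, y, trial_id = "tr",
                     t0 = as.POSIXct("2026-01-15 12:00:00", tz = "UTC"),
                     mode = "ground", elev = 0) {
  data.frame(trial_id = trial_id, reloc_idx = seq_along(t),
             timestamp = t0 + t, x = x, y = y, elevation_gps = elev,
             mode = mode, stringsAsFactors = FALSE)
}
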