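# The synthetic scene generator: grids, tracks and RSS emission.

test_that("lattice grids have the right size, spacing and hull", {
  cfg <- scene_config(n_rows = 7, n_cols = 7, spacing = 150)
  nodes <- make_grid(cfg)
  expect_equal(nrow(nodes), 49)
  # nearest-neighbour distance is the spacing
  d <- as.matrix(dist(nodes[c("x", "y")]))
  diag(d) <- Inf
  expect_equal(min(d), 150, tolerance = 1e-9)
  # dropping 3 nodes emulates a 46-node grid
  nodes46 <- make_grid(cfg, dropout = c("N0101", "N0207", "N0704"))
  expect_equal(nrow(nodes46), 46)
  # 2x2 grid hull area is exactly spacing^2
  n4 <- make_grid(scene_config(n_rows = 2, n_cols = 2, spacing = 150))
  h <- grDevices::chull(n4$x, n4$y)
  xs <- n4$x[h]; ys <- n4$y[h]
  area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  expect_equal(area, 150^2)
})

test_that("simulated tracks stay in bounds at roughly the requested speed", {
  cfg <- scene_config(n_rows = 5, n_cols = 5)
  nodes <- make_grid(cfg)
  speeds <- vapply(1:20, function(s) {
    trk <- simulate_track(nodes, "high_flight", duration = 300,
                          fix_interval = 2, seed = s)
    expect_true(all(trk$x >= min(nodes$x) & trk$x <= max(nodes$x)))
    expect_true(all(trk$y >= min(nodes$y) & trk$y <= max(nodes$y)))
    sum(sqrt(diff(trk$x)^2 + diff(trk$y)^2)) /
      diff(range(as.numeric(trk$timestamp)))
  }, numeric(1))
  expect_lt(abs(mean(speeds) - 3.57) / 3.57, 0.15)
})

test_that("noiseless emission reproduces the decay law and calibrates exactly", {
  cfg <- scene_config(n_rows = 4, n_cols = 4, noise_sd = 0,
                      veg_attenuation = c(grassland = 0, paramo = 0,
                                          dense = 0, builtup = 0), seed = 2)
  nodes <- make_grid(cfg)
  trk <- simulate_track(nodes, "high_flight", duration = 200,
                        fix_interval = 2, seed = 5)
  det <- emit_rss(trk, nodes, cfg, nominal_interval = 2)
  # every emitted rss equals the decay law at the true distance
  t_emit <- floor(as.numeric(det$timestamp_utc))  # jitter < 1 s
  ix <- match(t_emit, as.numeric(trk$timestamp))
  im <- match(det$node_id, nodes$node_id)
  d_true <- sqrt((trk$x[ix] - nodes$x[im])^2 + (trk$y[ix] - nodes$y[im])^2)
  expect_lt(max(abs(det$rss_db - (68 * exp(-0.01 * d_true) - 105))), 1e-9)
  # closed-loop calibration recovers the truth to 1e-4 relative
  obs <- prep_observations(det, trk)
  pts <- calibration_points(obs, trk, nodes, "max")
  m <- fit_decay(pts)
  expect_lt(abs(m$a - 68) / 68, 1e-4)
  expect_lt(abs(m$S - 0.01) / 0.01, 1e-4)
  expect_lt(abs(m$K + 105) / 105, 1e-4)
})

test_that("the detection floor censors honestly", {
  cfg <- scene_config(n_rows = 4, n_cols = 4, noise_sd = 1, seed = 6)
  nodes <- make_grid(cfg)
  trk <- simulate_track(nodes, "ground", duration = 120, fix_interval = 4,
                        seed = 7)
  det <- emit_rss(trk, nodes, cfg)
  expect_true(all(det$rss_db >= cfg$detection_floor))
  # raising the floor above a + K censors everything
  cfg2 <- cfg
  cfg2$detection_floor <- cfg$a + cfg$K + 1
  expect_equal(nrow(emit_rss(trk, nodes, cfg2)), 0)
})

test_that("dense vegetation thins ground-level detections", {
  cfg <- scene_config(n_rows = 5, n_cols = 5, noise_sd = 0,
                      veg_attenuation = c(grassland = 0, paramo = 0,
                                          dense = 10, builtup = 0),
                      detection_floor = -103, seed = 9)
  nodes <- make_grid(cfg)
  veg_dense <- make_vegetation(nodes, cellsize = 50)
  veg_dense$values[] <- 3  # everything dense
  veg_open <- veg_dense
  veg_open$values[] <- 1
  trk <- simulate_track(nodes, "ground", duration = 160, fix_interval = 4,
                        seed = 10)
  det_open <- emit_rss(trk, nodes, cfg, veg = veg_open)
  det_dense <- emit_rss(trk, nodes, cfg, veg = veg_dense)
  per_fix_open <- nrow(det_open)
  per_fix_dense <- nrow(det_dense)
  expect_lt(per_fix_dense, per_fix_open)
})

test_that("ground-mode flight height closes the loop through covariates", {
  sc <- make_test_scene(seed = 12, n_trials = 2, with_landscape = TRUE)
  # trial 1 flies at 39 m agl, trial 2 walks at ground level; the
  # covariate op should recover both heights from GPS minus DEM
  cov1 <- spatial_covariates(sc$tracks[[1]], sc$dem, sc$veg, sc$nodes)
  cov2 <- spatial_covariates(sc$tracks[[2]], sc$dem, sc$veg, sc$nodes)
  expect_lt(abs(median(cov1$flight_height) - 39), 2)
  expect_lt(abs(median(cov2$flight_height)), 2)
})
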