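# Distance inversion, node selection, multilateration and the grouped
# k-means consensus method.

test_that("distance inversion honours the asymptote and clamping rules", {
  m <- structure(list(a = 68, S = 0.01, K = -105), class = "decay_model")
  # rss = a + K is exactly zero distance
  expect_equal(invert_distance(-37, m), 0)
  # forward check at ~100 m
  d <- invert_distance(-80, m)
  expect_equal(68 * exp(-0.01 * d) - 105, -80, tolerance = 1e-9)
  expect_equal(d, 100.06, tolerance = 1e-3)
  # at/below the asymptote the read is excluded
  m2 <- structure(list(a = 68, S = 0.01, K = -103), class = "decay_model")
  expect_true(is.na(invert_distance(-103, m2)))
  expect_true(is.na(invert_distance(-110, m2)))
  # stronger than the zero-distance prediction clamps to 0
  expect_equal(invert_distance(-30, m), 0)
})

test_that("node selection sorts, enforces the 3-node floor and breaks ties", {
  est <- data.frame(node_id = paste0("N", 1:5),
                    rss_used = c(-80, -85, -90, -95, -100),
                    d_hat = c(50, 120, 80, 200, 300))
  s3 <- select_nodes(est, "strongest3")
  expect_equal(s3$node_id, c("N1", "N2", "N3"))
  n3 <- select_nodes(est, "nearest3")
  expect_equal(sort(n3$node_id), c("N1", "N2", "N3"))
  expect_equal(n3$d_hat, c(50, 80, 120))

  # exactly 3 valid nodes: every rule returns the same subset
  est3 <- est[1:3, ]
  for (r in c("all", "strongest3", "nearest3"))
    expect_equal(sort(select_nodes(est3, r)$node_id), sort(est3$node_id))

  # boundary tie broken by node_id, counted
  estt <- data.frame(node_id = c("N1", "N2", "N4", "N3"),
                     rss_used = c(-80, -82, -85, -85),
                     d_hat = c(10, 20, 30, 40))
  st <- select_nodes(estt, "strongest3")
  expect_equal(st$node_id[3], "N3")
  expect_equal(attr(st, "ties_broken"), 1L)

  expect_null(select_nodes(est[1:2, ], "all"))
})

test_that("multilateration solves exact and biased geometries", {
  nx <- c(0, 100, 0); ny <- c(0, 0, 100)
  d <- sqrt((30 - nx)^2 + (40 - ny)^2)
  expect_equal(d, c(50, sqrt(6500), sqrt(4500)))
  sub <- data.frame(node_id = c("A", "B", "C"), d_hat = d, x = nx, y = ny)
  p <- multilaterate(sub)
  expect_lt(sqrt((p$x_hat - 30)^2 + (p$y_hat - 40)^2), 0.5)
  expect_true(p$converged)
  # brute-force oracle agrees
  po <- grid_oracle(nx, ny, d, pad = 50, res = 1)
  expect_lt(sqrt((p$x_hat - po[1])^2 + (p$y_hat - po[2])^2), 1.5)

  # equilateral layout: exact centroid distances return the centroid
  ang <- c(90, 210, 330) * pi / 180
  ex <- 100 * cos(ang); ey <- 100 * sin(ang)
  sub_eq <- data.frame(node_id = c("A", "B", "C"), d_hat = rep(100, 3),
                       x = ex, y = ey)
  pe <- multilaterate(sub_eq)
  expect_lt(abs(pe$x_hat), 1e-3)
  expect_lt(abs(pe$y_hat), 1e-3)

  # symmetric +50 m bias cancels at the centroid
  sub_b <- sub_eq
  sub_b$d_hat <- sub_b$d_hat + 50
  pb <- multilaterate(sub_b)
  expect_lt(sqrt(pb$x_hat^2 + pb$y_hat^2), 1)

  # collinear subsets are attempted but flagged
  sub_c <- data.frame(node_id = c("A", "B", "C"), d_hat = c(10, 10, 20),
                      x = c(0, 20, 40), y = c(0, 0, 0))
  pc <- multilaterate(sub_c)
  expect_true(pc$collinear)
  expect_true(is.finite(pc$x_hat))
})

test_that("grouped consensus enumerates 99 subsets of 7 nodes", {
  set.seed(31)
  truth <- c(70, 95)
  nx <- c(0, 150, 300, 0, 150, 300, 0)
  ny <- c(0, 0, 0, 150, 150, 150, 300)
  d <- sqrt((truth[1] - nx)^2 + (truth[2] - ny)^2)
  est <- data.frame(node_id = sprintf("N%d", 1:7),
                    rss_used = 68 * exp(-0.01 * d) - 105, d_hat = d,
                    x = nx, y = ny)
  g <- grouped_kmeans_localise(est, seed = 4)
  expect_equal(g$diagnostics$n_candidates,
               sum(choose(7, 3:7)))  # 35+35+21+7+1 = 99
  expect_equal(sum(g$diagnostics$cluster_sizes), 99L)
  expect_lt(sqrt((g$x_hat - truth[1])^2 + (g$y_hat - truth[2])^2), 1)

  # exactly 3 nodes: single candidate, identical to plain multilateration
  e3 <- est[1:3, ]
  g3 <- grouped_kmeans_localise(e3, seed = 4)
  m3 <- multilaterate(e3)
  expect_equal(g3$diagnostics$n_candidates, 1L)
  expect_equal(c(g3$x_hat, g3$y_hat), c(m3$x_hat, m3$y_hat),
               tolerance = 1e-9)
})

test_that("consensus beats all-node multilateration under single-node corruption", {
  nx <- c(0, 150, 300, 0, 150, 300, 0)
  ny <- c(0, 0, 0, 150, 150, 150, 300)
  mdl <- structure(list(a = 68, S = 0.01, K = -105), class = "decay_model")
  wins <- 0L
  n_rep <- 50
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    truth <- runif(2, 50, 250)
    d <- sqrt((truth[1] - nx)^2 + (truth[2] - ny)^2)
    rss <- 68 * exp(-0.01 * d) - 105 + rnorm(7, 0, 0.5)
    # corrupt the strongest node so the bad read stays above the
    # asymptote and keeps contaminating candidate subsets
    bad <- which.max(rss)
    rss[bad] <- rss[bad] - 20
    dh <- invert_distance(rss, mdl)
    est <- data.frame(node_id = sprintf("N%d", 1:7), rss_used = rss,
                      d_hat = dh, x = nx, y = ny)
    est <- est[is.finite(est$d_hat), ]
    if (nrow(est) < 3) next
    pa <- multilaterate(est)
    pg <- grouped_kmeans_localise(est, seed = r)
    ea <- sqrt((pa$x_hat - truth[1])^2 + (pa$y_hat - truth[2])^2)
    eg <- sqrt((pg$x_hat - truth[1])^2 + (pg$y_hat - truth[2])^2)
    if (eg < ea) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.7)
})

test_that("localisation error shrinks as RSS noise vanishes", {
  meds <- vapply(c(4, 2, 1, 0), function(sd) {
    sc <- make_test_scene(noise_sd = sd, seed = 21, n_trials = 1)
    obs <- prep_observations(sc$detections[[1]], sc$tracks[[1]],
                             trial_id = names(sc$tracks)[1])
    pts <- calibration_points(obs, sc$tracks[[1]], sc$nodes, "max")
    m <- fit_decay(pts)
    est <- localise_trial(obs, sc$nodes, m, "all_nodes", "max")
    median(compute_error(est, sc$tracks[[1]])$error_m)
  }, numeric(1))
  expect_true(all(diff(meds) <= 0))
})
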