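# Synthetic ARTS scenes: node grids, landscape rasters, trial tracks and
# RSS detections generated from a known decay law, so every pipeline
# stage can be exercised and validated without field data.

#' Configure a synthetic scene
#'
#' Defaults emulate the study grid conditions: ~150 m node spacing, decay
#' truth near the calibrated curve (a = 68, S = 0.01 /m, K = -105 dB), a
#' -115 dB detection floor, and optional per-node offsets, vegetation
#' attenuation and AR(1) noise. All randomness flows from `seed` through
#' named substreams (grid/track/noise) so each stage is independently
#' reproducible; the noise substream draws standard innovations that are
#' scaled by `noise_sd`, so scenes differing only in `noise_sd` share the
#' same noise shape.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param spacing node spacing in metres (default 150).
#' @param a,S,K decay-law truth (dB, 1/m, dB).
#' @param node_offset_sd sd of per-node dB offsets (default 0).
#' @param noise_sd sd of the AR(1) observation noise in dB (default 0).
#' @param noise_ar1 lag-1 correlation of the noise (default 0.6).
#' @param veg_attenuation named dB penalties per vegetation class.
#' @param detection_floor reads below this are never emitted (default
#'   -115 dB).
#' @param origin_lon,origin_lat grid south-west anchor (default a
#'   high-Andean paramo valley).
#' @param seed scene seed.
#' @return a `scene_config` list.
#' @export
scene_config <- function(n_rows = 7, n_cols = 7, spacing = 150,
                         a = 68, S = 0.01, K = -105,
                         node_offset_sd = 0, noise_sd = 0, noise_ar1 = 0.6,
                         veg_attenuation = c(grassland = 0, paramo = 2,
                                             dense = 10, builtup = 5),
                         detection_floor = -115,
                         origin_lon = -73.773, origin_lat = 4.525,
                         seed = 1) {
  stopifnot(spacing > 0, noise_sd >= 0, noise_ar1 >= 0, noise_ar1 < 1,
            detection_floor < K + a)
  structure(list(n_rows = n_rows, n_cols = n_cols, spacing = spacing,
                 a = a, S = S, K = K, node_offset_sd = node_offset_sd,
                 noise_sd = noise_sd, noise_ar1 = noise_ar1,
                 veg_attenuation = veg_attenuation,
                 detection_floor = detection_floor,
                 origin_lon = origin_lon, origin_lat = origin_lat,
                 seed = seed),
            class = "scene_config")
}

# substream seeds derived from the scene seed; kept below 2^31
.sub_seed <- function(seed, stream) {
  offs <- c(grid = 101L, track = 211L, noise = 307L, misc = 401L)
  (as.integer(seed) * 7919L + offs[[stream]]) %% 2147483629L
}

#' Generate a rectangular node grid
#'
#' Lays nodes on a regular lattice at the given spacing in the working
#' CRS, anchored at the scene origin, and assigns lon/lat by inverse
#' projection. A dropout list emulates failed nodes (e.g. a 7x7 lattice
#' with 3 dropouts reproduces a 46-node grid).
#'
#' @param config a [scene_config()].
#' @param dropout character vector of node ids to remove.
#' @return node registry data.frame as from [read_nodes()].
#' @export
make_grid <- function(config, dropout = character(0)) {
  stopifnot(config$n_rows * config$n_cols >= 4)
  crs <- select_crs(config$origin_lon, config$origin_lat)
  o <- project_coordinates(config$origin_lon, config$origin_lat, crs)
  g <- expand.grid(row = seq_len(config$n_rows), col = seq_len(config$n_cols))
  x <- o$x + (g$col - 1) * config$spacing
  y <- o$y + (g$row - 1) * config$spacing
  id <- sprintf("N%02d%02d", g$row, g$col)
  keep <- !(id %in% dropout)
  ll <- unproject_coordinates(x[keep], y[keep], crs)
  nodes <- data.frame(node_id = id[keep], lon = ll$lon, lat = ll$lat,
                      x = x[keep], y = y[keep], height_agl = 2.5,
                      stringsAsFactors = FALSE)
  attr(nodes, "crs") <- crs
  nodes
}

#' Generate a smooth synthetic DEM over the grid
#'
#' A gently undulating surface (plane plus long-wavelength sinusoids)
#' emulating a high-Andean valley floor; amplitude and base elevation are
#' configurable. Covers the node bounding box plus `pad` metres at
#' `cellsize` resolution.
#'
#' @param nodes node registry.
#' @param cellsize cell size in metres (default 30, GLO-30-like).
#' @param pad margin beyond the node bounding box (default 300 m).
#' @param base base elevation in metres asl (default 3250).
#' @param relief sinusoid amplitude in metres (default 40).
#' @return a [grid_raster()] of elevations.
#' @export
make_dem <- function(nodes, cellsize = 30, pad = 300, base = 3250,
                     relief = 40) {
  xr <- range(nodes$x) + c(-pad, pad)
  yr <- range(nodes$y) + c(-pad, pad)
  nc <- ceiling(diff(xr) / cellsize)
  nr <- ceiling(diff(yr) / cellsize)
  cx <- xr[1] + (seq_len(nc) - 0.5) * cellsize
  cy <- yr[1] + (nr - seq_len(nr) + 0.5) * cellsize
  wl <- max(diff(xr), diff(yr)) / 2
  m <- outer(cy, cx, function(y, x)
    base + relief * sin(2 * pi * x / wl) * cos(2 * pi * y / wl) +
      (x - xr[1]) * 0.02)
  grid_raster(m, xr[1], yr[1], cellsize)
}

#' Generate a blocky vegetation class raster
#'
#' Splits the scene into vertical bands of the four classes (grassland,
#' paramo, dense, builtup as codes 1-4); a crude stand-in for digitised
#' polygons, sufficient to exercise attenuation and covariate logic.
#'
#' @param nodes node registry.
#' @param cellsize cell size in metres (default 5; 1 m mirrors digitised
#'   polygons but costs memory at full-scene extents).
#' @param pad margin beyond the node bounding box (default 300 m).
#' @return a [grid_raster()] of class codes 1-4.
#' @export
make_vegetation <- function(nodes, cellsize = 5, pad = 300) {
  xr <- range(nodes$x) + c(-pad, pad)
  yr <- range(nodes$y) + c(-pad, pad)
  nc <- ceiling(diff(xr) / cellsize)
  nr <- ceiling(diff(yr) / cellsize)
  cx <- xr[1] + (seq_len(nc) - 0.5) * cellsize
  band <- pmin(pmax(ceiling(4 * (cx - xr[1]) / diff(xr)), 1), 4)
  m <- matrix(band, nr, nc, byrow = TRUE)
  grid_raster(m, xr[1], yr[1], cellsize)
}

#' Simulate a trial track
#'
#' Correlated random walk inside the node bounding box with reflective
#' boundaries: lognormal step lengths matched to the trial's mean speed,
#' wrapped-normal turning angles, fixes every `fix_interval` seconds.
#' Elevation is the DEM surface plus the mode-specific height above
#' ground (high flight ~39 m, low flight 1 m, ground 0 m).
#'
#' @param nodes node registry (bounding box of the walk).
#' @param mode `"high_flight"`, `"low_flight"` or `"ground"`.
#' @param duration trial duration in seconds.
#' @param fix_interval seconds between fixes.
#' @param speed_mean mean speed in m/s; defaults per mode to the drone /
#'   mid-level / ground trial speeds (3.57, 0.44, 0.31 m/s).
#' @param dem optional [grid_raster()] DEM for elevations.
#' @param trial_id identifier.
#' @param t0 start time (POSIXct, default a fixed instant).
#' @param seed RNG seed.
#' @return relocation data.frame as from [read_truth_track()].
#' @export
simulate_track <- function(nodes, mode = c("high_flight", "low_flight",
                                           "ground"),
                           duration = 300, fix_interval = 2,
                           speed_mean = NULL, dem = NULL,
                           trial_id = "trial",
                           t0 = as.POSIXct("2026-01-15 12:00:00", tz = "UTC"),
                           seed = 1) {
  mode <- match.arg(mode)
  stopifnot(duration >= 10 * fix_interval)
  if (is.null(speed_mean))
    speed_mean <- switch(mode, high_flight = 3.57, low_flight = 0.44,
                         ground = 0.31)
  agl <- switch(mode, high_flight = 39, low_flight = 1, ground = 0)
  set.seed(seed)
  xr <- range(nodes$x); yr <- range(nodes$y)
  n <- floor(duration / fix_interval) + 1
  # lognormal step lengths with mean speed_mean * fix_interval, cv 0.5
  mu_step <- speed_mean * fix_interval
  sdlog <- sqrt(log(1 + 0.25))
  meanlog <- log(mu_step) - sdlog^2 / 2
  steps <- stats::rlnorm(n - 1, meanlog, sdlog)
  turns <- stats::rnorm(n - 1, 0, 0.6)
  heading <- stats::runif(1, 0, 2 * pi)
  x <- numeric(n); y <- numeric(n)
  x[1] <- stats::runif(1, xr[1] + 0.2 * diff(xr), xr[2] - 0.2 * diff(xr))
  y[1] <- stats::runif(1, yr[1] + 0.2 * diff(yr), yr[2] - 0.2 * diff(yr))
  for (k in 2:n) {
    heading <- heading + turns[k - 1]
    nx <- x[k - 1] + steps[k - 1] * cos(heading)
    ny <- y[k - 1] + steps[k - 1] * sin(heading)
    if (nx < xr[1] || nx > xr[2]) {
      heading <- pi - heading
      nx <- min(max(nx, 2 * xr[1] - nx), 2 * xr[2] - nx)
      nx <- min(max(nx, xr[1]), xr[2])
    }
    if (ny < yr[1] || ny > yr[2]) {
      heading <- -heading
      ny <- min(max(ny, 2 * yr[1] - ny), 2 * yr[2] - ny)
      ny <- min(max(ny, yr[1]), yr[2])
    }
    x[k] <- nx; y[k] <- ny
  }
  ground <- if (is.null(dem)) rep(0, n) else raster_bilinear(dem, x, y)
  out <- data.frame(trial_id = trial_id, reloc_idx = seq_len(n),
                    timestamp = t0 + (seq_len(n) - 1) * fix_interval,
                    x = x, y = y, elevation_gps = ground + agl, mode = mode,
                    stringsAsFactors = FALSE)
  attr(out, "crs") <- attr(nodes, "crs")
  out
}

.veg_class_at <- function(veg, x, y) {
  if (is.null(veg)) return(rep(1L, length(x)))
  cs <- veg$cellsize
  nr <- nrow(veg$values); nc <- ncol(veg$values)
  j <- pmin(pmax(ceiling((x - veg$xll) / cs), 1), nc)
  i <- pmin(pmax(nr - ceiling((y - veg$yll) / cs) + 1, 1), nr)
  as.integer(veg$values[cbind(i, j)])
}

#' Emit synthetic detections along a track
#'
#' At every tag emission time (the tag's nominal interval), each node
#' receives `rss = a exp(-S d) + K + node_offset + veg_penalty + noise`
#' where the noise is AR(1) per node (standard innovations scaled by
#' `noise_sd`) and the vegetation penalty is taken from the class at the
#' emitter position. Reads below the detection floor are never emitted —
#' the censoring mechanism of a real grid. Emission timestamps are
#' jittered by up to 1 s to exercise the time matching.
#'
#' @param track relocation data.frame (truth positions).
#' @param nodes node registry.
#' @param config a [scene_config()].
#' @param veg optional vegetation class raster.
#' @param tag_id tag identifier.
#' @param nominal_interval emission interval in seconds (2 for solar
#'   tags, 60 for battery tags).
#' @param seed RNG seed (defaults to the scene's noise substream).
#' @return detection data.frame in the canonical schema.
#' @export
emit_rss <- function(track, nodes, config, veg = NULL, tag_id = "T01",
                     nominal_interval = 2,
                     seed = .sub_seed(config$seed, "noise")) {
  tt <- as.numeric(track$timestamp)
  t_emit <- seq(tt[1], tt[length(tt)], by = nominal_interval)
  ex <- stats::approx(tt, track$x, xout = t_emit)$y
  ey <- stats::approx(tt, track$y, xout = t_emit)$y
  set.seed(seed)
  n_nodes <- nrow(nodes)
  offsets <- if (config$node_offset_sd > 0)
    stats::rnorm(n_nodes, 0, config$node_offset_sd) else rep(0, n_nodes)
  veg_cls <- .veg_class_at(veg, ex, ey)
  veg_pen <- unname(config$veg_attenuation[veg_cls])
  veg_pen[is.na(veg_pen)] <- 0
  jit <- stats::runif(length(t_emit), 0, 1)
  # standard AR(1) innovations per node, scaled by noise_sd afterwards
  rho <- config$noise_ar1
  eps_std <- matrix(stats::rnorm(length(t_emit) * n_nodes), length(t_emit))
  if (rho > 0 && length(t_emit) > 1) {
    for (k in 2:length(t_emit))
      eps_std[k, ] <- rho * eps_std[k - 1, ] +
        sqrt(1 - rho^2) * eps_std[k, ]
  }
  rows <- vector("list", n_nodes)
  for (j in seq_len(n_nodes)) {
    d <- sqrt((ex - nodes$x[j])^2 + (ey - nodes$y[j])^2)
    rss <- config$a * exp(-config$S * d) + config$K + offsets[j] -
      veg_pen + config$noise_sd * eps_std[, j]
    keep <- rss >= config$detection_floor
    if (!any(keep)) next
    rows[[j]] <- data.frame(
      tag_id = tag_id, node_id = nodes$node_id[j],
      timestamp_utc = as.POSIXct(t_emit[keep] + jit[keep],
                                 origin = "1970-01-01", tz = "UTC"),
      rss_db = rss[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(tag_id = character(0), node_id = character(0),
                      timestamp_utc = as.POSIXct(character(0), tz = "UTC"),
                      rss_db = numeric(0))
  rownames(out) <- NULL
  out[order(out$timestamp_utc, out$node_id), , drop = FALSE]
}

#' Simulate a complete scene
#'
#' Bundles grid, landscape, trial tracks and detections: the one-call
#' generator used by the tests and the acceptance script.
#'
#' @param config a [scene_config()].
#' @param trials data.frame with columns `trial_id, mode, duration,
#'   fix_interval, tag_id, nominal_interval` (one row per trial); a
#'   default of three trials (one per mode) is used when `NULL`.
#' @param dropout node ids to drop from the lattice.
#' @param with_landscape generate DEM and vegetation rasters (default
#'   TRUE).
#' @return an `arts_scene` list: `config, nodes, dem, veg, tracks (list),
#'   detections (list), tag_ids (named by trial)`.
#' @export
simulate_scene <- function(config = scene_config(), trials = NULL,
                           dropout = character(0), with_landscape = TRUE) {
  if (is.null(trials)) {
    trials <- data.frame(
      trial_id = c("high1", "low1", "ground1"),
      mode = c("high_flight", "low_flight", "ground"),
      duration = c(300, 260, 300), fix_interval = c(2, 3, 3),
      tag_id = c("T01", "T02", "T03"),
      nominal_interval = c(2, 2, 2), stringsAsFactors = FALSE)
  }
  nodes <- make_grid(config, dropout = dropout)
  dem <- if (with_landscape) make_dem(nodes) else NULL
  veg <- if (with_landscape) make_vegetation(nodes) else NULL
  tracks <- list(); dets <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    trk <- simulate_track(nodes, mode = tr$mode, duration = tr$duration,
                          fix_interval = tr$fix_interval, dem = dem,
                          trial_id = tr$trial_id,
                          t0 = as.POSIXct("2026-01-15 12:00:00", tz = "UTC") +
                            (i - 1) * 86400,
                          seed = .sub_seed(config$seed, "track") + i)
    det <- emit_rss(trk, nodes, config, veg = veg, tag_id = tr$tag_id,
                    nominal_interval = tr$nominal_interval,
                    seed = .sub_seed(config$seed, "noise") + i)
    tracks[[tr$trial_id]] <- trk
    dets[[tr$trial_id]] <- det
  }
  structure(list(config = config, nodes = nodes, dem = dem, veg = veg,
                 tracks = tracks, detections = dets,
                 tag_ids = stats::setNames(trials$tag_id, trials$trial_id)),
            class = "arts_scene")
}

#' @export
print.arts_scene <- function(x, ...) {
  cat("arts_scene: ", nrow(x$nodes), " nodes, ", length(x$tracks),
      " trial(s), noise sd ", x$config$noise_sd, " dB\n", sep = "")
  invisible(x)
}
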