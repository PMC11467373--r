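# Error evaluation across the workflow factorial, random-track null
# comparisons, and spatial covariates of error.

#' Localisation error against ground truth
#'
#' Planar Euclidean distance (metres, working CRS) between estimated and
#' true positions, joined on (trial_id, reloc_idx).
#'
#' @param estimates data.frame from [localise_trial()].
#' @param truth relocation data.frame.
#' @return `estimates` with an added `error_m` column (rows without a
#'   matching truth relocation are dropped).
#' @export
compute_error <- function(estimates, truth) {
  key_e <- paste(estimates$trial_id, estimates$reloc_idx)
  key_t <- paste(truth$trial_id, truth$reloc_idx)
  it <- match(key_e, key_t)
  ok <- !is.na(it)
  out <- estimates[ok, , drop = FALSE]
  out$error_m <- sqrt((out$x_hat - truth$x[it[ok]])^2 +
                      (out$y_hat - truth$y[it[ok]])^2)
  out
}

#' Enumerate the workflow factorial
#'
#' The five decision axes — RSS type (max/avg), signal smoothing
#' (none/spline/kalman), decay-model scope (general/node/tag),
#' localisation method (all_nodes/strongest3/nearest3/grouped_kmeans) and
#' track smoothing (none/spline/kalman) — give 2 x 3 x 3 x 4 x 3 = 216
#' workflows.
#'
#' @return data.frame of 216 rows with columns `rss_type,signal_smoother,
#'   scope,method,track_smoother`.
#' @export
enumerate_workflows <- function() {
  out <- expand.grid(
    rss_type = c("max", "avg"),
    signal_smoother = c("none", "spline", "kalman"),
    scope = c("general", "node", "tag"),
    method = c("all_nodes", "strongest3", "nearest3", "grouped_kmeans"),
    track_smoother = c("none", "spline", "kalman"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out[do.call(order, unname(as.list(out))), , drop = FALSE]
}

# smooth the rss_max/rss_avg series of one trial's observation table,
# per node, at the relocation timestamps
.smooth_observations <- function(obs, track, method, step = NULL) {
  if (method == "none" || !nrow(obs)) return(obs)
  tt <- as.numeric(track$timestamp)[match(obs$reloc_idx, track$reloc_idx)]
  if (is.null(step))
    step <- max(stats::median(diff(sort(unique(tt)))), 1e-6)
  for (nid in unique(obs$node_id)) {
    sel <- which(obs$node_id == nid)
    sel <- sel[order(tt[sel])]
    if (length(sel) < 2) next
    for (col in c("rss_max", "rss_avg")) {
      s <- gl_series(tt[sel], obs[[col]][sel])
      obs[[col]][sel] <- smooth_series(s, method, step = step,
                                       collision = "max")$values
    }
  }
  obs
}

#' Run the full workflow factorial over a scene
#'
#' Executes every workflow combination end to end on prepared
#' observations: per-workflow signal smoothing, decay calibration at all
#' three scopes, localisation by all four methods, track smoothing, and
#' error against truth. Emits the long error table used for downstream
#' (external) mixed-model analysis, one row per (relocation x workflow)
#' that yielded an estimate.
#'
#' @param scene an `arts_scene` from [simulate_scene()], or a list with
#'   the same `nodes`, `tracks`, `detections`, `tag_ids` elements built
#'   from field files.
#' @param workflows subset of [enumerate_workflows()] to run (default
#'   all 216).
#' @param max_gap,outlier_db signal-prep parameters.
#' @param min_group_points minimum points for per-group decay refits.
#' @param seed RNG seed (consensus clustering).
#' @return list `errors` (long data.frame `trial_id,reloc_idx,rss_type,
#'   signal_smoother,scope,method,track_smoother,error_m`), `models`
#'   (nested list of fitted decay models), `absent` (workflow rows that
#'   produced no estimate, flagged not dropped).
#' @export
run_workflows <- function(scene, workflows = enumerate_workflows(),
                          max_gap = 10, outlier_db = 4.33,
                          min_group_points = 10, seed = 1) {
  nodes <- scene$nodes
  trial_ids <- names(scene$tracks)
  obs0 <- lapply(trial_ids, function(tid)
    prep_observations(scene$detections[[tid]], scene$tracks[[tid]],
                      max_gap = max_gap, outlier_db = outlier_db,
                      trial_id = tid))
  names(obs0) <- trial_ids

  smoothers <- unique(workflows$signal_smoother)
  obs_sm <- list()
  for (sm in smoothers) {
    obs_sm[[sm]] <- lapply(trial_ids, function(tid)
      .smooth_observations(obs0[[tid]], scene$tracks[[tid]], sm))
    names(obs_sm[[sm]]) <- trial_ids
  }

  truth_all <- do.call(rbind, scene$tracks)
  models <- list()
  loc_cache <- list()
  err_rows <- list()
  absent <- list()

  cells <- unique(workflows[c("rss_type", "signal_smoother", "scope",
                              "method")])
  for (ci in seq_len(nrow(cells))) {
    cl <- cells[ci, ]
    obs_list <- obs_sm[[cl$signal_smoother]]
    calib_key <- paste(cl$rss_type, cl$signal_smoother)
    if (is.null(models[[calib_key]])) {
      pts <- calibration_points(do.call(rbind, obs_list), truth_all, nodes,
                                rss_type = cl$rss_type,
                                tag_ids = scene$tag_ids)
      general <- fit_decay(pts)
      models[[calib_key]] <- list(
        general = general,
        node = refit_by_group(pts, "node_id", general,
                              min_points = min_group_points),
        tag = refit_by_group(pts, "tag_id", general,
                             min_points = min_group_points))
    }
    mset <- models[[calib_key]]
    mdl <- switch(cl$scope, general = mset$general, node = mset$node,
                  tag = mset$tag)
    est <- do.call(rbind, lapply(trial_ids, function(tid)
      localise_trial(obs_list[[tid]], nodes, mdl, method = cl$method,
                     rss_type = cl$rss_type,
                     tag_id = scene$tag_ids[[tid]], seed = seed)))
    loc_cache[[paste(calib_key, cl$scope, cl$method)]] <- est
  }

  for (wi in seq_len(nrow(workflows))) {
    w <- workflows[wi, ]
    est <- loc_cache[[paste(w$rss_type, w$signal_smoother, w$scope,
                            w$method)]]
    if (is.null(est) || nrow(est) == 0) {
      absent[[length(absent) + 1]] <- w
      next
    }
    est_s <- est
    if (w$track_smoother != "none") {
      parts <- lapply(split(est, est$trial_id), function(e) {
        e <- e[order(e$reloc_idx), , drop = FALSE]
        tt <- scene$tracks[[e$trial_id[1]]]
        e$timestamp <- tt$timestamp[match(e$reloc_idx, tt$reloc_idx)]
        e2 <- e
        sm2 <- smooth_track(data.frame(timestamp = e$timestamp,
                                       x = e$x_hat, y = e$y_hat),
                            w$track_smoother)
        e2$x_hat <- sm2$x; e2$y_hat <- sm2$y
        e2$timestamp <- NULL
        e2
      })
      est_s <- do.call(rbind, parts)
    }
    ee <- compute_error(est_s, truth_all)
    if (!nrow(ee)) {
      absent[[length(absent) + 1]] <- w
      next
    }
    err_rows[[wi]] <- data.frame(
      trial_id = ee$trial_id, reloc_idx = ee$reloc_idx,
      rss_type = w$rss_type, signal_smoother = w$signal_smoother,
      scope = w$scope, method = w$method, track_smoother = w$track_smoother,
      error_m = ee$error_m, stringsAsFactors = FALSE)
  }
  list(errors = do.call(rbind, err_rows), models = models,
       absent = if (length(absent)) do.call(rbind, absent) else NULL)
}

# step-resampling surrogate of one trial: resample step lengths and
# turning angles with replacement, start at the trial centroid
.surrogate_track <- function(track, bbox) {
  n <- nrow(track)
  dx <- diff(track$x); dy <- diff(track$y)
  steps <- sqrt(dx^2 + dy^2)
  abs_ang <- atan2(dy, dx)
  turns <- diff(abs_ang)
  s <- sample(steps, n - 1, replace = TRUE)
  tu <- if (length(turns)) sample(turns, n - 1, replace = TRUE)
        else rep(0, n - 1)
  h <- stats::runif(1, 0, 2 * pi)
  x <- numeric(n); y <- numeric(n)
  x[1] <- mean(track$x); y[1] <- mean(track$y)
  for (k in 2:n) {
    h <- h + tu[k - 1]
    x[k] <- min(max(x[k - 1] + s[k - 1] * cos(h), bbox[1]), bbox[2])
    y[k] <- min(max(y[k - 1] + s[k - 1] * sin(h), bbox[3]), bbox[4])
  }
  data.frame(timestamp = track$timestamp, x = x, y = y)
}

#' Random-track null comparison
#'
#' Generates step-resampling surrogate tracks per trial (same duration,
#' fix count and step-speed distribution as the trial; start at the trial
#' centroid; clipped to the node bounding box padded 500 m) and compares
#' the observed localisation errors to the errors a random process would
#' produce: the distance from each true relocation to the time-matched
#' surrogate point. Per-trial observed median error is paired with the
#' mean of the surrogate medians in a Wilcoxon signed-rank test.
#'
#' @param tracks list of relocation data.frames (>= 10 fixes each;
#'   shorter trials are excluded with a message).
#' @param errors long error data.frame with `trial_id` and `error_m`
#'   (a single workflow's rows).
#' @param nodes node registry (for the clipping box).
#' @param n_sims surrogates per trial (default 99).
#' @param seed RNG seed.
#' @param pad clip-box padding in metres (default 500).
#' @return list `per_trial` (data.frame `trial_id, observed_median,
#'   surrogate_median`), `test` (the `htest`, or NULL if degenerate),
#'   `p_value`, `degenerate` flag, `n_sims`.
#' @export
random_track_null <- function(tracks, errors, nodes, n_sims = 99, seed = 1,
                              pad = 500) {
  set.seed(seed)
  bbox <- c(min(nodes$x) - pad, max(nodes$x) + pad,
            min(nodes$y) - pad, max(nodes$y) + pad)
  rows <- list()
  for (trk in tracks) {
    tid <- trk$trial_id[1]
    if (nrow(trk) < 10) {
      message("trial ", tid, " has < 10 fixes; excluded from null")
      next
    }
    obs_err <- errors$error_m[errors$trial_id == tid]
    if (!length(obs_err)) next
    med_sur <- numeric(n_sims)
    for (s in seq_len(n_sims)) {
      sur <- .surrogate_track(trk, bbox)
      med_sur[s] <- stats::median(sqrt((trk$x - sur$x)^2 +
                                       (trk$y - sur$y)^2))
    }
    rows[[length(rows) + 1]] <- data.frame(
      trial_id = tid, observed_median = stats::median(obs_err),
      surrogate_median = mean(med_sur), stringsAsFactors = FALSE)
  }
  per_trial <- do.call(rbind, rows)
  degenerate <- is.null(per_trial) ||
    all(per_trial$observed_median == per_trial$surrogate_median)
  test <- NULL; p <- NA_real_
  if (!degenerate && nrow(per_trial) >= 2) {
    test <- stats::wilcox.test(per_trial$observed_median,
                               per_trial$surrogate_median, paired = TRUE,
                               exact = TRUE)
    p <- test$p.value
  }
  list(per_trial = per_trial, test = test, p_value = p,
       degenerate = degenerate, n_sims = n_sims)
}

# signed distance to the convex hull of the nodes: positive inside
.hull_signed_distance <- function(x, y, nodes) {
  h <- grDevices::chull(nodes$x, nodes$y)
  hx <- nodes$x[h]; hy <- nodes$y[h]
  n <- length(hx)
  inside <- .point_in_poly(x, y, cbind(hx, hy))
  dmin <- rep(Inf, length(x))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1 else k + 1
    ex <- hx[k2] - hx[k]; ey <- hy[k2] - hy[k]
    L2 <- ex^2 + ey^2
    t <- pmin(pmax(((x - hx[k]) * ex + (y - hy[k]) * ey) / L2, 0), 1)
    d <- sqrt((x - hx[k] - t * ex)^2 + (y - hy[k] - t * ey)^2)
    dmin <- pmin(dmin, d)
  }
  ifelse(inside, dmin, -dmin)
}

#' Spatial covariates of relocations
#'
#' For each relocation: terrain ruggedness (sd of DEM cells whose centres
#' fall within 100 m), flight height (GPS elevation minus bilinear DEM),
#' dominant vegetation class within 100 m (ties broken in the declared
#' order grassland > paramo > dense > builtup), grid membership
#' (point-in-convex-hull of the nodes) and signed distance to the hull
#' edge (negative outside).
#'
#' @param relocs relocation data.frame.
#' @param dem DEM [grid_raster()].
#' @param veg vegetation class [grid_raster()] (codes 1-4).
#' @param nodes node registry.
#' @param radius buffer radius in metres (default 100).
#' @return data.frame `trial_id,reloc_idx,ruggedness,flight_height,
#'   veg_class,inside_grid,dist_to_edge`; covariates are `NA` (with a
#'   message) where the DEM does not cover the point.
#' @export
spatial_covariates <- function(relocs, dem, veg, nodes, radius = 100) {
  classes <- c("grassland", "paramo", "dense", "builtup")
  n <- nrow(relocs)
  rug <- numeric(n); fh <- numeric(n); vc <- character(n)
  ground <- raster_bilinear(dem, relocs$x, relocs$y)
  for (i in seq_len(n)) {
    cells <- raster_values_in_radius(dem, relocs$x[i], relocs$y[i], radius)
    rug[i] <- if (length(cells) > 1) stats::sd(cells) else
      if (length(cells) == 1) 0 else NA_real_
    if (!length(cells))
      message("relocation ", relocs$reloc_idx[i],
              ": DEM does not cover the buffer")
    fh[i] <- relocs$elevation_gps[i] - ground[i]
    vcells <- raster_values_in_radius(veg, relocs$x[i], relocs$y[i], radius)
    if (length(vcells)) {
      counts <- tabulate(vcells, nbins = 4)
      vc[i] <- classes[which.max(counts)]  # which.max = first max: tie order
    } else {
      vc[i] <- NA_character_
    }
  }
  sd_edge <- .hull_signed_distance(relocs$x, relocs$y, nodes)
  data.frame(trial_id = relocs$trial_id, reloc_idx = relocs$reloc_idx,
             ruggedness = rug, flight_height = fh, veg_class = vc,
             inside_grid = sd_edge > 0, dist_to_edge = sd_edge,
             stringsAsFactors = FALSE)
}
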