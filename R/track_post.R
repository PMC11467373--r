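# Post-processing of estimated location sequences: coordinate smoothing
# (the workflow's third smoothing axis) and outlier-speed filtering.

#' Smooth a track's coordinates
#'
#' Smooths x(t) and y(t) independently with the signal-smoothing
#' operations (`"spline"` = GCV cubic smoothing spline, `"kalman"` =
#' local-level Kalman smoother on a regular grid at the track's median
#' fix interval). Timestamps are unchanged; tracks below the smoother's
#' length threshold pass through untouched.
#'
#' @param track data.frame with columns `timestamp` (POSIXct or numeric
#'   seconds), `x`, `y`, ordered in time.
#' @param method `"none"`, `"spline"` or `"kalman"`.
#' @return the track with smoothed `x`, `y`.
#' @export
smooth_track <- function(track, method = c("none", "spline", "kalman")) {
  method <- match.arg(method)
  if (method == "none" || nrow(track) == 0) return(track)
  tt <- as.numeric(track$timestamp)
  step <- if (nrow(track) > 1) max(stats::median(diff(tt)), 1e-6) else 1
  for (axis in c("x", "y")) {
    s <- gl_series(tt, track[[axis]])
    sm <- smooth_series(s, method, step = step, collision = "first")
    track[[axis]] <- sm$values
  }
  track
}

.step_speeds <- function(track) {
  tt <- as.numeric(track$timestamp)
  dt <- diff(tt)
  dd <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  dd / pmax(dt, 1e-9)
}

#' Filter fixes that imply outlier speeds
#'
#' Computes step speeds (planar distance over elapsed time between
#' consecutive fixes) and removes the fix terminating every step above
#' the threshold, recomputing after each pass until no step exceeds it.
#' The threshold is either `hard_cap` (e.g. 25 m/s, under which 95% of
#' hummingbird speeds fell) or the given quantile of the initial speed
#' distribution.
#'
#' @param track data.frame with `timestamp`, `x`, `y` ordered in time
#'   (>= 3 fixes).
#' @param quantile speed quantile defining the threshold when no
#'   `hard_cap` is given (default 0.95).
#' @param hard_cap optional absolute speed cap in m/s overriding the
#'   quantile rule.
#' @return list `track` (filtered), `removed` (count), `threshold` (m/s).
#' @export
filter_speeds <- function(track, quantile = 0.95, hard_cap = NULL) {
  stopifnot(nrow(track) >= 3)
  v0 <- .step_speeds(track)
  threshold <- if (!is.null(hard_cap)) hard_cap
               else unname(stats::quantile(v0, quantile))
  removed <- 0L
  repeat {
    if (nrow(track) < 2) break
    v <- .step_speeds(track)
    bad <- which(v > threshold)
    if (!length(bad)) break
    track <- track[-(bad + 1), , drop = FALSE]
    removed <- removed + length(bad)
  }
  if (nrow(track) == 0)
    warning("speed filter removed every fix")
  list(track = track, removed = removed, threshold = threshold)
}

#' Export a fix table for external home-range tools
#'
#' Writes `timestamp,lon,lat,x,y` rows (lon/lat by inverse projection)
#' consumable by continuous-time movement-model / kernel-density software.
#'
#' @param track data.frame with `timestamp`, `x`, `y`.
#' @param path output CSV path.
#' @param crs working CRS identifier used for the inverse projection.
#' @return `path`, invisibly.
#' @export
export_fixes_csv <- function(track, path, crs) {
  ll <- unproject_coordinates(track$x, track$y, crs)
  out <- data.frame(timestamp = .format_utc(track$timestamp),
                    lon = ll$lon, lat = ll$lat, x = track$x, y = track$y)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a track as a GeoJSON LineString
#'
#' @param track data.frame with `x`, `y` in the working CRS.
#' @param path output GeoJSON path.
#' @param crs working CRS identifier.
#' @return `path`, invisibly.
#' @export
write_track_geojson <- function(track, path, crs) {
  ll <- unproject_coordinates(track$x, track$y, crs)
  gj <- list(type = "Feature",
             geometry = list(type = "LineString",
                             coordinates = lapply(seq_len(nrow(track)),
                               function(i) c(ll$lon[i], ll$lat[i]))),
             properties = list(n_fixes = nrow(track)))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
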