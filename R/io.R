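# Readers and writers for the canonical tabular inputs: detection tables,
# node registries and ground-truth tracks.

.canonical_detection_cols <- c("tag_id", "node_id", "timestamp_utc", "rss_db")

# Column map for CTT SensorStation node exports.
.sensorstation_map <- c(Time = "timestamp_utc", TagId = "tag_id",
                        NodeId = "node_id", TagRSSI = "rss_db")

.parse_utc <- function(x, file = "<input>") {
  x <- as.character(x)
  t <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                  tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                "%Y-%m-%d %H:%M:%OS", "%Y/%m/%d %H:%M:%OS")) {
    miss <- is.na(t)
    if (!any(miss)) break
    t[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"), tz = "UTC")
  }
  bad <- which(is.na(t) & !is.na(x) & nzchar(x))
  if (length(bad))
    stop("unparseable timestamp in ", file, " at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": '", x[bad[1]], "'")
  t
}

.format_utc <- function(t) {
  has_frac <- any(abs(as.numeric(t) - round(as.numeric(t))) > 1e-9)
  fmt <- if (has_frac) "%Y-%m-%dT%H:%M:%OS3Z" else "%Y-%m-%dT%H:%M:%SZ"
  format(t, fmt, tz = "UTC")
}

#' Read a raw detection table
#'
#' One row per received radio signal: tag id, node id, UTC timestamp and
#' received signal strength (RSS) in dB. Two dialects are understood: the
#' canonical schema (`tag_id,node_id,timestamp_utc,rss_db`) and CTT
#' SensorStation node exports (`Time,TagId,NodeId,TagRSSI`, extra columns
#' ignored). Rows whose RSS falls outside the plausibility window are
#' dropped with a warning giving the count.
#'
#' @param path CSV file path.
#' @param dialect `"canonical"` or `"sensorstation"`, or a named character
#'   vector mapping source column names to canonical ones.
#' @param rss_window length-2 numeric, plausible RSS interval in dB
#'   (default `c(-120, 0)`; the upper bound is exclusive).
#' @return data.frame with the canonical columns; `timestamp_utc` is
#'   POSIXct (UTC), `rss_db` numeric.
#' @export
read_detections <- function(path, dialect = c("canonical", "sensorstation"),
                            rss_window = c(-120, 0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  map <- if (is.character(dialect) && !is.null(names(dialect)) &&
             any(nzchar(names(dialect)))) {
    dialect
  } else {
    switch(match.arg(dialect),
           canonical = stats::setNames(.canonical_detection_cols,
                                       .canonical_detection_cols),
           sensorstation = .sensorstation_map)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(names(map), names(raw))
  if (length(missing_cols))
    stop("detection file ", path, " lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  d <- raw[names(map)]
  names(d) <- unname(map)
  d <- d[.canonical_detection_cols]
  d$timestamp_utc <- .parse_utc(d$timestamp_utc, file = path)
  d$rss_db <- as.numeric(d$rss_db)
  keep <- is.finite(d$rss_db) & d$rss_db >= rss_window[1] &
    d$rss_db < rss_window[2]
  if (any(!keep))
    warning(sum(!keep), " detection(s) outside RSS window [",
            rss_window[1], ", ", rss_window[2], ") dropped")
  d <- d[keep, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Write a detection table in the canonical schema
#'
#' Round-trips with [read_detections()]: reading a canonical file and
#' writing it again reproduces the content.
#'
#' @param detections data.frame as returned by [read_detections()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  out <- detections[.canonical_detection_cols]
  out$timestamp_utc <- .format_utc(out$timestamp_utc)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a node registry
#'
#' Expects columns `node_id,lon,lat` and optionally `height_agl` (metres
#' above ground, default 2.5 as for nodes mounted on conduit). Node
#' positions are projected into the working CRS; by default the UTM zone
#' of the registry centroid is auto-selected.
#'
#' @param path CSV file path.
#' @param crs working CRS identifier; `NULL` auto-selects via
#'   [select_crs()].
#' @return data.frame `node_id,lon,lat,x,y,height_agl` with the CRS stored
#'   in `attr(, "crs")`.
#' @export
read_nodes <- function(path, crs = NULL) {
  n <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("node_id", "lon", "lat")
  missing_cols <- setdiff(need, names(n))
  if (length(missing_cols))
    stop("node file ", path, " lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(n$node_id))
    stop("duplicate node_id in ", path)
  if (is.null(n$height_agl)) n$height_agl <- 2.5
  if (is.null(crs)) crs <- select_crs(n$lon, n$lat)
  xy <- project_coordinates(n$lon, n$lat, crs)
  n$x <- xy$x
  n$y <- xy$y
  n <- n[c("node_id", "lon", "lat", "x", "y", "height_agl")]
  attr(n, "crs") <- crs
  n
}

.read_gpx_fixes <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  pts <- xml2::xml_find_all(doc, ".//g:trkpt | .//g:wpt", ns)
  if (!length(pts))  # GPX without a namespace declaration
    pts <- xml2::xml_find_all(doc, ".//trkpt | .//wpt")
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  time <- vapply(pts, function(p) {
    t <- xml2::xml_find_first(p, ".//g:time", ns)
    if (inherits(t, "xml_missing"))
      t <- xml2::xml_find_first(p, ".//time")
    xml2::xml_text(t)
  }, character(1))
  ele <- vapply(pts, function(p) {
    e <- xml2::xml_find_first(p, ".//g:ele", ns)
    if (inherits(e, "xml_missing"))
      e <- xml2::xml_find_first(p, ".//ele")
    xml2::xml_text(e)
  }, character(1))
  data.frame(timestamp = time, lon = lon, lat = lat,
             elevation = as.numeric(ele), stringsAsFactors = FALSE)
}

#' Read a ground-truth calibration track
#'
#' Reads GPS fixes from a GPX 1.1 track or a CSV with columns
#' `timestamp,lon,lat[,elevation]`, projects them into the working CRS,
#' sorts by time and collapses duplicate timestamps to the first
#' occurrence.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"gpx"` or `"csv"`; `NULL` infers from the extension.
#' @param crs working CRS identifier; `NULL` auto-selects from the fixes.
#' @param trial_id identifier stored on every relocation.
#' @param mode trial movement mode: `"high_flight"`, `"low_flight"` or
#'   `"ground"`.
#' @return data.frame of relocations:
#'   `trial_id,reloc_idx,timestamp,x,y,elevation_gps,mode` with the CRS in
#'   `attr(, "crs")`.
#' @export
read_truth_track <- function(path, format = NULL, crs = NULL,
                             trial_id = basename(path),
                             mode = c("high_flight", "low_flight", "ground")) {
  mode <- match.arg(mode)
  if (is.null(format))
    format <- if (grepl("\\.gpx$", path, ignore.case = TRUE)) "gpx" else "csv"
  fx <- if (format == "gpx") {
    .read_gpx_fixes(path)
  } else {
    f <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("timestamp", "lon", "lat")
    missing_cols <- setdiff(need, names(f))
    if (length(missing_cols))
      stop("track file ", path, " lacks mandatory column(s): ",
           paste(missing_cols, collapse = ", "))
    if (is.null(f$elevation)) f$elevation <- NA_real_
    f[c("timestamp", "lon", "lat", "elevation")]
  }
  fx$timestamp <- .parse_utc(fx$timestamp, file = path)
  fx <- fx[order(fx$timestamp), , drop = FALSE]
  dup <- duplicated(fx$timestamp)
  if (any(dup)) {
    warning(sum(dup), " duplicate timestamp(s) in ", path,
            " collapsed to first occurrence")
    fx <- fx[!dup, , drop = FALSE]
  }
  if (nrow(fx) < 2)
    stop("track ", path, " has fewer than 2 distinct fixes")
  if (is.null(crs)) crs <- select_crs(fx$lon, fx$lat)
  xy <- project_coordinates(fx$lon, fx$lat, crs)
  out <- data.frame(trial_id = trial_id, reloc_idx = seq_len(nrow(fx)),
                    timestamp = fx$timestamp, x = xy$x, y = xy$y,
                    elevation_gps = fx$elevation, mode = mode,
                    stringsAsFactors = FALSE)
  attr(out, "crs") <- crs
  out
}
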