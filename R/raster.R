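# Minimal single-band raster container with plain-text (ESRI ASCII grid)
# serialisation, bilinear extraction, buffered cell queries and polygon
# rasterisation. Values are stored as a matrix whose first row is the
# NORTHERNMOST row, matching the ASCII-grid layout.

#' Construct a grid raster
#'
#' @param values numeric matrix; row 1 is the northernmost row.
#' @param xll,yll coordinates of the lower-left corner of the lower-left
#'   cell, in the working CRS (metres).
#' @param cellsize cell edge length in metres.
#' @param nodata value standing for missing cells in files (default -9999).
#' @return object of class `grid_raster`.
#' @export
grid_raster <- function(values, xll, yll, cellsize, nodata = -9999) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat("grid_raster: ", nrow(x$values), " rows x ", ncol(x$values),
      " cols, cell ", x$cellsize, " m\n",
      "  extent x [", x$xll, ", ", x$xll + ncol(x$values) * x$cellsize,
      "], y [", x$yll, ", ", x$yll + nrow(x$values) * x$cellsize, "]\n",
      sep = "")
  invisible(x)
}

.raster_extent <- function(r) {
  c(xmin = r$xll, xmax = r$xll + ncol(r$values) * r$cellsize,
    ymin = r$yll, ymax = r$yll + nrow(r$values) * r$cellsize)
}

# cell centres: column j -> x = xll + (j - 0.5) cs; row i (from top) ->
# y = yll + (nrow - i + 0.5) cs
.cell_centres <- function(r) {
  cs <- r$cellsize
  list(x = r$xll + (seq_len(ncol(r$values)) - 0.5) * cs,
       y = r$yll + (nrow(r$values) - seq_len(nrow(r$values)) + 0.5) * cs)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path `.asc` file path.
#' @return a [grid_raster()].
#' @export
read_ascii_grid <- function(path) {
  hdr <- utils::read.table(path, nrows = 6, stringsAsFactors = FALSE)
  h <- stats::setNames(as.numeric(hdr[[2]]), tolower(hdr[[1]]))
  vals <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  nodata <- if ("nodata_value" %in% names(h)) h[["nodata_value"]] else -9999
  m[m == nodata] <- NA_real_
  xll <- if ("xllcorner" %in% names(h)) h[["xllcorner"]]
         else h[["xllcenter"]] - h[["cellsize"]] / 2
  yll <- if ("yllcorner" %in% names(h)) h[["yllcorner"]]
         else h[["yllcenter"]] - h[["cellsize"]] / 2
  grid_raster(m, xll, yll, h[["cellsize"]], nodata)
}

#' Write an ESRI ASCII grid raster
#'
#' @param r a [grid_raster()].
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(r$values)),
               paste("nrows", nrow(r$values)),
               paste("xllcorner", format(r$xll, scientific = FALSE)),
               paste("yllcorner", format(r$yll, scientific = FALSE)),
               paste("cellsize", format(r$cellsize, scientific = FALSE)),
               paste("NODATA_value", r$nodata)), con)
  m <- r$values
  m[is.na(m)] <- r$nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bilinear raster extraction at points
#'
#' Interpolates between the four surrounding cell centres; points in the
#' outer half-cell margin use nearest-edge values; points outside the
#' raster return `NA`.
#'
#' @param r a [grid_raster()].
#' @param x,y point coordinates, metres.
#' @return numeric vector of interpolated values.
#' @export
raster_bilinear <- function(r, x, y) {
  cs <- r$cellsize
  nr <- nrow(r$values); nc <- ncol(r$values)
  ext <- .raster_extent(r)
  # fractional column/row position in cell-centre coordinates
  fc <- (x - r$xll) / cs + 0.5
  fr <- (ext[["ymax"]] - y) / cs + 0.5
  out <- rep(NA_real_, length(x))
  inside <- x >= ext[["xmin"]] & x <= ext[["xmax"]] &
    y >= ext[["ymin"]] & y <= ext[["ymax"]]
  fc <- pmin(pmax(fc, 1), nc)
  fr <- pmin(pmax(fr, 1), nr)
  j0 <- pmin(floor(fc), nc - 1); j1 <- j0 + 1
  i0 <- pmin(floor(fr), nr - 1); i1 <- i0 + 1
  wx <- fc - j0; wy <- fr - i0
  v <- (1 - wx) * (1 - wy) * r$values[cbind(i0, j0)] +
    wx * (1 - wy) * r$values[cbind(i0, j1)] +
    (1 - wx) * wy * r$values[cbind(i1, j0)] +
    wx * wy * r$values[cbind(i1, j1)]
  out[inside] <- v[inside]
  out
}

#' Raster cell values within a radius of a point
#'
#' Returns values of all cells whose CENTRES fall within `radius` of
#' `(x, y)` (no partial-cell weighting).
#'
#' @param r a [grid_raster()].
#' @param x,y point coordinates, metres.
#' @param radius buffer radius, metres.
#' @return numeric vector of cell values (possibly length 0).
#' @export
raster_values_in_radius <- function(r, x, y, radius) {
  cc <- .cell_centres(r)
  jj <- which(abs(cc$x - x) <= radius)
  ii <- which(abs(cc$y - y) <= radius)
  if (!length(ii) || !length(jj)) return(numeric(0))
  g <- expand.grid(i = ii, j = jj)
  d2 <- (cc$x[g$j] - x)^2 + (cc$y[g$i] - y)^2
  r$values[cbind(g$i, g$j)][d2 <= radius^2]
}

# even-odd rule point-in-polygon; poly is a 2-column matrix of vertices
.point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    crosses <- ((ys[k] > py) != (ye[k] > py))
    if (any(crosses)) {
      xint <- xs[k] + (py - ys[k]) / (ye[k] - ys[k]) * (xe[k] - xs[k])
      flip <- crosses & (px < xint)
      inside[flip] <- !inside[flip]
    }
  }
  inside
}

#' Rasterise classed polygons onto a grid
#'
#' Burns polygon class codes into a new raster by cell-centre inclusion
#' (even-odd rule). Later polygons overwrite earlier ones where they
#' overlap; untouched cells get `background`.
#'
#' @param polys list of polygons, each a list with elements `coords`
#'   (2-column matrix of x/y vertices, metres) and `class` (integer code).
#' @param xll,yll,cellsize,nrows,ncols target grid geometry.
#' @param background value for uncovered cells (default `NA`).
#' @return a [grid_raster()] of class codes.
#' @export
rasterize_polygons <- function(polys, xll, yll, cellsize, nrows, ncols,
                               background = NA_real_) {
  m <- matrix(background, nrows, ncols)
  cx <- xll + (seq_len(ncols) - 0.5) * cellsize
  cy <- yll + (nrows - seq_len(nrows) + 0.5) * cellsize
  g <- expand.grid(i = seq_len(nrows), j = seq_len(ncols))
  px <- cx[g$j]; py <- cy[g$i]
  for (p in polys) {
    hit <- .point_in_poly(px, py, p$coords)
    m[cbind(g$i[hit], g$j[hit])] <- p$class
  }
  grid_raster(m, xll, yll, cellsize)
}

#' Read vegetation polygons from GeoJSON
#'
#' Expects Polygon/MultiPolygon features with a `class` property holding
#' one of the four vegetation categories. Coordinates are lon/lat and are
#' projected into the working CRS.
#'
#' @param path GeoJSON file path.
#' @param crs working CRS identifier.
#' @param class_levels category names in code order.
#' @return list of polygons suitable for [rasterize_polygons()], with the
#'   `class` slot an integer index into `class_levels`.
#' @export
read_vegetation_geojson <- function(path, crs,
                                    class_levels = c("grassland", "paramo",
                                                     "dense", "builtup")) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  out <- list()
  for (f in feats) {
    cls <- match(f$properties$class, class_levels)
    if (is.na(cls))
      stop("unknown vegetation class '", f$properties$class, "' in ", path)
    geom <- f$geometry
    rings <- switch(geom$type,
                    Polygon = list(geom$coordinates[[1]]),
                    MultiPolygon = lapply(geom$coordinates, `[[`, 1),
                    stop("unsupported geometry type: ", geom$type))
    for (ring in rings) {
      ll <- do.call(rbind, lapply(ring, function(c2)
        c(as.numeric(c2[[1]]), as.numeric(c2[[2]]))))
      xy <- project_coordinates(ll[, 1], ll[, 2], crs)
      out[[length(out) + 1]] <- list(coords = cbind(xy$x, xy$y), class = cls)
    }
  }
  out
}
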