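# WGS84 transverse-Mercator (UTM) projection, Snyder series formulas.
# Accuracy is sub-millimetre within a zone, far below the GPS noise of any
# telemetry application; verified against a geodesic oracle in the tests.

.WGS84 <- list(a = 6378137, f = 1 / 298.257223563)

#' Pick a working projected CRS for a set of points
#'
#' Selects the UTM zone containing the centroid of the supplied
#' longitude/latitude points. All package distances are Euclidean in this
#' metric, locally conformal CRS.
#'
#' @param lon,lat numeric vectors, decimal degrees WGS84.
#' @return a CRS identifier string such as `"utm18n"`.
#' @export
select_crs <- function(lon, lat) {
  stopifnot(length(lon) == length(lat), length(lon) >= 1)
  clon <- mean(lon)
  clat <- mean(lat)
  zone <- floor((clon + 180) / 6) + 1
  zone <- max(1L, min(60L, as.integer(zone)))
  paste0("utm", zone, if (clat >= 0) "n" else "s")
}

.parse_crs <- function(crs) {
  m <- regmatches(crs, regexec("^utm([0-9]{1,2})([ns])$", tolower(crs)))[[1]]
  if (length(m) != 3)
    stop("unsupported CRS identifier: ", crs, " (expected e.g. 'utm18n')")
  list(zone = as.integer(m[2]), north = m[3] == "n")
}

#' Project longitude/latitude to metric grid coordinates
#'
#' Forward transverse-Mercator projection into the given UTM zone.
#' Invertible by [unproject_coordinates()] to within 1e-6 degrees; planar
#' distances approximate geodesic distances to well under 0.1% at
#' radio-grid scale.
#'
#' @param lon,lat numeric vectors, decimal degrees WGS84.
#' @param crs CRS identifier from [select_crs()].
#' @return data.frame with columns `x`, `y` in metres.
#' @export
project_coordinates <- function(lon, lat, crs) {
  stopifnot(length(lon) == length(lat))
  if (any(!is.finite(lat)) || any(abs(lat) > 90))
    stop("latitude outside [-90, 90]")
  p <- .parse_crs(crs)
  a <- .WGS84$a; f <- .WGS84$f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  k0 <- 0.9996
  lam0 <- (-183 + 6 * p$zone) * pi / 180
  phi <- lat * pi / 180
  lam <- lon * pi / 180

  sp <- sin(phi); cp <- cos(phi)
  N <- a / sqrt(1 - e2 * sp^2)
  T <- (sp / cp)^2
  C <- ep2 * cp^2
  A <- (lam - lam0) * cp
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
            (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
            (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
            (35 * e2^3 / 3072) * sin(6 * phi))
  x <- 500000 + k0 * N * (A + (1 - T + C) * A^3 / 6 +
         (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120)
  y <- k0 * (M + N * (sp / cp) * (A^2 / 2 +
         (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
         (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  if (!p$north) y <- y + 10000000
  data.frame(x = x, y = y)
}

#' Inverse-project metric grid coordinates to longitude/latitude
#'
#' @param x,y numeric vectors, metres in the working CRS.
#' @param crs CRS identifier from [select_crs()].
#' @return data.frame with columns `lon`, `lat` in decimal degrees.
#' @export
unproject_coordinates <- function(x, y, crs) {
  stopifnot(length(x) == length(y))
  p <- .parse_crs(crs)
  a <- .WGS84$a; f <- .WGS84$f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  k0 <- 0.9996
  lam0 <- (-183 + 6 * p$zone) * pi / 180
  if (!p$north) y <- y - 10000000
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  M <- y / k0
  mu <- M / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)
  sp <- sin(phi1); cp <- cos(phi1)
  C1 <- ep2 * cp^2
  T1 <- (sp / cp)^2
  N1 <- a / sqrt(1 - e2 * sp^2)
  R1 <- a * (1 - e2) / (1 - e2 * sp^2)^1.5
  D <- (x - 500000) / (N1 * k0)
  phi <- phi1 - (N1 * sp / cp / R1) * (D^2 / 2 -
    (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
    (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
  lam <- lam0 + (D - (1 + 2 * T1 + C1) * D^3 / 6 +
    (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) * D^5 / 120) / cp
  data.frame(lon = lam * 180 / pi, lat = phi * 180 / pi)
}
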