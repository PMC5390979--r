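# Transverse Mercator (UTM) forward/inverse on the WGS84 ellipsoid.
# Implemented from the standard series expansions; accurate to well under
# 1 m within a zone, which is ample for 1 km2 rasters and 500 km2 cells.

.wgs84 <- list(a = 6378137, f = 1 / 298.257223563)
.utm_k0 <- 0.9996
.utm_false_easting <- 5e5
.utm_false_northing_south <- 1e7

#' UTM zone for a longitude
#'
#' @param lon longitude in decimal degrees (-180, 180]
#' @return integer zone number in 1..60
#' @export
#' @examples
#' utm_zone(-110.5) # 12
utm_zone <- function(lon) {
  stopifnot(is.numeric(lon), all(is.finite(lon)))
  z <- floor((lon + 180) / 6) + 1
  as.integer(pmin(pmax(z, 1L), 60L))
}

.utm_central_meridian <- function(zone) (zone - 1) * 6 - 180 + 3

#' Project geographic coordinates to UTM meters
#'
#' Forward Transverse Mercator projection on WGS84. The zone is auto-derived
#' from the centroid longitude when not supplied; coordinates far outside the
#' chosen zone raise a warning (distortion grows away from the central
#' meridian) but are still projected.
#'
#' @param lon,lat numeric vectors, decimal degrees
#' @param zone UTM zone (1..60); default derived from `mean(lon)`
#' @param hemisphere "N" or "S"; controls the false northing
#' @return data.frame with columns `x`, `y` (meters) and attributes
#'   `zone`, `hemisphere`
#' @export
project_geometry <- function(lon, lat, zone = NULL, hemisphere = c("N", "S")) {
  hemisphere <- match.arg(hemisphere)
  if (length(lon) != length(lat) || length(lon) == 0)
    stop("lon and lat must be non-empty vectors of equal length")
  if (!all(is.finite(lon)) || !all(is.finite(lat)))
    stop("invalid geometry: non-finite coordinates")
  if (any(abs(lat) > 84)) stop("invalid geometry: |lat| > 84 is outside UTM")
  if (is.null(zone)) zone <- utm_zone(mean(lon))
  lon0 <- .utm_central_meridian(zone)
  if (any(abs(lon - lon0) > 6))
    warning("coordinates more than 6 degrees from the zone ", zone,
            " central meridian; distortion will be large")

  a <- .wgs84$a; f <- .wgs84$f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  phi <- lat * pi / 180
  dlam <- (lon - lon0) * pi / 180

  sphi <- sin(phi); cphi <- cos(phi)
  N <- a / sqrt(1 - e2 * sphi^2)
  T <- tan(phi)^2
  C <- ep2 * cphi^2
  A <- cphi * dlam
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
            (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
            (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
            (35 * e2^3 / 3072) * sin(6 * phi))
  x <- .utm_k0 * N * (A + (1 - T + C) * A^3 / 6 +
                      (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) +
       .utm_false_easting
  y <- .utm_k0 * (M + N * tan(phi) * (A^2 / 2 +
                  (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
                  (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  if (hemisphere == "S") y <- y + .utm_false_northing_south
  out <- data.frame(x = x, y = y)
  attr(out, "zone") <- as.integer(zone)
  attr(out, "hemisphere") <- hemisphere
  out
}

#' Inverse UTM projection back to geographic coordinates
#'
#' @param x,y projected coordinates in meters
#' @param zone UTM zone used for the forward projection
#' @param hemisphere "N" or "S"
#' @return data.frame with columns `lon`, `lat` in decimal degrees
#' @export
unproject_geometry <- function(x, y, zone, hemisphere = c("N", "S")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  a <- .wgs84$a; f <- .wgs84$f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  lon0 <- .utm_central_meridian(zone)

  xs <- x - .utm_false_easting
  ys <- if (hemisphere == "S") y - .utm_false_northing_south else y
  M <- ys / .utm_k0
  mu <- M / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
          (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
          (151 * e1^3 / 96) * sin(6 * mu) +
          (1097 * e1^4 / 512) * sin(8 * mu)

  sphi <- sin(phi1); cphi <- cos(phi1)
  N1 <- a / sqrt(1 - e2 * sphi^2)
  R1 <- a * (1 - e2) / (1 - e2 * sphi^2)^1.5
  T1 <- tan(phi1)^2
  C1 <- ep2 * cphi^2
  D <- xs / (N1 * .utm_k0)
  lat <- phi1 - (N1 * tan(phi1) / R1) *
         (D^2 / 2 - (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
          (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
  lon <- (D - (1 + 2 * T1 + C1) * D^3 / 6 +
          (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) * D^5 / 120) / cphi
  data.frame(lon = lon0 + lon * 180 / pi, lat = lat * 180 / pi)
}
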