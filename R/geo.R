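# Spherical geometry on the WGS84 mean radius. Coordinates are degrees;
# distances are meters. Everything is vectorized and recycles like rnorm().

#' Mean Earth radius (meters) used for all spherical geometry
#' @keywords internal
.EARTH_RADIUS_M <- 6371008.8

.deg2rad <- function(x) x * (pi / 180)
.rad2deg <- function(x) x * (180 / pi)

#' Haversine great-circle distance
#'
#' Distance in meters between points on the sphere of radius 6371.0088 km.
#' Symmetric, non-negative and zero exactly when the coordinates coincide.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS84).
#' @return numeric vector of distances in meters.
#' @examples
#' haversine_m(45.4384, 10.9916, 45.4484, 10.9916) # ~1111.9 m
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  if (!all(is.finite(lat1), is.finite(lon1), is.finite(lat2), is.finite(lon2)))
    stop("haversine_m: non-finite coordinate")
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dphi <- phi2 - phi1
  dlam <- .deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * .EARTH_RADIUS_M * asin(sqrt(a))
}

#' Initial bearing from one point to another
#'
#' @inheritParams haversine_m
#' @return bearing in degrees in [0, 360), measured clockwise from north.
#' @export
bearing_deg <- function(lat1, lon1, lat2, lon2) {
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dlam <- .deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
  (.rad2deg(atan2(y, x)) + 360) %% 360
}

#' Destination point given start, bearing and distance
#'
#' @inheritParams haversine_m
#' @param bearing bearing in degrees clockwise from north.
#' @param dist_m distance in meters.
#' @return list with `lat` and `lon` in degrees.
#' @export
destination_point <- function(lat1, lon1, bearing, dist_m) {
  phi1 <- .deg2rad(lat1); lam1 <- .deg2rad(lon1)
  theta <- .deg2rad(bearing)
  delta <- dist_m / .EARTH_RADIUS_M
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(theta))
  lam2 <- lam1 + atan2(
    sin(theta) * sin(delta) * cos(phi1),
    cos(delta) - sin(phi1) * sin(phi2)
  )
  list(lat = .rad2deg(phi2), lon = ((.rad2deg(lam2) + 540) %% 360) - 180)
}

# Absolute heading change |a - b| folded to [0, 180].
.heading_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}
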