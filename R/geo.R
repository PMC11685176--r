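# Spherical-earth geometry. All distances in km on a sphere of mean radius
# 6371.0088 km; coordinates are WGS84 decimal degrees, longitude first.

#' Mean Earth radius (km) used throughout the package
#' @keywords internal
EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Inputs are
#' vectorised and recycled; coordinates are WGS84 decimal degrees in
#' longitude/latitude order.
#'
#' @param lon1,lat1 coordinates of the first point(s), decimal degrees.
#' @param lon2,lat2 coordinates of the second point(s), decimal degrees.
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(-89, 36, -89, 37)  # one degree of latitude, ~111.195 km
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  stopifnot(is.finite(lon1), is.finite(lat1), is.finite(lon2), is.finite(lat2))
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range: |lat| <= 90, |lon| <= 180 required")
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

# Destination point after moving `km` along an initial bearing (degrees,
# clockwise from north) on the sphere. Used by the track generator.
move_point <- function(lon, lat, bearing_deg, km) {
  rad <- pi / 180
  d <- km / EARTH_RADIUS_KM
  br <- bearing_deg * rad
  la1 <- lat * rad
  lo1 <- lon * rad
  la2 <- asin(sin(la1) * cos(d) + cos(la1) * sin(d) * cos(br))
  lo2 <- lo1 + atan2(sin(br) * sin(d) * cos(la1),
                     cos(d) - sin(la1) * sin(la2))
  c(lon = ((lo2 / rad + 540) %% 360) - 180, lat = la2 / rad)
}
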