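# Geodesy helpers shared across modules. All distances in km on a sphere of
# mean radius 6371.009 km; bearings in degrees clockwise from north.

#' Mean Earth radius used throughout the package (km)
#' @keywords internal
EARTH_RADIUS_KM <- 6371.009

#' Great-circle (haversine) distance in km
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees; vectors recycle.
#' @return distance in km
#' @export
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Initial great-circle bearing, degrees clockwise from north in [0, 360)
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees
#' @export
gc_bearing_deg <- function(lon1, lat1, lon2, lat2) {
  b <- geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2))
  (b + 360) %% 360
}

#' Destination point from start, bearing and distance
#' @param lon,lat start position (degrees)
#' @param bearing_deg bearing clockwise from north
#' @param dist_km great-circle distance in km
#' @return matrix with columns lon, lat
#' @export
gc_destination <- function(lon, lat, bearing_deg, dist_km) {
  p <- geosphere::destPoint(cbind(lon, lat), bearing_deg, dist_km * 1000,
                            r = EARTH_RADIUS_KM * 1000)
  colnames(p) <- c("lon", "lat")
  p
}

#' Intermediate point a fraction f along the great circle p1 -> p2
#' @keywords internal
gc_interpolate <- function(lon1, lat1, lon2, lat2, f) {
  d <- gc_dist_km(lon1, lat1, lon2, lat2)
  out <- cbind(lon = lon1, lat = lat1)
  mv <- d > 1e-9
  if (any(mv)) {
    b <- gc_bearing_deg(lon1[mv], lat1[mv], lon2[mv], lat2[mv])
    out[mv, ] <- gc_destination(lon1[mv], lat1[mv], b, (d * f)[mv])
  }
  out
}

# Local azimuthal-equidistant projection about a centre: x east, y north, km.
# Used by the track smoother; accurate for the few-thousand-km scales of a
# seal trip.
project_aeq <- function(lon, lat, lon0, lat0) {
  d <- gc_dist_km(lon0, lat0, lon, lat)
  b <- gc_bearing_deg(lon0, lat0, lon, lat) * pi / 180
  cbind(x = d * sin(b), y = d * cos(b))
}

unproject_aeq <- function(x, y, lon0, lat0) {
  d <- sqrt(x^2 + y^2)
  b <- (atan2(x, y) * 180 / pi + 360) %% 360
  out <- cbind(lon = rep(lon0, length(x)), lat = rep(lat0, length(x)))
  mv <- d > 1e-12
  if (any(mv)) out[mv, ] <- gc_destination(lon0, lat0, b[mv], d[mv])
  out
}

#' Normalize longitudes to (-180, 180]
#' @keywords internal
norm_lon <- function(lon) {
  l <- ((lon + 180) %% 360) - 180
  ifelse(l == -180, 180, l)
}
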