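# Spherical earth, mean radius 6371.0088 km; positions are lon/lat WGS84
# decimal degrees throughout.
.earth_radius_m <- 6371008.8
.m_per_deg <- .earth_radius_m * pi / 180

#' Great-circle distance between lon/lat points
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Inputs are
#' recycled; `p1`/`p2` are two-column (lon, lat) matrices or length-2
#' vectors.
#'
#' @param p1,p2 matrix with columns lon, lat (decimal degrees) or a
#'   length-2 vector.
#' @return distances in metres.
#' @export
haversine_m <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = .earth_radius_m)
}

# Displace points by dist metres along bearing (radians, 0 = north,
# clockwise). Local equirectangular step: adequate for sub-10-km hourly
# moves at mid latitudes.
move_point <- function(lon, lat, bearing, dist_m) {
  dlat <- dist_m * cos(bearing) / .m_per_deg
  dlon <- dist_m * sin(bearing) / (.m_per_deg * cos(lat * pi / 180))
  cbind(lon = lon + dlon, lat = lat + dlat)
}

# Initial bearing (radians from north) from point 1 towards point 2.
bearing_to <- function(lon1, lat1, lon2, lat2) {
  phi1 <- lat1 * pi / 180
  phi2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  atan2(sin(dl) * cos(phi2),
        cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dl))
}

# Linear interpolation of a track (data.frame t, lon, lat) at times tq.
# Returns a matrix with columns lon, lat; NA outside the fix range.
interp_track <- function(track, tq) {
  if (nrow(track) < 2) {
    out <- matrix(NA_real_, length(tq), 2,
                  dimnames = list(NULL, c("lon", "lat")))
    if (nrow(track) == 1) {
      hit <- !is.na(tq) & tq == track$t[1]
      out[hit, 1] <- track$lon[1]
      out[hit, 2] <- track$lat[1]
    }
    return(out)
  }
  lon <- approx(track$t, track$lon, xout = tq, rule = 1)$y
  lat <- approx(track$t, track$lat, xout = tq, rule = 1)$y
  cbind(lon = lon, lat = lat)
}
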