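# Spherical-earth constants shared by the tracker and the distance metrics.
# R_EARTH_M is the mean radius; M_PER_DEG is meters per degree of latitude
# (2*pi*R/360), the metric used to convert velocities to angular displacement.
R_EARTH_M <- 6371000
M_PER_DEG <- 2 * pi * R_EARTH_M / 360  # 111194.9266 m

#' Great-circle distance (haversine, R = 6371 km)
#'
#' Distance between points on the sphere used throughout the package:
#' larval dispersal distances and MPA pairwise distances. Vectorised and
#' recycled over the longer of the two point sets.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (WGS84 lon/lat).
#' @return distance in kilometers.
#' @export
#' @examples
#' great_circle_km(0, 0, 1, 0)  # one degree of longitude on the equator
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = R_EARTH_M) / 1000
}

# Spherical area of a lon/lat cell bounded by [lon1,lon2] x [lat1,lat2], km^2.
cell_area_km2 <- function(lon1, lon2, lat1, lat2) {
  (R_EARTH_M / 1000)^2 * abs(lon2 - lon1) * pi / 180 *
    abs(sin(lat2 * pi / 180) - sin(lat1 * pi / 180))
}

# Cell edges from strictly increasing cell centers.
axis_edges <- function(centers) {
  n <- length(centers)
  if (n == 1L) {
    return(c(centers - 0.5, centers + 0.5))
  }
  mid <- (centers[-n] + centers[-1]) / 2
  c(centers[1] - (mid[1] - centers[1]), mid,
    centers[n] + (centers[n] - mid[n - 1]))
}

stop_domain <- function(...) stop(..., call. = FALSE)
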