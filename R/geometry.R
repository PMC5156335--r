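#' Great-circle distance between points
#'
#' Spherical (haversine) great-circle distance. All angles in decimal
#' degrees; latitude positive north, longitude positive east.
#'
#' @param lat1,lon1 Coordinates of the first point(s), degrees.
#' @param lat2,lon2 Coordinates of the second point(s), degrees.
#' @param radius_km Sphere radius in km (default mean Earth radius 6371.0).
#' @return Distance(s) in km; vectorised over the inputs.
#' @examples
#' haversine_km(0, 0, 0, 90)   # a quarter of the equator, ~10007.5 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371.0) {
  stopifnot(radius_km > 0)
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * radius_km * asin(sqrt(a))
}

#' Normalise longitudes to [-180, 180)
#'
#' @param lon Longitude(s) in degrees.
#' @return Equivalent longitude(s) in the half-open interval [-180, 180).
#' @export
norm_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

# lat/lon (degrees) -> unit 3-vectors, rows = points
latlon_to_xyz <- function(lat, lon) {
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
}

xyz_to_latlon <- function(v) {
  v <- v / sqrt(rowSums(v^2))
  lat <- asin(pmin(pmax(v[, 3], -1), 1)) * 180 / pi
  lon <- atan2(v[, 2], v[, 1]) * 180 / pi
  cbind(lat = lat, lon = norm_lon(lon))
}

# Spherical linear interpolation between two points at fractions f in [0,1].
gc_interpolate <- function(lat1, lon1, lat2, lon2, f) {
  a <- latlon_to_xyz(lat1, lon1)[1, ]
  b <- latlon_to_xyz(lat2, lon2)[1, ]
  omega <- acos(pmin(pmax(sum(a * b), -1), 1))
  if (omega < 1e-12) {
    out <- matrix(rep(c(lat1, lon1), length(f)), ncol = 2, byrow = TRUE)
    colnames(out) <- c("lat", "lon")
    return(out)
  }
  s <- sin(omega)
  w1 <- sin((1 - f) * omega) / s
  w2 <- sin(f * omega) / s
  xyz_to_latlon(cbind(w1 * a[1] + w2 * b[1],
                      w1 * a[2] + w2 * b[2],
                      w1 * a[3] + w2 * b[3]))
}

# Walk a piecewise great-circle route; returns lat/lon at arc distances d_km
# from the start (d_km clipped to [0, total length]).
route_point <- function(route_lat, route_lon, d_km, radius_km = 6371.0) {
  seg <- haversine_km(route_lat[-length(route_lat)], route_lon[-length(route_lon)],
                      route_lat[-1], route_lon[-1], radius_km)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  d_km <- pmin(pmax(d_km, 0), total)
  out <- matrix(NA_real_, nrow = length(d_km), ncol = 2,
                dimnames = list(NULL, c("lat", "lon")))
  for (k in seq_along(d_km)) {
    d <- d_km[k]
    i <- findInterval(d, cum, rightmost.closed = TRUE)
    i <- min(i, length(seg))
    f <- if (seg[i] > 0) (d - cum[i]) / seg[i] else 0
    out[k, ] <- gc_interpolate(route_lat[i], route_lon[i],
                               route_lat[i + 1], route_lon[i + 1], f)
  }
  out
}

# Displace a point by dx/dy km (east/north, local tangent approximation).
offset_km <- function(lat, lon, dx_km, dy_km, radius_km = 6371.0) {
  dlat <- dy_km / (radius_km * pi / 180)
  lat2 <- pmin(pmax(lat + dlat, -89.9), 89.9)
  dlon <- dx_km / (radius_km * pi / 180 * cos(lat2 * pi / 180))
  cbind(lat = lat2, lon = norm_lon(lon + dlon))
}
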