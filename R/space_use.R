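#' Albers equal-area conic projection
#'
#' Spherical Albers equal-area conic (Snyder's closed forms). Named presets
#' approximate the standard continental projections used for wintering-area
#' analysis; `"auto"` centres the cone on the point set with standard
#' parallels at the 1/6 and 5/6 latitude quantiles.
#'
#' @param lat,lon Points to project, degrees.
#' @param region_hint `"PACIFIC"`/`"south-america"`, `"ATLANTIC"`/`"africa"`,
#'   or `"auto"`.
#' @param radius_km Sphere radius, km.
#' @return List with `x`, `y` (km) and `projection` (parameter descriptor
#'   reusable with [albers_forward()] / [albers_inverse()]).
#' @export
to_equal_area <- function(lat, lon, region_hint = "auto", radius_km = 6371.0) {
  stopifnot(length(lat) >= 1, length(lat) == length(lon))
  lon <- norm_lon(lon)
  span <- diff(range(lon))
  if (min(span, 360 - span) > 160) {
    stop("points span more than 160 degrees of longitude; ",
         "split per basin before projecting", call. = FALSE)
  }
  proj <- switch(tolower(region_hint),
    "pacific" = , "south-america" = list(lat1 = -5, lat2 = -42, lat0 = -32,
                                         lon0 = -60, radius_km = radius_km),
    "atlantic" = , "africa" = list(lat1 = 20, lat2 = -23, lat0 = 0,
                                   lon0 = 25, radius_km = radius_km),
    {
      q <- stats::quantile(lat, c(1 / 6, 5 / 6), names = FALSE)
      if (diff(q) < 0.5) q <- q + c(-0.5, 0.5)
      list(lat1 = q[1], lat2 = q[2], lat0 = mean(lat),
           lon0 = mean(lon), radius_km = radius_km)
    })
  proj$n <- (sin(proj$lat1 * pi / 180) + sin(proj$lat2 * pi / 180)) / 2
  if (abs(proj$n) < 1e-9) proj$n <- 1e-9
  proj$C <- cos(proj$lat1 * pi / 180)^2 + 2 * proj$n * sin(proj$lat1 * pi / 180)
  proj$rho0 <- albers_rho(proj, proj$lat0)
  p <- albers_forward(proj, lat, lon)
  list(x = p$x, y = p$y, projection = proj)
}

albers_rho <- function(proj, lat) {
  proj$radius_km * sqrt(pmax(proj$C - 2 * proj$n * sin(lat * pi / 180), 0)) / proj$n
}

#' Forward Albers projection
#' @param proj Projection descriptor from [to_equal_area()].
#' @param lat,lon Points, degrees.
#' @return List with `x`, `y` in km.
#' @export
albers_forward <- function(proj, lat, lon) {
  rho <- albers_rho(proj, lat)
  theta <- proj$n * norm_lon(lon - proj$lon0) * pi / 180
  list(x = rho * sin(theta), y = proj$rho0 - rho * cos(theta))
}

#' Inverse Albers projection
#' @param proj Projection descriptor.
#' @param x,y Projected coordinates, km.
#' @return List with `lat`, `lon` in degrees.
#' @export
albers_inverse <- function(proj, x, y) {
  sgn <- sign(proj$n)
  rho <- sgn * sqrt(x^2 + (proj$rho0 - y)^2)
  theta <- atan2(sgn * x, sgn * (proj$rho0 - y))
  lat <- asin(pmin(pmax((proj$C - (rho * proj$n / proj$radius_km)^2) /
                          (2 * proj$n), -1), 1)) * 180 / pi
  lon <- norm_lon(proj$lon0 + theta / proj$n * 180 / pi)
  list(lat = lat, lon = lon)
}

#' Kernel density surface with a quartic kernel
#'
#' Fixed-bandwidth kernel density in projected km with the quartic
#' (biweight) kernel, whose compact support matches the "search radius"
#' semantics of the GIS kernel-density tools this reproduces: density is
#' exactly zero beyond `bandwidth_km` of every point. The grid covers the
#' point bounding box padded by one bandwidth and is normalised to unit
#' volume.
#'
#' @param x,y Projected point coordinates, km.
#' @param bandwidth_km Kernel radius, km.
#' @param cell_km Output cell size, km.
#' @return Object of class `kernel_surface`: `x`, `y` (cell-centre axes),
#'   `z` (density matrix, `length(x)` by `length(y)`), `cell_km`,
#'   `bandwidth_km`.
#' @export
kernel_density <- function(x, y, bandwidth_km = 200, cell_km = 10) {
  stopifnot(length(x) >= 1, length(x) == length(y),
            bandwidth_km > 0, cell_km > 0)
  h <- bandwidth_km
  gx <- seq(min(x) - h, max(x) + h + cell_km, by = cell_km)
  gy <- seq(min(y) - h, max(y) + h + cell_km, by = cell_km)
  z <- matrix(0, nrow = length(gx), ncol = length(gy))
  half <- ceiling(h / cell_km) + 1L
  for (k in seq_along(x)) {
    i0 <- findInterval(x[k], gx)
    j0 <- findInterval(y[k], gy)
    ii <- max(1L, i0 - half):min(length(gx), i0 + half)
    jj <- max(1L, j0 - half):min(length(gy), j0 + half)
    u2 <- outer((gx[ii] - x[k])^2, (gy[jj] - y[k])^2, "+") / h^2
    kern <- ifelse(u2 < 1, (3 / pi) * (1 - u2)^2, 0)
    z[ii, jj] <- z[ii, jj] + kern
  }
  vol <- sum(z) * cell_km^2
  if (vol > 0) z <- z / vol
  structure(list(x = gx, y = gy, z = z, cell_km = cell_km,
                 bandwidth_km = bandwidth_km),
            class = "kernel_surface")
}

#' Occupancy (utilization) contours of a kernel surface
#'
#' Highest-density regions: for each level p the density threshold is the
#' largest t such that cells with density >= t hold at least p% of the total
#' volume; the region is those cells, polygonised along the isoline at t.
#' Regions nest exactly by construction.
#'
#' @param surface A `kernel_surface`.
#' @param levels Percent levels in (0, 100).
#' @param projection Optional projection descriptor; when supplied, polygon
#'   coordinates are also returned in geographic (WGS84) degrees.
#' @return List of class `occupancy_contours`; one element per level with
#'   `level`, `threshold`, `captured_fraction`, `polygons` (list of
#'   two-column matrices, km) and `polygons_geo` (lon/lat matrices) when a
#'   projection is given.
#' @export
occupancy_contours <- function(surface, levels = c(25, 50, 75),
                               projection = NULL) {
  if (any(levels <= 0) || any(levels > 100)) {
    stop("contour levels must lie in (0, 100]", call. = FALSE)
  }
  cell_area <- surface$cell_km^2
  vals <- sort(as.numeric(surface$z[surface$z > 0]), decreasing = TRUE)
  if (length(vals) == 0) stop("surface has no positive volume", call. = FALSE)
  cum <- cumsum(vals) * cell_area
  total <- cum[length(cum)]
  out <- lapply(sort(levels), function(p) {
    k <- which(cum >= total * p / 100)[1]
    t <- vals[k]
    captured <- sum(surface$z[surface$z >= t]) * cell_area
    iso <- grDevices::contourLines(surface$x, surface$y, surface$z,
                                   levels = t * (1 - 1e-9))
    polys <- lapply(iso, function(l) cbind(x = l$x, y = l$y))
    res <- list(level = p, threshold = t, captured_fraction = captured / total,
                polygons = polys)
    if (!is.null(projection)) {
      res$polygons_geo <- lapply(polys, function(m) {
        g <- albers_inverse(projection, m[, 1], m[, 2])
        cbind(lon = g$lon, lat = g$lat)
      })
    }
    res
  })
  structure(out, class = "occupancy_contours")
}

contour_threshold <- function(contours, level) {
  for (ct in contours) if (ct$level == level) return(ct$threshold)
  stop("no contour at level ", level, call. = FALSE)
}

#' Cell membership in a thresholded kernel surface
#'
#' @param surface A `kernel_surface`.
#' @param threshold Density threshold.
#' @param x,y Projected points, km.
#' @return Logical: does the point's cell have density >= threshold?
#' @export
surface_contains <- function(surface, threshold, x, y) {
  i <- findInterval(x, surface$x - surface$cell_km / 2)
  j <- findInterval(y, surface$y - surface$cell_km / 2)
  ok <- i >= 1 & i <= length(surface$x) & j >= 1 & j <= length(surface$y)
  res <- rep(FALSE, length(x))
  res[ok] <- surface$z[cbind(i[ok], j[ok])] >= threshold
  res
}

#' Write occupancy contours as GeoJSON
#'
#' One Feature per contour ring, WGS84 coordinates, with `level`,
#' `captured_fraction` and optional extra properties.
#'
#' @param contours An `occupancy_contours` built with a projection.
#' @param path Output file.
#' @param properties Named list of extra properties for every feature.
#' @return `path`, invisibly.
#' @export
write_contours_geojson <- function(contours, path, properties = list()) {
  features <- list()
  for (ct in contours) {
    if (is.null(ct$polygons_geo)) {
      stop("contours lack geographic coordinates; rebuild with a projection",
           call. = FALSE)
    }
    for (ring in ct$polygons_geo) {
      if (nrow(ring) < 4) next
      if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
      props <- c(list(level = ct$level,
                      captured_fraction = round(ct$captured_fraction, 4)),
                 properties)
      features[[length(features) + 1]] <- list(
        type = "Feature",
        properties = props,
        geometry = list(type = "Polygon",
                        coordinates = list(unname(ring))))
    }
  }
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
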