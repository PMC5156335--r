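#' Implied speeds between consecutive positions
#'
#' Great-circle distance between each adjacent pair of positions divided by
#' the actual elapsed time (so multi-day gaps are handled by elapsed time,
#' not assumed to be one day).
#'
#' @param track Position data frame with `date`, `lat`, `lon` (complete
#'   coordinates, strictly increasing dates).
#' @param radius_km Sphere radius, km.
#' @return Data frame with one row per adjacent pair: `from`, `to` (dates),
#'   `km`, `days`, `speed_ms` (m/s).
#' @export
implied_speeds <- function(track, radius_km = 6371.0) {
  stopifnot(nrow(track) >= 2)
  d <- as.numeric(diff(track$date))
  if (any(d <= 0)) stop("duplicate or non-increasing dates in track", call. = FALSE)
  n <- nrow(track)
  km <- haversine_km(track$lat[-n], track$lon[-n],
                     track$lat[-1], track$lon[-1], radius_km)
  data.frame(from = track$date[-n], to = track$date[-1],
             km = km, days = d, speed_ms = km * 1000 / (d * 86400))
}

# Sustained-speed metric for every position: RMS (or max, strict mode) of
# implied speeds to all other retained positions within the sustain window.
sustained_metric <- function(track, sustain_hours, radius_km, strict = FALSE) {
  n <- nrow(track)
  tnum <- as.numeric(track$date)
  out <- numeric(n)
  win_days <- sustain_hours / 24
  for (i in seq_len(n)) {
    j <- which(abs(tnum - tnum[i]) <= win_days & seq_len(n) != i)
    if (length(j) == 0) { out[i] <- 0; next }
    km <- haversine_km(track$lat[i], track$lon[i], track$lat[j], track$lon[j],
                       radius_km)
    sp <- km * 1000 / (abs(tnum[j] - tnum[i]) * 86400)
    out[i] <- if (strict) max(sp) else sqrt(mean(sp^2))
  }
  out
}

#' Sustained-speed filter
#'
#' Iteratively removes the position with the largest sustained-speed metric
#' (root-mean-square of implied speeds to retained neighbours within the
#' sustain window; maximum pair speed in strict mode) until no position
#' exceeds `v_max`. Speeds are recomputed after each removal, so a single
#' spike is removed without dragging its neighbours out. Fixed colony
#' positions are never removed.
#'
#' @param track Position data frame for one bird (complete coordinates,
#'   increasing dates).
#' @param config A [pipeline_config()]; uses `v_max` (m/s), `sustain_hours`,
#'   `strict_pairwise`, `earth_radius_km`.
#' @return List with `kept` (the filtered track) and `removed` (rows flagged
#'   `speed_rejected = TRUE`).
#' @export
speed_filter <- function(track, config = pipeline_config()) {
  keep <- track
  removed <- track[0, ]
  repeat {
    if (nrow(keep) < 2) break
    m <- sustained_metric(keep, config$sustain_hours, config$earth_radius_km,
                          config$strict_pairwise)
    m[keep$source == "fixed_colony"] <- 0
    worst <- which.max(m)
    if (m[worst] <= config$v_max) break
    row <- keep[worst, ]
    row$speed_rejected <- TRUE
    removed <- rbind(removed, row)
    keep <- keep[-worst, ]
  }
  if (all(keep$source == "fixed_colony")) {
    warning("speed filter removed every non-fixed position", call. = FALSE)
  }
  rownames(keep) <- rownames(removed) <- NULL
  list(kept = keep, removed = removed)
}

#' Weighted moving-average track smoothing
#'
#' Replaces each interior position by the 1:2:1 weighted mean of the
#' previous, current and next positions (latitudes averaged directly,
#' longitudes averaged after unwrapping about the current position, so
#' antimeridian crossings smooth correctly). All positions are smoothed
#' simultaneously from the original neighbours. Not smoothed, but still used
#' as neighbours: the first and last position, fixed colony positions, and
#' positions whose movement to either neighbour exceeds the jump limits
#' (4 deg longitude or 6 deg latitude by default); the latter are flagged
#' `unsmoothed_jump`.
#'
#' @param track Position data frame (speed-filtered).
#' @param config A [pipeline_config()].
#' @return The smoothed track; altered rows carry `source = "smoothed"`.
#' @export
smooth_track <- function(track, config = pipeline_config()) {
  n <- nrow(track)
  if (n < 3) return(track)
  w <- config$smooth_weights / sum(config$smooth_weights)
  lat0 <- track$lat; lon0 <- track$lon
  out <- track
  for (i in 2:(n - 1)) {
    if (track$source[i] == "fixed_colony") next
    dlat_p <- lat0[i - 1] - lat0[i]
    dlat_n <- lat0[i + 1] - lat0[i]
    dlon_p <- norm_lon(lon0[i - 1] - lon0[i])
    dlon_n <- norm_lon(lon0[i + 1] - lon0[i])
    if (max(abs(c(dlon_p, dlon_n))) > config$jump_lon ||
        max(abs(c(dlat_p, dlat_n))) > config$jump_lat) {
      out$unsmoothed_jump[i] <- TRUE
      next
    }
    out$lat[i] <- lat0[i] + w[1] * dlat_p + w[3] * dlat_n
    out$lon[i] <- norm_lon(lon0[i] + w[1] * dlon_p + w[3] * dlon_n)
    out$source[i] <- "smoothed"
  }
  out
}
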