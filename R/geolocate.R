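#' Threshold-method geolocation of a bird's twilight records
#'
#' Converts one bird's twilight records into daily position estimates:
#' longitude from the sunrise/sunset midpoint, latitude from day length.
#' A fixed colony position (source `fixed_colony`) is prepended one day
#' before the first record, anchoring the track at the deployment site.
#' Because a High-Arctic colony sits in continuous daylight for part of the
#' deployment, the leading run of POLAR_DAY records (light consistent with
#' continued residency in the polar zone) is also held at the fixed colony
#' position, up to three days before the first twilight-resolved record --
#' the remaining gap lets the catch-up displacement spread over enough days
#' to stay under the speed filter while still being credited to migration.
#' Days without a usable position (polar sentinel en route, or no latitude
#' solution) keep a row with `NA` coordinates and the relevant flag so
#' downstream stages can account for every record.
#'
#' @param twilights Data frame with columns `bird_id`, `date`, `sunrise`,
#'   `sunset` (UTC decimal hours, `NA` when polar), `polar` (`"day"`,
#'   `"night"`, or `NA`) as returned by [read_twilights()] or
#'   [synthesize_twilights()]. One bird only.
#' @param config A [pipeline_config()].
#' @return A position data frame (one row per day plus the colony anchor)
#'   with columns `bird_id`, `date`, `lat`, `lon`, `source`,
#'   `equinox_flagged`, `polar_flagged`, `speed_rejected`, `unsmoothed_jump`.
#' @export
geolocate_twilights <- function(twilights, config = pipeline_config()) {
  stopifnot(nrow(twilights) >= 1)
  if (length(unique(twilights$bird_id)) != 1) {
    stop("geolocate_twilights processes one bird at a time", call. = FALSE)
  }
  tw <- twilights[order(twilights$date), ]
  n <- nrow(tw)
  lat <- lon <- rep(NA_real_, n)
  eqx <- pol <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!is.na(tw$polar[i])) {
      pol[i] <- TRUE
      next
    }
    lon[i] <- estimate_longitude(tw$sunrise[i], tw$sunset[i], tw$date[i])
    dl <- (tw$sunset[i] - tw$sunrise[i]) %% 24
    est <- estimate_latitude(dl, tw$date[i], config$sun_angle,
                             config$equinox_decl_deg)
    lat[i] <- est$lat
    eqx[i] <- est$equinox_flagged
    pol[i] <- est$polar_flagged
  }
  source <- rep("threshold", n)
  # leading polar-day run: hold at the colony until shortly before the
  # first twilight-resolved day
  lead <- which(cumprod(!is.na(tw$polar) & tw$polar == "day") == 1)
  if (length(lead) > 0 && length(lead) < n) {
    first_fix <- tw$date[length(lead) + 1L]
    fix <- lead[tw$date[lead] <= first_fix - 3]
    if (length(fix) > 0) {
      lat[fix] <- config$colony_lat
      lon[fix] <- config$colony_lon
      source[fix] <- "fixed_colony"
      pol[fix] <- FALSE
    }
  }
  out <- data.frame(
    bird_id = tw$bird_id[1],
    date = c(tw$date[1] - 1, tw$date),
    lat = c(config$colony_lat, lat),
    lon = c(config$colony_lon, lon),
    source = c("fixed_colony", source),
    equinox_flagged = c(FALSE, eqx),
    polar_flagged = c(FALSE, pol),
    speed_rejected = FALSE,
    unsmoothed_jump = FALSE,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# Pick the grid whose [period_start, period_start + period_days) covers date.
grid_for_date <- function(grids, date) {
  for (g in grids) {
    if (date >= g$period_start && date < g$period_start + g$period_days) {
      return(g)
    }
  }
  NULL
}

#' SST correction of one latitude estimate
#'
#' Refines a threshold latitude by matching tag-recorded SST to a satellite
#' composite along the (fixed) twilight longitude. The meridional SST
#' profile (averaged over the longitude cell and its two neighbours) is
#' scanned for latitudes where it crosses the tag value (linearly
#' interpolated between grid rows); where the profile merely plateaus
#' within `sst_tolerance` of the tag value, the plateau cells are the
#' candidates. The candidate nearest the previous day's latitude wins. The
#' search is limited to `sst_band_deg` around the threshold latitude except
#' on equinox-flagged days (or days without a threshold latitude), where
#' the whole grid is searched. Longitude is never altered.
#'
#' @param position One-row position data frame (see
#'   [geolocate_twilights()]).
#' @param tag_sst Tag minimum daily SST, deg C, or `NA`.
#' @param grid An `sst_grid` (see [read_sst_grid()]) covering the date.
#' @param previous_lat Latitude of the previous day's accepted position.
#' @param config A [pipeline_config()].
#' @return The position row, with `lat` and `source = "sst_corrected"` when a
#'   match was found; unchanged (plus `sst_unmatched` attribute semantics via
#'   `source`) otherwise.
#' @export
sst_correct_latitude <- function(position, tag_sst, grid, previous_lat,
                                 config = pipeline_config()) {
  if (is.na(tag_sst) || is.null(grid) || is.na(position$lon)) {
    return(position)
  }
  if (position$source == "fixed_colony") return(position)
  j <- which.min(abs(norm_lon(grid$lon - position$lon)))
  jj <- unique(pmin(pmax(j + (-1:1), 1L), length(grid$lon)))
  prof <- rowMeans(grid$values[, jj, drop = FALSE], na.rm = TRUE)
  lat_axis <- grid$lat
  use <- is.finite(prof)
  if (!is.na(position$lat) && !position$equinox_flagged) {
    use <- use & abs(lat_axis - position$lat) <= config$sst_band_deg
  }
  # candidate latitudes: exact crossings of the SST profile through the tag
  # value (linearly interpolated between grid rows), restricted to the band
  cand <- numeric(0)
  idx <- which(use)
  for (i in idx[idx < length(prof)]) {
    if (!use[i + 1] || !is.finite(prof[i]) || !is.finite(prof[i + 1])) next
    d1 <- prof[i] - tag_sst; d2 <- prof[i + 1] - tag_sst
    if (d1 == 0) cand <- c(cand, lat_axis[i])
    if (d1 * d2 < 0) {
      f <- d1 / (d1 - d2)
      cand <- c(cand, lat_axis[i] + f * (lat_axis[i + 1] - lat_axis[i]))
    }
  }
  if (length(idx) > 0 && is.finite(prof[idx[length(idx)]]) &&
      prof[idx[length(idx)]] == tag_sst) {
    cand <- c(cand, lat_axis[idx[length(idx)]])
  }
  if (length(cand) == 0) {
    # flat plateau within tolerance but no exact crossing
    near <- idx[abs(prof[idx] - tag_sst) <= config$sst_tolerance]
    cand <- lat_axis[near]
  }
  if (length(cand) == 0) return(position)
  prev <- if (is.na(previous_lat)) position$lat else previous_lat
  if (is.na(prev)) prev <- 0
  position$lat <- cand[which.min(abs(cand - prev))]
  position$source <- "sst_corrected"
  position
}

#' SST correction over a whole track
#'
#' Applies [sst_correct_latitude()] day by day, carrying the previous
#' accepted latitude forward as the disambiguation anchor.
#'
#' @param positions Position data frame for one bird.
#' @param sst_samples Data frame `bird_id`, `date`, `min_sst` for that bird.
#' @param grids List of `sst_grid` objects.
#' @param config A [pipeline_config()].
#' @return The position data frame with corrected latitudes.
#' @export
sst_correct_track <- function(positions, sst_samples, grids,
                              config = pipeline_config()) {
  half <- (config$sst_match_window - 1L) %/% 2L
  sst <- vapply(positions$date, function(d) {
    v <- sst_samples$min_sst[abs(as.numeric(sst_samples$date - d)) <= half]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  prev <- NA_real_
  for (i in seq_len(nrow(positions))) {
    g <- grid_for_date(grids, positions$date[i])
    row <- sst_correct_latitude(positions[i, ], sst[i], g, prev, config)
    positions[i, ] <- row
    if (!is.na(row$lat)) prev <- row$lat
  }
  positions
}
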