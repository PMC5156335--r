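#' Stopover/travel classification of daily movement
#'
#' Two-state machine over a daily-distance series. The bird starts in a
#' stopover state (it is at the breeding site). While in STOPOVER, the
#' forward window of `window` days anchored at the current day is examined:
#' if at least `count` of its days exceed `threshold` km/d, the state
#' becomes TRAVEL starting at the first exceeding day in that window. The
#' symmetric rule (at least `count` days under the threshold) returns the
#' bird to STOPOVER at the first sub-threshold day. Truncated windows at the
#' end of the series use the available days with the same count requirement.
#'
#' @param daily_km Numeric vector of per-day movement rates (km/d).
#' @param threshold Travel threshold, km/d.
#' @param window,count Sliding-window length and required count.
#' @return Character vector (`"STOPOVER"`/`"TRAVEL"`), same length as input.
#' @export
classify_days <- function(daily_km, threshold = 100, window = 5, count = 3) {
  n <- length(daily_km)
  stopifnot(n >= 1, count <= window)
  exceed <- daily_km > threshold
  states <- character(n)
  state <- "STOPOVER"
  i <- 1L
  while (i <= n) {
    win <- i:min(i + window - 1L, n)
    hits <- if (state == "STOPOVER") exceed[win] else !exceed[win]
    if (sum(hits) >= count) {
      j <- win[which(hits)[1]]
      if (j > i) states[i:(j - 1L)] <- state
      state <- if (state == "STOPOVER") "TRAVEL" else "STOPOVER"
      states[j] <- state
      i <- j + 1L
    } else {
      states[i] <- state
      i <- i + 1L
    }
  }
  states
}

#' Burst-travel adjustment of stopover classifications
#'
#' Reclassifies short bursts the sliding-window rule cannot catch: a run of
#' one or two consecutive STOPOVER days that each exceed the travel
#' threshold, and whose removal separates the surrounding stopover positions
#' into clusters whose centroids are more than `burst_factor * seg_threshold`
#' km apart, is relabelled TRAVEL. The symmetric cleanup is applied too:
#' a 1-2 day TRAVEL run between stopovers whose centroids are closer than
#' the same criterion is a spurious (noise-triggered) transition and
#' reverts to STOPOVER. Together these automate the manual "fast and far
#' for 1-2 d" screening step.
#'
#' @param states Output of [classify_days()].
#' @param daily_km The daily-distance series the states were built from.
#' @param lat,lon Position coordinates aligned with `states`.
#' @param config A [pipeline_config()].
#' @param prune_spurious_travel Apply the symmetric cleanup (default TRUE).
#' @return List with `states` (adjusted) and `burst_adjusted` (logical).
#' @export
adjust_bursts <- function(states, daily_km, lat, lon,
                          config = pipeline_config(),
                          prune_spurious_travel = TRUE) {
  n <- length(states)
  burst <- rep(FALSE, n)
  exceed <- daily_km > config$seg_threshold
  r <- rle(states == "STOPOVER" & exceed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] || r$lengths[k] > 2) next
    a <- starts[k]; b <- ends[k]
    # contiguous stopover days on either side of the run
    pre <- integer(0)
    i <- a - 1L
    while (i >= 1 && states[i] == "STOPOVER") { pre <- c(pre, i); i <- i - 1L }
    post <- integer(0)
    i <- b + 1L
    while (i <= n && states[i] == "STOPOVER") { post <- c(post, i); i <- i + 1L }
    if (length(pre) == 0 || length(post) == 0) next
    c1 <- c(mean(lat[pre]), mean(lon[pre]))
    c2 <- c(mean(lat[post]), mean(lon[post]))
    gap <- haversine_km(c1[1], c1[2], c2[1], c2[2], config$earth_radius_km)
    if (gap > config$burst_factor * config$seg_threshold) {
      states[a:b] <- "TRAVEL"
      burst[a:b] <- TRUE
    }
  }
  if (prune_spurious_travel) {
    r <- rle(states)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$lengths)) {
      if (r$values[k] != "TRAVEL" || r$lengths[k] > 2) next
      if (k == 1 || k == length(r$values)) next
      if (any(burst[starts[k]:ends[k]])) next
      pre <- starts[k - 1]:ends[k - 1]
      post <- starts[k + 1]:ends[k + 1]
      gap <- haversine_km(mean(lat[pre]), mean(lon[pre]),
                          mean(lat[post]), mean(lon[post]),
                          config$earth_radius_km)
      if (gap <= config$burst_factor * config$seg_threshold) {
        states[starts[k]:ends[k]] <- "STOPOVER"
      }
    }
    # trim travel-run edge days that move at less than half the run's own
    # rate: 1:2:1 smoothing drags the stopover day adjacent to a travel leg
    # about a quarter of the leg length, which can push it just over the
    # threshold; a day travelling far slower than its run is not travel
    r <- rle(states)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$lengths)) {
      if (r$values[k] != "TRAVEL" || r$lengths[k] < 3) next
      run <- starts[k]:ends[k]
      for (side in 1:2) {
        for (trim in 1:2) {
          run_now <- run[states[run] == "TRAVEL"]
          if (length(run_now) < 3) break
          edge <- if (side == 1) run_now[1] else run_now[length(run_now)]
          if (burst[edge]) break
          if (daily_km[edge] < 0.5 * mean(daily_km[run_now])) {
            states[edge] <- "STOPOVER"
          } else break
        }
      }
    }
  }
  list(states = states, burst_adjusted = burst)
}

#' Infer the wintering basin of a track
#'
#' Pacific or Atlantic, from the winter-position centroid longitude when
#' winter positions exist, otherwise from the net east-west displacement
#' accumulated along the track (westward migration out of the Canadian
#' Arctic leads to the Pacific, eastward to the Atlantic).
#'
#' @param track Position data frame.
#' @param states Optional state vector aligned with `track` rows.
#' @return `"PACIFIC"` or `"ATLANTIC"`.
#' @export
infer_basin <- function(track, states = NULL) {
  south <- !is.na(track$lat) & track$lat < 0
  if (!is.null(states)) south <- south & states == "STOPOVER"
  if (any(south)) {
    lon <- mean(norm_lon(track$lon[south]))
    return(if (lon < -30) "PACIFIC" else "ATLANTIC")
  }
  dlon <- norm_lon(diff(track$lon[!is.na(track$lon)]))
  if (sum(dlon) < 0) "PACIFIC" else "ATLANTIC"
}

#' Wintering area from pooled winter positions
#'
#' Kernel density of the pooled post-migration stopover positions of a basin
#' in its equal-area projection, bounded by the 50% occupancy contour. This
#' is the first pass of the two-pass arrival bootstrap: the area is derived
#' without an arrival rule (all Southern-Hemisphere stopover positions
#' pooled), then arrival dates are re-derived against the polygon.
#'
#' @param winter_positions Data frame with `lat`, `lon` of pooled positions.
#' @param basin `"PACIFIC"` or `"ATLANTIC"` (names the projection preset and
#'   error messages).
#' @param config A [pipeline_config()].
#' @param min_positions Minimum pooled positions required.
#' @return An object of class `wintering_area`: the kernel surface, its
#'   projection, the occupancy contours, and the 50% membership test.
#' @export
define_wintering_area <- function(winter_positions, basin,
                                  config = pipeline_config(),
                                  min_positions = 30) {
  if (nrow(winter_positions) < min_positions) {
    stop("too few pooled winter positions for basin ", basin, " (",
         nrow(winter_positions), " < ", min_positions, ")", call. = FALSE)
  }
  proj <- to_equal_area(winter_positions$lat, winter_positions$lon,
                        region_hint = basin,
                        radius_km = config$earth_radius_km)
  surf <- kernel_density(proj$x, proj$y,
                         bandwidth_km = config$kde_bandwidth_km,
                         cell_km = config$kde_cell_km)
  contours <- occupancy_contours(surf, levels = config$contour_levels,
                                 projection = proj$projection)
  structure(list(basin = basin, projection = proj$projection,
                 surface = surf, contours = contours),
            class = "wintering_area")
}

#' Test whether positions fall inside a wintering area
#'
#' Membership in the 50% occupancy region, evaluated on the kernel surface
#' grid (the same thresholded cells the contour polygons trace).
#'
#' @param area A `wintering_area`.
#' @param lat,lon Positions, degrees.
#' @param level Occupancy level (percent), default 50.
#' @return Logical vector.
#' @export
in_wintering_area <- function(area, lat, lon, level = 50) {
  p <- albers_forward(area$projection, lat, lon)
  surface_contains(area$surface, contour_threshold(area$contours, level),
                   p$x, p$y)
}

#' @export
print.wintering_area <- function(x, ...) {
  cat(sprintf("<wintering_area> basin %s; %d x %d cells; levels %s%%\n",
              x$basin, length(x$surface$x), length(x$surface$y),
              paste(vapply(x$contours, `[[`, 0, "level"), collapse = "/")))
  invisible(x)
}

#' Split a classified track into breeding, fall migration and winter
#'
#' Departure is the first TRAVEL day after the initial breeding-site
#' stopover; arrival is the first STOPOVER day whose position falls inside
#' the wintering area. Days before departure are BREEDING, days from
#' departure to the day before arrival are FALL_MIGRATION, and days from
#' arrival on are WINTER. A track that never enters the polygon (for
#' example, a tag that failed mid-ocean) gets a departure but no arrival
#' (direction-only record).
#'
#' @param track Position data frame.
#' @param states State vector aligned with `track` rows.
#' @param wintering_area A `wintering_area`, or `NULL` (arrival undefined).
#' @return List: `phase` (character per row), `departure`, `arrival`
#'   (`Date` or `NA`), `has_migration`.
#' @export
split_phases <- function(track, states, wintering_area = NULL) {
  n <- nrow(track)
  stopifnot(length(states) == n)
  travel_idx <- which(states == "TRAVEL")
  if (length(travel_idx) == 0) {
    return(list(phase = rep("BREEDING", n), departure = as.Date(NA),
                arrival = as.Date(NA), has_migration = FALSE))
  }
  dep_i <- travel_idx[1]
  departure <- track$date[dep_i]
  arr_i <- NA_integer_
  if (!is.null(wintering_area)) {
    cand <- which(states == "STOPOVER" & seq_len(n) > dep_i & !is.na(track$lat))
    if (length(cand) > 0) {
      inside <- in_wintering_area(wintering_area, track$lat[cand], track$lon[cand])
      if (any(inside)) arr_i <- cand[inside][1]
    }
  }
  phase <- rep("BREEDING", n)
  if (is.na(arr_i)) {
    phase[seq_len(n) >= dep_i] <- "FALL_MIGRATION"
    arrival <- as.Date(NA)
  } else {
    phase[seq_len(n) >= dep_i & seq_len(n) < arr_i] <- "FALL_MIGRATION"
    phase[seq_len(n) >= arr_i] <- "WINTER"
    arrival <- track$date[arr_i]
  }
  list(phase = phase, departure = departure, arrival = arrival,
       has_migration = TRUE)
}
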