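#' Synthetic sea-surface temperature field
#'
#' Analytic SST field used by the simulator in place of satellite
#' composites. The default profile is linear in latitude
#' (`base_temp + gradient * lat`) with a gradient of -0.3 deg C per degree:
#' strictly monotone (so SST uniquely identifies latitude along a
#' meridian), informative everywhere the simulated birds fly, and within
#' the physical range [-2, 40] deg C over the whole grid domain the birds
#' occupy. A bounded logistic profile (monotone, asymptoting at
#' `t_cold`/`t_warm`) is also available. A small additive seasonal cycle is
#' time-only, so monotonicity in latitude is preserved within any
#' composite period.
#'
#' @param profile `"linear"` or `"logistic"`.
#' @param base_temp,gradient Intercept (deg C) and slope (deg C per degree
#'   latitude) of the linear profile.
#' @param t_warm,t_cold Asymptotic warm/cold temperatures, deg C (logistic).
#' @param mid_lat,width_deg Logistic midpoint latitude and e-folding width.
#' @param seasonal_amp Amplitude of the seasonal cycle, deg C.
#' @param seasonal_peak_doy Day of year of the seasonal maximum.
#' @param noise_sd Per-cell grid noise, deg C.
#' @return A list of class `sst_field_spec`.
#' @export
sst_field_spec <- function(profile = c("linear", "logistic"),
                           base_temp = 20.9, gradient = -0.3,
                           t_warm = 28, t_cold = -2,
                           mid_lat = 25, width_deg = 10,
                           seasonal_amp = 1, seasonal_peak_doy = 60,
                           noise_sd = 0.1) {
  profile <- match.arg(profile)
  if (profile == "linear" && gradient == 0) {
    stop("linear SST field requires a non-zero meridional gradient",
         call. = FALSE)
  }
  structure(list(profile = profile, t_warm = t_warm, t_cold = t_cold,
                 mid_lat = mid_lat, width_deg = width_deg,
                 base_temp = base_temp, gradient = gradient,
                 seasonal_amp = seasonal_amp,
                 seasonal_peak_doy = seasonal_peak_doy,
                 noise_sd = noise_sd),
            class = "sst_field_spec")
}

#' Evaluate the synthetic SST field
#'
#' @param field An [sst_field_spec()].
#' @param lat Latitude(s), degrees.
#' @param date `Date` (drives the seasonal term); a single date or one per
#'   latitude.
#' @return SST in deg C (noise-free).
#' @export
sst_field_value <- function(field, lat, date) {
  base <- if (field$profile == "logistic") {
    field$t_cold + (field$t_warm - field$t_cold) /
      (1 + exp((lat - field$mid_lat) / field$width_deg))
  } else {
    field$base_temp + field$gradient * lat
  }
  doy <- as.integer(format(as.Date(date), "%j"))
  base + field$seasonal_amp * cos(2 * pi * (doy - field$seasonal_peak_doy) / 365.25)
}

#' Simulation configuration
#'
#' Study conditions for the synthetic cohort: a High-Arctic colony at
#' 75.8 N, 96.3 W, fall departures in August, coastal great-circle routes of
#' roughly 14,600 km to a Humboldt-like Pacific or Benguela-like Atlantic
#' wintering centre, ~350 km/d travel days alternating with week-scale
#' stopovers (total fall duration about 84 days), then a wandering wintering
#' residency. Twilight noise of 4 min and tag-SST noise of 0.3 deg C give
#' position errors comparable to published geolocator accuracy.
#'
#' @param colony_lat,colony_lon Colony coordinates, degrees.
#' @param track_start First tracked day (`Date`).
#' @param dep_start,dep_span Departure drawn uniformly from `dep_start` +
#'   0..`dep_span` days.
#' @param speed_mean,speed_sd,speed_range Travel-speed distribution, km/d
#'   (normal, truncated to the range).
#' @param stopover_n_range,stopover_dur_range Number of en-route stopovers
#'   and their duration range, days.
#' @param stopover_jitter_km Daily position jitter within a stopover, km.
#' @param stopover_min_sep_km Minimum along-route separation of stopovers.
#' @param burst_prob Probability that one stopover is split by a 1-day burst
#'   relocation.
#' @param burst_gap_range Burst relocation distance range, km.
#' @param winter_days_range Wintering residency length, days.
#' @param winter_step_km,winter_cap_km,winter_radius_km Winter random-walk
#'   daily step s.d., hard per-day cap (kept below the segmentation
#'   threshold so truth labels stay a valid oracle), and reflecting radius
#'   about the wintering centre.
#' @param winter_center_jitter_km Per-bird scatter (s.d., km) of individual
#'   wintering centres about the basin centre (site fidelity with
#'   individual variation).
#' @param winter_drift_kmd Slow southward drift of the winter range through
#'   the season (km/d), emulating movement along the upwelling current; the
#'   combined daily displacement is still capped at `winter_cap_km`.
#' @param twilight_sd_min Gaussian noise s.d. on each twilight time, min.
#' @param tag_sst_sd Tag SST noise s.d., deg C.
#' @param sst_missing_rate Fraction of tag-SST days missing.
#' @param grid_res_deg,grid_lat_range SST-grid resolution and latitude span.
#' @param field An [sst_field_spec()].
#' @param wintering_centers Named list of basin centres (`lat`, `lon`).
#' @param routes Named list of waypoint matrices (columns lat, lon) from the
#'   colony to each basin centre; `NULL` uses the built-in coastal routes.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(colony_lat = 75.8, colony_lon = -96.3,
                       track_start = as.Date("2010-07-15"),
                       dep_start = as.Date("2010-08-05"), dep_span = 29,
                       speed_mean = 350, speed_sd = 35,
                       speed_range = c(260, 480),
                       stopover_n_range = c(3, 5),
                       stopover_dur_range = c(7, 15),
                       stopover_jitter_km = 8,
                       stopover_min_sep_km = 150,
                       burst_prob = 0.3, burst_gap_range = c(300, 500),
                       winter_days_range = c(40, 60),
                       winter_step_km = 45, winter_cap_km = 95,
                       winter_radius_km = 600,
                       winter_center_jitter_km = 0,
                       winter_drift_kmd = 0,
                       twilight_sd_min = 4, tag_sst_sd = 0.3,
                       sst_missing_rate = 0.05,
                       grid_res_deg = 1, grid_lat_range = c(-45, 84),
                       field = sst_field_spec(),
                       wintering_centers = list(
                         PACIFIC = c(lat = -10, lon = -85),
                         ATLANTIC = c(lat = -25, lon = 10)),
                       routes = NULL) {
  if (is.null(routes)) {
    routes <- list(
      # westward through the Canadian Arctic and Bering Strait, then down the
      # eastern Pacific to the Humboldt upwelling (~14,630 km)
      PACIFIC = rbind(
        c(colony_lat, colony_lon),
        c(71, -120), c(68, -145), c(64.5, -164), c(56, -161),
        c(47, -140), c(38, -126), c(28, -115), c(18, -104),
        c(8, -85), c(-2, -82),
        unname(wintering_centers$PACIFIC)),
      # eastward over Baffin Bay and the North Atlantic, then down the West
      # African coast to the Benguela upwelling (~14,660 km)
      ATLANTIC = rbind(
        c(colony_lat, colony_lon),
        c(74, -80), c(70, -62), c(64, -54), c(59, -44),
        c(52, -37), c(44, -28), c(40, -19), c(32, -25),
        c(24, -19), c(16, -21), c(7, -13), c(0, -3),
        c(-8, 5), c(-16, 10),
        unname(wintering_centers$ATLANTIC)))
  }
  structure(list(colony_lat = colony_lat, colony_lon = norm_lon(colony_lon),
                 track_start = track_start, dep_start = dep_start,
                 dep_span = dep_span,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 speed_range = speed_range,
                 stopover_n_range = stopover_n_range,
                 stopover_dur_range = stopover_dur_range,
                 stopover_jitter_km = stopover_jitter_km,
                 stopover_min_sep_km = stopover_min_sep_km,
                 burst_prob = burst_prob, burst_gap_range = burst_gap_range,
                 winter_days_range = winter_days_range,
                 winter_step_km = winter_step_km,
                 winter_cap_km = winter_cap_km,
                 winter_radius_km = winter_radius_km,
                 winter_center_jitter_km = winter_center_jitter_km,
                 winter_drift_kmd = winter_drift_kmd,
                 twilight_sd_min = twilight_sd_min, tag_sst_sd = tag_sst_sd,
                 sst_missing_rate = sst_missing_rate,
                 grid_res_deg = grid_res_deg, grid_lat_range = grid_lat_range,
                 field = field, wintering_centers = wintering_centers,
                 routes = routes),
            class = "sim_config")
}

route_length_km <- function(route, radius_km = 6371.0) {
  n <- nrow(route)
  if (n < 2) return(0)
  sum(haversine_km(route[-n, 1], route[-n, 2], route[-1, 1], route[-1, 2],
                   radius_km))
}

draw_trunc_norm <- function(mean, sd, range) {
  for (i in 1:100) {
    v <- stats::rnorm(1, mean, sd)
    if (v >= range[1] && v <= range[2]) return(v)
  }
  mean
}

#' Simulate one bird's itinerary
#'
#' Generates ground-truth daily positions and behavioural states: a breeding
#' residency at the colony, travel legs following the basin's great-circle
#' waypoint route at a bird-specific daily speed, en-route stopovers
#' (optionally split by a 1-day burst relocation), and a winter random walk
#' about the basin centre. Travel-day displacements always exceed the
#' 100 km/d segmentation threshold and stopover/winter displacements always
#' stay below it, so the truth labels are a valid oracle for segmentation.
#'
#' @param bird_id Identifier.
#' @param destination `"PACIFIC"` or `"ATLANTIC"`.
#' @param sim A [sim_config()].
#' @param seed Optional integer seed (reproducible itineraries).
#' @return A list of class `itinerary`: `bird_id`, `destination`, `daily`
#'   (data frame `date`, `lat`, `lon`, `state`, `leg`), `departure`,
#'   `arrival`, `speed_kmd`, `route_km`, `travel_km`.
#' @export
simulate_itinerary <- function(bird_id, destination, sim = sim_config(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  route <- sim$routes[[destination]]
  if (is.null(route)) stop("unknown destination ", destination, call. = FALSE)
  # per-bird wintering centre: jittered about the basin centre, the travel
  # route is re-aimed at it
  if (sim$winter_center_jitter_km > 0 && route_length_km(route) >= 1) {
    off <- stats::rnorm(2, 0, sim$winter_center_jitter_km)
    ctr0 <- route[nrow(route), ]
    route[nrow(route), ] <- offset_km(ctr0[1], ctr0[2], off[1], off[2])
  }
  winter_center <- route[nrow(route), ]
  D <- route_length_km(route)
  departure <- sim$dep_start + sample.int(sim$dep_span + 1, 1) - 1L
  winter_days <- sample(seq(sim$winter_days_range[1],
                            sim$winter_days_range[2]), 1)
  dates <- list(); lats <- list(); lons <- list()
  states <- list(); legs <- list()
  push <- function(date, lat, lon, state, leg) {
    k <- length(dates) + 1
    dates[[k]] <<- date; lats[[k]] <<- lat; lons[[k]] <<- lon
    states[[k]] <<- state; legs[[k]] <<- leg
  }
  # breeding residency at the colony
  breeding <- seq(sim$track_start, departure - 1, by = "day")
  push(breeding, rep(sim$colony_lat, length(breeding)),
       rep(sim$colony_lon, length(breeding)),
       rep("STOPOVER", length(breeding)), rep("breeding", length(breeding)))
  cur <- departure
  if (D < 1) {
    # degenerate destination: stay put, winter at the colony
    winter <- seq(cur, by = "day", length.out = winter_days)
    push(winter, rep(sim$colony_lat, winter_days),
         rep(sim$colony_lon, winter_days),
         rep("STOPOVER", winter_days), rep("winter", winter_days))
  } else {
    speed <- draw_trunc_norm(sim$speed_mean, sim$speed_sd, sim$speed_range)
    if (speed * 200 < D) stop("configured speed too low to reach destination",
                              call. = FALSE)
    k_range <- seq(sim$stopover_n_range[1], sim$stopover_n_range[2])
    k <- if (length(k_range) == 1) k_range else sample(k_range, 1)
    stop_d <- numeric(0)
    if (k > 0) {
      for (try in 1:200) {
        cand <- sort(stats::runif(k, 0.08 * D, 0.92 * D))
        if (all(diff(c(0, cand, D)) >= sim$stopover_min_sep_km)) {
          stop_d <- cand
          break
        }
      }
    }
    durs <- if (k > 0)
      sample(seq(sim$stopover_dur_range[1], sim$stopover_dur_range[2]),
             length(stop_d), replace = TRUE) else integer(0)
    bursts <- rep(FALSE, length(stop_d))
    if (length(stop_d) > 0 && stats::runif(1) < sim$burst_prob) {
      gap <- stats::runif(1, sim$burst_gap_range[1], sim$burst_gap_range[2])
      i <- sample(length(stop_d), 1)
      if (stop_d[i] + gap < 0.95 * D &&
          (i == length(stop_d) || stop_d[i + 1] - stop_d[i] - gap >
             sim$stopover_min_sep_km)) {
        # split stopover i: half before a one-day burst hop, half after
        stop_d <- append(stop_d, stop_d[i] + gap, after = i)
        d2 <- max(2, durs[i] %/% 2)
        durs <- append(durs, d2, after = i)
        durs[i] <- max(2, durs[i] - d2)
        bursts <- append(bursts, FALSE, after = i)
        bursts[i + 1] <- TRUE  # reached by a burst hop
      }
    }
    seg_start <- c(0, stop_d)
    seg_end <- c(stop_d, D)
    for (s in seq_along(seg_start)) {
      L <- seg_end[s] - seg_start[s]
      burst_leg <- s <= length(bursts) && bursts[s]
      if (L > 0.5) {
        nd <- if (burst_leg) 1L else max(1L, as.integer(ceiling(L / speed)))
        dd <- L / nd
        pos <- route_point(route[, 1], route[, 2],
                           seg_start[s] + dd * seq_len(nd))
        days <- seq(cur, by = "day", length.out = nd)
        push(days, pos[, "lat"], pos[, "lon"], rep("TRAVEL", nd),
             rep(if (burst_leg) "burst" else "travel", nd))
        cur <- cur + nd
      }
      if (s <= length(stop_d)) {
        ctr <- route_point(route[, 1], route[, 2], stop_d[s])
        nd <- durs[s]
        off <- matrix(stats::rnorm(2 * nd, 0, sim$stopover_jitter_km), ncol = 2)
        pos <- offset_km(rep(ctr[1, "lat"], nd), rep(ctr[1, "lon"], nd),
                         off[, 1], off[, 2])
        days <- seq(cur, by = "day", length.out = nd)
        push(days, pos[, "lat"], pos[, "lon"], rep("STOPOVER", nd),
             rep("stopover", nd))
        cur <- cur + nd
      }
    }
    # winter: reflected random walk about the bird's wintering centre
    ctr <- c(lat = winter_center[1], lon = winter_center[2])
    wlat <- numeric(winter_days); wlon <- numeric(winter_days)
    px <- 0; py <- 0; last_x <- 0; last_y <- 0
    for (d in seq_len(winter_days)) {
      step <- stats::rnorm(2, 0, sim$winter_step_km)
      nx <- px + step[1]; ny <- py + step[2]
      r <- sqrt(nx^2 + ny^2)
      if (r > sim$winter_radius_km) {
        nx <- nx * (2 * sim$winter_radius_km - r) / r
        ny <- ny * (2 * sim$winter_radius_km - r) / r
      }
      # absolute displacement this day, including the southward range drift
      dx <- nx - last_x
      dy <- (ny - sim$winter_drift_kmd * d) - last_y
      dn <- sqrt(dx^2 + dy^2)
      if (dn > sim$winter_cap_km) {
        dx <- dx * sim$winter_cap_km / dn
        dy <- dy * sim$winter_cap_km / dn
      }
      last_x <- last_x + dx; last_y <- last_y + dy
      px <- nx; py <- ny
      p <- offset_km(ctr["lat"], ctr["lon"], last_x, last_y)
      wlat[d] <- p[1, "lat"]; wlon[d] <- p[1, "lon"]
    }
    winter <- seq(cur, by = "day", length.out = winter_days)
    push(winter, wlat, wlon, rep("STOPOVER", winter_days),
         rep("winter", winter_days))
  }
  daily <- data.frame(date = do.call(c, dates),
                      lat = unlist(lats), lon = unlist(lons),
                      state = unlist(states), leg = unlist(legs),
                      stringsAsFactors = FALSE)
  n <- nrow(daily)
  disp <- c(0, haversine_km(daily$lat[-n], daily$lon[-n],
                            daily$lat[-1], daily$lon[-1]))
  arrival <- if (any(daily$leg == "winter")) daily$date[daily$leg == "winter"][1]
             else as.Date(NA)
  fall <- !is.na(arrival) & daily$date >= departure & daily$date < arrival
  travel_km <- sum(disp[daily$state == "TRAVEL" & fall])
  structure(list(bird_id = bird_id, destination = destination, daily = daily,
                 departure = if (D < 1) as.Date(NA) else departure,
                 arrival = arrival,
                 speed_kmd = if (D < 1) NA_real_ else
                   travel_km / sum(daily$state == "TRAVEL" & fall),
                 route_km = D, travel_km = travel_km),
            class = "itinerary")
}

#' @export
print.itinerary <- function(x, ...) {
  cat(sprintf("<itinerary> %s -> %s: %d days, departure %s, arrival %s, %.0f km\n",
              x$bird_id, x$destination, nrow(x$daily),
              format(x$departure), format(x$arrival), x$travel_km))
  invisible(x)
}

#' Synthesize twilight records from an itinerary
#'
#' Forward solar model at the true daily position plus independent Gaussian
#' noise on each twilight time; polar day/night produce sentinels.
#'
#' @param itinerary An [simulate_itinerary()] result.
#' @param sun_angle Twilight sun elevation angle, degrees.
#' @param noise_sd_minutes Noise s.d. per twilight, minutes.
#' @param seed Optional seed.
#' @return Twilight data frame (`bird_id`, `date`, `sunrise`, `sunset`,
#'   `polar`, `valid`).
#' @export
synthesize_twilights <- function(itinerary, sun_angle = -3.44,
                                 noise_sd_minutes = 4, seed = NULL) {
  stopifnot(noise_sd_minutes >= 0)
  if (!is.null(seed)) set.seed(seed)
  d <- itinerary$daily
  n <- nrow(d)
  sr <- ss <- rep(NA_real_, n)
  polar <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tw <- twilight_forward(d$lat[i], d$lon[i], d$date[i], sun_angle)
    polar[i] <- tw$polar
    if (is.na(tw$polar)) {
      sr[i] <- (tw$sunrise + stats::rnorm(1, 0, noise_sd_minutes / 60)) %% 24
      ss[i] <- (tw$sunset + stats::rnorm(1, 0, noise_sd_minutes / 60)) %% 24
    }
  }
  data.frame(bird_id = itinerary$bird_id, date = d$date,
             sunrise = sr, sunset = ss, polar = polar, valid = TRUE,
             stringsAsFactors = FALSE)
}

#' Synthesize tag SST samples and satellite-style grids
#'
#' Tag samples are the analytic field at the true position plus noise
#' (clamped to the physical range, occasional missing days); grids are the
#' field evaluated per 8-day composite period on a regular lat/lon raster.
#'
#' @param itinerary An [simulate_itinerary()] result.
#' @param sim A [sim_config()] (field spec, noise, grid geometry).
#' @param seed Optional seed.
#' @param grids If `FALSE`, only tag samples are generated.
#' @param lon_range Grid longitude span (degrees, default global).
#' @return List with `samples` (data frame `bird_id`, `date`, `min_sst`) and
#'   `grids` (list of `sst_grid`).
#' @export
synthesize_sst <- function(itinerary, sim = sim_config(), seed = NULL,
                           grids = TRUE, lon_range = c(-180, 179)) {
  if (!is.null(seed)) set.seed(seed)
  d <- itinerary$daily
  truth <- sst_field_value(sim$field, d$lat, d$date)
  sst <- pmin(pmax(truth + stats::rnorm(nrow(d), 0, sim$tag_sst_sd), -2), 40)
  sst[stats::runif(nrow(d)) < sim$sst_missing_rate] <- NA_real_
  samples <- data.frame(bird_id = itinerary$bird_id, date = d$date,
                        min_sst = sst, stringsAsFactors = FALSE)
  glist <- if (grids) {
    synthesize_sst_grids(range(d$date), sim, lon_range = lon_range)
  } else list()
  list(samples = samples, grids = glist)
}

#' Synthesize the 8-day composite grid stack for a date range
#'
#' @param date_range Length-2 `Date` vector to cover.
#' @param sim A [sim_config()].
#' @param lon_range Grid longitude span, degrees.
#' @return List of `sst_grid` objects (consecutive 8-day periods).
#' @export
synthesize_sst_grids <- function(date_range, sim = sim_config(),
                                 lon_range = c(-180, 179)) {
  lat_axis <- seq(sim$grid_lat_range[1], sim$grid_lat_range[2],
                  by = sim$grid_res_deg)
  lon_axis <- seq(lon_range[1], lon_range[2], by = sim$grid_res_deg)
  starts <- seq(as.Date(date_range[1]), as.Date(date_range[2]), by = 8)
  lapply(starts, function(p0) {
    mid <- p0 + 4
    prof <- sst_field_value(sim$field, lat_axis, mid)
    vals <- matrix(rep(prof, length(lon_axis)), nrow = length(lat_axis))
    if (sim$field$noise_sd > 0) {
      vals <- vals + stats::rnorm(length(vals), 0, sim$field$noise_sd)
    }
    new_sst_grid(p0, 8L, lat_axis, lon_axis, vals)
  })
}

#' Simulate a cohort of tracked birds
#'
#' Draws per-bird itineraries and the observational data the pipeline
#' consumes (twilights, tag SST, one shared grid stack), with all
#' randomness flowing from one seed.
#'
#' @param n_pacific,n_atlantic Number of birds per wintering basin.
#' @param sim A [sim_config()].
#' @param seed Integer seed.
#' @param truncate_frac Fraction of birds whose record is truncated
#'   mid-migration (tag failure before arrival), default 0.
#' @return A list of class `gls_cohort`: `birds` (data frame), `truth`
#'   (named list of itineraries), `twilights`, `sst_samples`, `grids`.
#' @export
simulate_cohort <- function(n_pacific = 8, n_atlantic = 2,
                            sim = sim_config(), seed = 1,
                            truncate_frac = 0) {
  set.seed(seed)
  dest <- c(rep("PACIFIC", n_pacific), rep("ATLANTIC", n_atlantic))
  ids <- sprintf("bird%02d", seq_along(dest))
  n_trunc <- round(truncate_frac * length(ids))
  trunc_ids <- if (n_trunc > 0) sample(ids, n_trunc) else character(0)
  truth <- list(); tw <- list(); sst <- list()
  for (i in seq_along(ids)) {
    it <- simulate_itinerary(ids[i], dest[i], sim)
    if (ids[i] %in% trunc_ids && !is.na(it$arrival)) {
      cut <- it$departure + as.integer(0.5 * (it$arrival - it$departure))
      it$daily <- it$daily[it$daily$date <= cut, ]
      it$arrival <- as.Date(NA)
      it$truncated <- TRUE
    } else {
      it$truncated <- FALSE
    }
    truth[[ids[i]]] <- it
    tw[[i]] <- synthesize_twilights(it, noise_sd_minutes = sim$twilight_sd_min)
    sst[[i]] <- synthesize_sst(it, sim, grids = FALSE)$samples
  }
  all_dates <- range(do.call(c, lapply(truth, function(x) range(x$daily$date))))
  grids <- synthesize_sst_grids(all_dates, sim)
  structure(list(
    birds = data.frame(bird_id = ids, destination = dest,
                       truncated = ids %in% trunc_ids,
                       stringsAsFactors = FALSE),
    truth = truth,
    twilights = do.call(rbind, tw),
    sst_samples = do.call(rbind, sst),
    grids = grids,
    sim = sim, seed = seed), class = "gls_cohort")
}

#' @export
print.gls_cohort <- function(x, ...) {
  cat(sprintf("<gls_cohort> %d birds (%d Pacific, %d Atlantic), %d twilight records, %d grids\n",
              nrow(x$birds), sum(x$birds$destination == "PACIFIC"),
              sum(x$birds$destination == "ATLANTIC"),
              nrow(x$twilights), length(x$grids)))
  invisible(x)
}
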