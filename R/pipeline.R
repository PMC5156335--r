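#' Run the full geolocator processing pipeline
#'
#' Chains the processing stages in their fixed order for every bird:
#' threshold geolocation, SST latitude correction, sustained-speed
#' filtering, 1:2:1 smoothing, stopover/travel segmentation with burst
#' adjustment, pooled wintering-area kernel densities per basin, phase
#' splitting against the 50% occupancy contour, and per-bird migration
#' summaries. A bird whose record collapses at some stage (for example a
#' tag that failed at the colony) is recorded as failed and the pipeline
#' continues with the rest.
#'
#' @param twilights Twilight data frame for all birds, or a `gls_cohort`
#'   from [simulate_cohort()] (in which case the remaining data arguments
#'   are taken from it).
#' @param sst_samples Tag SST data frame for all birds.
#' @param grids List of `sst_grid` objects.
#' @param config A [pipeline_config()].
#' @return An object of class `gls_pipeline`: `tracks` and `day_states`
#'   (named lists), `wintering_areas`, `summary` (one row per bird),
#'   `tests` (between-basin Welch tests, when both basins have two or more
#'   complete tracks), `stage_log`, `failed`, `config`.
#' @export
run_pipeline <- function(twilights, sst_samples = NULL, grids = NULL,
                         config = pipeline_config()) {
  if (inherits(twilights, "gls_cohort")) {
    cohort <- twilights
    sst_samples <- cohort$sst_samples
    grids <- cohort$grids
    twilights <- cohort$twilights
  }
  birds <- unique(twilights$bird_id)
  if (length(birds) == 0) stop("no twilight records supplied", call. = FALSE)
  tracks <- list(); day_states <- list(); phase_list <- list()
  stage_log <- list(); failed <- character(0)
  log_stage <- function(bird, stage, n_in, n_removed) {
    stage_log[[length(stage_log) + 1]] <<- list(
      bird_id = bird, stage = stage, n_in = n_in,
      n_removed = n_removed, n_out = n_in - n_removed)
  }
  for (b in birds) {
    res <- tryCatch({
      tw <- twilights[twilights$bird_id == b, ]
      pos <- geolocate_twilights(tw, config)
      log_stage(b, "geolocate", nrow(pos), 0L)
      pos <- sst_correct_track(pos, sst_samples[sst_samples$bird_id == b, ],
                               grids, config)
      log_stage(b, "sst_correct", nrow(pos), 0L)
      resolved <- pos[!is.na(pos$lat) & !is.na(pos$lon), ]
      log_stage(b, "resolve", nrow(pos), nrow(pos) - nrow(resolved))
      sf <- speed_filter(resolved, config)
      log_stage(b, "speed_filter", nrow(resolved), nrow(sf$removed))
      sm <- smooth_track(sf$kept, config)
      log_stage(b, "smooth", nrow(sm), 0L)
      if (nrow(sm) < 3) stop("track too short after cleaning")
      dd <- daily_km(sm, config$earth_radius_km)
      st <- classify_days(dd$daily_km, config$seg_threshold,
                          config$seg_window, config$seg_count)
      adj <- adjust_bursts(st, dd$daily_km,
                           sm$lat[-1], sm$lon[-1], config)
      states <- c("STOPOVER", adj$states)
      list(track = sm, states = states,
           day_state = data.frame(date = sm$date,
                                  daily_km = c(0, dd$daily_km),
                                  state = states,
                                  burst_adjusted = c(FALSE, adj$burst_adjusted),
                                  stringsAsFactors = FALSE),
           n_resolved = nrow(resolved))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, b)
      stage_log[[length(stage_log) + 1]] <- list(
        bird_id = b, stage = "failed", n_in = 0L, n_removed = 0L, n_out = 0L,
        message = conditionMessage(res))
      next
    }
    tracks[[b]] <- res$track
    day_states[[b]] <- res$day_state
    attr(tracks[[b]], "n_resolved") <- res$n_resolved
  }
  # pass 1: pool each bird's post-migration (terminal) stopover run, south
  # of the equator, per basin
  basin <- vapply(names(tracks), function(b)
    infer_basin(tracks[[b]], day_states[[b]]$state), "")
  pooled <- list(PACIFIC = NULL, ATLANTIC = NULL)
  for (b in names(tracks)) {
    tr <- tracks[[b]]
    st <- day_states[[b]]$state
    r <- rle(st)
    k <- length(r$values)
    if (r$values[k] != "STOPOVER") next
    # terminal stopover block: walk back over stopover runs, treating travel
    # interruptions of <= 2 days (burst-scale) as part of the same residency
    first <- nrow(tr) - r$lengths[k] + 1L
    while (k >= 3 && r$values[k - 1] == "TRAVEL" && r$lengths[k - 1] <= 2) {
      k <- k - 2L
      first <- first - r$lengths[k + 1L] - r$lengths[k]
    }
    tail_run <- first:nrow(tr)
    sel <- tail_run[st[tail_run] == "STOPOVER" & tr$lat[tail_run] < 0]
    if (length(sel) > 0) {
      pooled[[basin[b]]] <- rbind(pooled[[basin[b]]],
                                  tr[sel, c("lat", "lon")])
    }
  }
  areas <- list(PACIFIC = NULL, ATLANTIC = NULL)
  for (bs in names(areas)) {
    if (!is.null(pooled[[bs]]) && nrow(pooled[[bs]]) >= 30) {
      areas[[bs]] <- define_wintering_area(pooled[[bs]], bs, config)
    }
  }
  # pass 2: phases and summaries against the wintering polygons
  summaries <- list()
  for (b in names(tracks)) {
    ph <- split_phases(tracks[[b]], day_states[[b]]$state, areas[[basin[b]]])
    day_states[[b]]$phase <- ph$phase
    phase_list[[b]] <- ph
    s <- summarize_migration(tracks[[b]], day_states[[b]]$state, ph,
                             basin[b], config$earth_radius_km)
    s$n_positions <- nrow(tracks[[b]])
    # valid = estimated locations surviving the speed filter
    s$pct_valid <- 100 * nrow(tracks[[b]]) / attr(tracks[[b]], "n_resolved")
    summaries[[b]] <- s
  }
  summary_df <- do.call(rbind, summaries)
  if (!is.null(summary_df)) rownames(summary_df) <- NULL
  tests <- pipeline_tests(summary_df)
  structure(list(tracks = tracks, day_states = day_states,
                 phases = phase_list, wintering_areas = areas,
                 summary = summary_df, tests = tests,
                 stage_log = stage_log, failed = failed, config = config),
            class = "gls_pipeline")
}

pipeline_tests <- function(summary_df) {
  if (is.null(summary_df)) return(NULL)
  ok <- summary_df$complete
  pac <- summary_df[ok & summary_df$basin == "PACIFIC", ]
  atl <- summary_df[ok & summary_df$basin == "ATLANTIC", ]
  if (nrow(pac) < 2 || nrow(atl) < 2) return(NULL)
  list(travel_distance = welch_t(pac$travel_distance_km, atl$travel_distance_km),
       travel_speed = welch_t(pac$travel_speed_kmd, atl$travel_speed_kmd))
}

#' Write the pipeline stage log as JSON lines
#'
#' One JSON object per line per (bird, stage), with the counts entering,
#' removed at, and leaving the stage, so removal statistics can be
#' reproduced from the log alone.
#'
#' @param pipeline A `gls_pipeline` (or its `stage_log`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stage_log <- function(pipeline, path) {
  log <- if (inherits(pipeline, "gls_pipeline")) pipeline$stage_log else pipeline
  lines <- vapply(log, function(e)
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE)), "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gls_pipeline <- function(x, ...) {
  cat(sprintf("<gls_pipeline> %d birds processed, %d failed\n",
              length(x$tracks), length(x$failed)))
  if (!is.null(x$summary)) {
    comp <- sum(x$summary$complete)
    cat(sprintf("  complete migrations : %d of %d (%d Pacific, %d Atlantic)\n",
                comp, nrow(x$summary),
                sum(x$summary$basin == "PACIFIC"),
                sum(x$summary$basin == "ATLANTIC")))
  }
  invisible(x)
}

#' @export
summary.gls_pipeline <- function(object, ...) {
  s <- object$summary
  cat("Migration summary (complete tracks):\n")
  for (bs in c("PACIFIC", "ATLANTIC")) {
    g <- s[s$complete & s$basin == bs, ]
    if (nrow(g) == 0) next
    cat(sprintf(
      "  %-8s n=%d  duration %.0f d (%.0f-%.0f)  distance %.0f km (%.0f-%.0f)  speed %.0f km/d\n",
      bs, nrow(g), mean(g$duration_days), min(g$duration_days),
      max(g$duration_days), mean(g$travel_distance_km),
      min(g$travel_distance_km), max(g$travel_distance_km),
      mean(g$travel_speed_kmd)))
  }
  dir_only <- s[!s$complete, ]
  if (nrow(dir_only) > 0) {
    cat(sprintf("  direction-only birds: %d\n", nrow(dir_only)))
  }
  cat(sprintf("  mean %% valid positions: %.1f\n", mean(s$pct_valid)))
  if (!is.null(object$tests)) {
    cat("Between-basin Welch tests:\n  distance: ")
    print(object$tests$travel_distance)
    cat("  speed:    ")
    print(object$tests$travel_speed)
  }
  invisible(s)
}

#' @export
plot.gls_pipeline <- function(x, ...) {
  lats <- unlist(lapply(x$tracks, `[[`, "lat"))
  lons <- unlist(lapply(x$tracks, `[[`, "lon"))
  graphics::plot(NA, xlim = range(lons, na.rm = TRUE),
                 ylim = range(lats, na.rm = TRUE),
                 xlab = "Longitude", ylab = "Latitude",
                 main = "Processed tracks", ...)
  cols <- grDevices::hcl.colors(max(2, length(x$tracks)), "Dark 3")
  for (i in seq_along(x$tracks)) {
    tr <- x$tracks[[i]]
    jump <- c(FALSE, abs(diff(tr$lon)) > 180)
    lon <- tr$lon; lon[jump] <- NA  # break antimeridian wraps
    graphics::lines(lon, tr$lat, col = cols[i])
  }
  for (area in x$wintering_areas) {
    if (is.null(area)) next
    for (ct in area$contours) {
      if (ct$level != 50 || is.null(ct$polygons_geo)) next
      for (ring in ct$polygons_geo) {
        graphics::lines(ring[, "lon"], ring[, "lat"], lwd = 2)
      }
    }
  }
  invisible(x)
}
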