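#' Pipeline configuration
#'
#' Builds the configuration object consumed by every pipeline stage. Defaults
#' encode the processing rules used throughout: a 13.9 m/s (50 km/h) maximum
#' sustained speed over a 48 h window, 1:2:1 weighted smoothing with 4 deg
#' longitude / 6 deg latitude jump exclusions, 100 km/d stopover/travel
#' threshold applied with a 3-of-5 sliding window, and kernel densities with
#' a 200 km search radius on a 10 km output grid contoured at 25/50/75%
#' occupancy.
#'
#' @param colony_lat,colony_lon Breeding-colony coordinates, degrees.
#' @param sun_angle Sun elevation angle (degrees, negative below the horizon)
#'   defining twilight for the threshold method. Default -3.44, a conventional
#'   geolocator calibration angle.
#' @param v_max Maximum realistic sustained speed, m/s.
#' @param sustain_hours Window (h) over which speed must be sustained.
#' @param strict_pairwise If TRUE the speed filter removes on any single
#'   pair exceedance instead of the windowed root-mean-square.
#' @param smooth_weights Weights for previous/current/next position.
#' @param jump_lon,jump_lat Daily movement (degrees) beyond which a position
#'   is excluded from smoothing.
#' @param seg_threshold Stopover/travel daily-distance threshold, km/d.
#' @param seg_window,seg_count Sliding-window length and required count for a
#'   state transition (`seg_count <= seg_window`).
#' @param burst_factor Stopover-cluster separation, in multiples of
#'   `seg_threshold`, required to relabel a 1-2 day burst as travel.
#' @param breeding_radius_km Radius around the colony defining the breeding
#'   residency used when locating departure.
#' @param kde_bandwidth_km,kde_cell_km Kernel search radius and output cell
#'   size, km.
#' @param contour_levels Occupancy contour levels, percent, in (0, 100).
#' @param sst_tolerance Max |tag SST - grid SST| (deg C) for a plateau
#'   latitude match (profile crossings always qualify).
#' @param sst_match_window Days of tag SST averaged (centred window) before
#'   matching against the composite; 1 = single-day matching.
#' @param sst_band_deg Search band (degrees) around the threshold latitude for
#'   SST matching; ignored (unbounded) when the day is equinox-flagged.
#' @param equinox_decl_deg |solar declination| below which latitude from day
#'   length is considered ill-conditioned and flagged.
#' @param earth_radius_km Sphere radius used for all distances.
#' @param seed Optional integer seed recorded in the configuration.
#' @return A list of class `gls_config`.
#' @export
pipeline_config <- function(colony_lat = 75.8, colony_lon = -96.3,
                            sun_angle = -3.44,
                            v_max = 13.9, sustain_hours = 48,
                            strict_pairwise = FALSE,
                            smooth_weights = c(1, 2, 1),
                            jump_lon = 4, jump_lat = 6,
                            seg_threshold = 100, seg_window = 5, seg_count = 3,
                            burst_factor = 2, breeding_radius_km = 20,
                            kde_bandwidth_km = 200, kde_cell_km = 10,
                            contour_levels = c(25, 50, 75),
                            sst_tolerance = 0.5, sst_band_deg = 15,
                            sst_match_window = 3,
                            equinox_decl_deg = 5,
                            earth_radius_km = 6371.0,
                            seed = NULL) {
  cfg <- list(colony_lat = colony_lat, colony_lon = norm_lon(colony_lon),
              sun_angle = sun_angle,
              v_max = v_max, sustain_hours = sustain_hours,
              strict_pairwise = isTRUE(strict_pairwise),
              smooth_weights = smooth_weights,
              jump_lon = jump_lon, jump_lat = jump_lat,
              seg_threshold = seg_threshold, seg_window = as.integer(seg_window),
              seg_count = as.integer(seg_count),
              burst_factor = burst_factor,
              breeding_radius_km = breeding_radius_km,
              kde_bandwidth_km = kde_bandwidth_km, kde_cell_km = kde_cell_km,
              contour_levels = contour_levels,
              sst_tolerance = sst_tolerance, sst_band_deg = sst_band_deg,
              sst_match_window = as.integer(sst_match_window),
              equinox_decl_deg = equinox_decl_deg,
              earth_radius_km = earth_radius_km,
              seed = seed)
  validate_config(cfg)
  class(cfg) <- "gls_config"
  cfg
}

validate_config <- function(cfg) {
  pos <- c("v_max", "sustain_hours", "jump_lon", "jump_lat", "seg_threshold",
           "seg_window", "seg_count", "burst_factor", "breeding_radius_km",
           "kde_bandwidth_km", "kde_cell_km", "sst_tolerance", "sst_band_deg",
           "equinox_decl_deg", "earth_radius_km")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || any(cfg[[nm]] <= 0)) {
      stop("configuration value '", nm, "' must be > 0", call. = FALSE)
    }
  }
  if (cfg$seg_count > cfg$seg_window) {
    stop("seg_count must not exceed seg_window", call. = FALSE)
  }
  if (any(cfg$contour_levels <= 0) || any(cfg$contour_levels >= 100)) {
    stop("contour_levels must lie in (0, 100)", call. = FALSE)
  }
  if (length(cfg$smooth_weights) != 3 || any(cfg$smooth_weights < 0) ||
      sum(cfg$smooth_weights) <= 0) {
    stop("smooth_weights must be three non-negative weights", call. = FALSE)
  }
  if (abs(cfg$colony_lat) > 90) stop("colony latitude out of range", call. = FALSE)
  invisible(cfg)
}

#' @export
print.gls_config <- function(x, ...) {
  cat("<gls_config>\n")
  cat(sprintf("  colony          : %.2f N, %.2f E\n", x$colony_lat, x$colony_lon))
  cat(sprintf("  sun angle       : %.2f deg\n", x$sun_angle))
  cat(sprintf("  speed filter    : %.1f m/s sustained over %g h (%s)\n",
              x$v_max, x$sustain_hours,
              if (x$strict_pairwise) "strict pairwise" else "windowed RMS"))
  cat(sprintf("  smoothing       : weights %s, jump limits %g deg lon / %g deg lat\n",
              paste(x$smooth_weights, collapse = ":"), x$jump_lon, x$jump_lat))
  cat(sprintf("  segmentation    : %g km/d, %d of %d window\n",
              x$seg_threshold, x$seg_count, x$seg_window))
  cat(sprintf("  kernel density  : %g km radius, %g km cells, contours %s%%\n",
              x$kde_bandwidth_km, x$kde_cell_km,
              paste(x$contour_levels, collapse = "/")))
  cat(sprintf("  SST correction  : tolerance %g degC, band +/-%g deg\n",
              x$sst_tolerance, x$sst_band_deg))
  invisible(x)
}
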