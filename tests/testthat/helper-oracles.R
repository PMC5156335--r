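# Shared fixtures and independent reference implementations used as oracles.

# Build a position data frame with all pipeline columns filled in.
make_track <- function(lat, lon, start = as.Date("2010-09-01"),
                       dates = NULL, source = NULL, bird_id = "t1") {
  n <- length(lat)
  if (is.null(dates)) dates <- start + seq_len(n) - 1
  if (is.null(source)) source <- rep("threshold", n)
  data.frame(bird_id = bird_id, date = dates, lat = lat, lon = lon,
             source = source,
             equinox_flagged = FALSE, polar_flagged = FALSE,
             speed_rejected = FALSE, unsmoothed_jump = FALSE,
             stringsAsFactors = FALSE)
}

# Reference stopover/travel state machine, written as a literal day-by-day
# transcription of the transition rule (no early exits, no vectorisation),
# used to cross-check classify_days by exhaustive enumeration.
ref_classify <- function(exceed, window = 5, count = 3) {
  n <- length(exceed)
  out <- character(n)
  state <- "STOPOVER"
  i <- 1
  while (i <= n) {
    last <- min(i + window - 1, n)
    qualifying <- integer(0)
    for (k in i:last) {
      hit <- if (state == "STOPOVER") exceed[k] else !exceed[k]
      if (hit) qualifying <- c(qualifying, k)
    }
    if (length(qualifying) >= count) {
      j <- qualifying[1]
      while (i < j) {
        out[i] <- state
        i <- i + 1
      }
      state <- if (state == "STOPOVER") "TRAVEL" else "STOPOVER"
      out[i] <- state
      i <- i + 1
    } else {
      out[i] <- state
      i <- i + 1
    }
  }
  out
}

# A compact wintering area built from a spread-out point cluster.
make_area <- function(center_lat = -10, center_lon = -85, n = 300,
                      sd_km = 300, seed = 42, basin = "PACIFIC") {
  set.seed(seed)
  p <- glspipe:::offset_km(rep(center_lat, n), rep(center_lon, n),
                           rnorm(n, 0, sd_km), rnorm(n, 0, sd_km))
  define_wintering_area(data.frame(lat = p[, 1], lon = p[, 2]), basin)
}
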