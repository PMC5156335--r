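#' Low-precision solar ephemeris
#'
#' Solar declination and equation of time from the standard low-precision
#' series (NOAA solar-calculator formulation). Accuracy is ample for
#' light-level geolocation: declination to ~0.01 deg, equation of time to
#' ~0.1 min over 1990-2100.
#'
#' @param when `Date` or UTC `POSIXct`; a `Date` is evaluated at 12:00 UTC.
#' @return A list with numeric vectors `declination` (degrees) and
#'   `equation_of_time` (minutes, apparent minus mean solar time).
#' @export
solar_ephemeris <- function(when) {
  if (inherits(when, "Date")) {
    t <- as.POSIXct(paste(format(when), "12:00:00"), tz = "UTC")
  } else {
    t <- as.POSIXct(when, tz = "UTC")
  }
  yr <- as.integer(format(t, "%Y"))
  if (any(yr < 1990 | yr > 2100)) {
    stop("solar_ephemeris supports years 1990-2100", call. = FALSE)
  }
  # Julian centuries since J2000.0
  jc <- as.numeric(difftime(t, as.POSIXct("2000-01-01 12:00:00", tz = "UTC"),
                            units = "days")) / 36525
  deg <- pi / 180
  L0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  M <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  C <- sin(M * deg) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * M * deg) * (0.019993 - 0.000101 * jc) +
    sin(3 * M * deg) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * deg)
  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega * deg)
  decl <- asin(sin(eps * deg) * sin(app_long * deg)) / deg
  y <- tan(eps * deg / 2)^2
  eot <- 4 / deg * (y * sin(2 * L0 * deg) - 2 * e * sin(M * deg) +
                      4 * e * y * sin(M * deg) * cos(2 * L0 * deg) -
                      0.5 * y^2 * sin(4 * L0 * deg) -
                      1.25 * e^2 * sin(2 * M * deg))
  list(declination = decl, equation_of_time = eot)
}

# Day length (hours) implied by the hour-angle equation at latitude phi for
# declination decl and sun angle a (all degrees). 24 = polar day, 0 = night.
day_length_model <- function(phi, decl, sun_angle) {
  deg <- pi / 180
  cosH <- (sin(sun_angle * deg) - sin(phi * deg) * sin(decl * deg)) /
    (cos(phi * deg) * cos(decl * deg))
  ifelse(cosH < -1, 24, ifelse(cosH > 1, 0, 2 * acos(cosH) / deg / 15))
}

#' Forward twilight model
#'
#' Predicts UTC sunrise and sunset times for a position and date by solving
#' the hour-angle equation `cos H = (sin a - sin phi sin delta) /
#' (cos phi cos delta)` at the configured sun elevation angle.
#'
#' @param lat,lon Position, degrees.
#' @param date `Date` (UTC calendar day).
#' @param sun_angle Sun elevation angle defining twilight (degrees, negative
#'   below the horizon).
#' @return A list with `sunrise` and `sunset` (UTC decimal hours in [0, 24),
#'   `NA` when polar) and `polar` (`"day"`, `"night"`, or `NA`).
#' @export
twilight_forward <- function(lat, lon, date, sun_angle = -3.44) {
  stopifnot(abs(lat) <= 90)
  eph <- solar_ephemeris(date)
  deg <- pi / 180
  cosH <- (sin(sun_angle * deg) - sin(lat * deg) * sin(eph$declination * deg)) /
    (cos(lat * deg) * cos(eph$declination * deg))
  polar <- ifelse(cosH < -1, "day", ifelse(cosH > 1, "night", NA_character_))
  halfday <- ifelse(is.na(polar), acos(pmin(pmax(cosH, -1), 1)) / deg / 15, NA_real_)
  noon <- 12 - lon / 15 - eph$equation_of_time / 60
  list(sunrise = ifelse(is.na(polar), (noon - halfday) %% 24, NA_real_),
       sunset = ifelse(is.na(polar), (noon + halfday) %% 24, NA_real_),
       polar = polar)
}

#' Longitude from twilight times
#'
#' Threshold-method longitude: the UTC midpoint of sunrise and sunset (taken
#' on the shorter arc, so local midnight between the two is handled) gives
#' local apparent noon; longitude is `-15 deg/h * (t_mid - 12 h + EoT)`,
#' normalised to [-180, 180).
#'
#' @param sunrise,sunset UTC decimal hours.
#' @param date `Date` used to evaluate the equation of time.
#' @return Longitude in degrees, or `NA` if either twilight is missing.
#' @export
estimate_longitude <- function(sunrise, sunset, date) {
  if (is.na(sunrise) || is.na(sunset)) return(NA_real_)
  ss <- if (sunset < sunrise) sunset + 24 else sunset
  tmid <- ((sunrise + ss) / 2) %% 24
  eot_h <- solar_ephemeris(date)$equation_of_time / 60
  # place t_mid on the branch nearest local noon for this longitude family
  delta <- tmid - 12 + eot_h
  delta <- ((delta + 12) %% 24) - 12
  norm_lon(-15 * delta)
}

#' Latitude from day length
#'
#' Threshold-method latitude: inverts the hour-angle equation for latitude by
#' bisection on [-85, 85] deg given the observed day length and the date's
#' solar declination. Near the equinoxes (|declination| below
#' `equinox_decl_deg`) the inversion is ill-conditioned and the estimate is
#' flagged rather than suppressed; days with no solution (polar day/night or
#' noise pushing day length outside the attainable range) are polar-flagged.
#'
#' @param day_length_h Observed day length, hours.
#' @param date `Date`.
#' @param sun_angle Twilight sun elevation angle, degrees.
#' @param equinox_decl_deg Equinox-window half width in declination degrees.
#' @return A list with `lat` (degrees or `NA`), `equinox_flagged`,
#'   `polar_flagged`.
#' @export
estimate_latitude <- function(day_length_h, date, sun_angle = -3.44,
                              equinox_decl_deg = 5) {
  decl <- solar_ephemeris(date)$declination
  equinox <- abs(decl) < equinox_decl_deg
  if (is.na(day_length_h) || day_length_h <= 0 || day_length_h >= 24) {
    return(list(lat = NA_real_, equinox_flagged = equinox, polar_flagged = TRUE))
  }
  f <- function(phi) day_length_model(phi, decl, sun_angle) - day_length_h
  lo <- -85; hi <- 85
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    return(list(lat = NA_real_, equinox_flagged = equinox, polar_flagged = TRUE))
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) break
    if (flo * fm < 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
  }
  list(lat = (lo + hi) / 2, equinox_flagged = equinox, polar_flagged = FALSE)
}
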