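test_that("solar ephemeris matches published solstice/equinox values", {
  e <- solar_ephemeris(as.Date("2010-06-21"))
  expect_lt(abs(e$declination - 23.44), 0.3)
  expect_lt(abs(solar_ephemeris(as.Date("2010-03-20"))$declination), 1)
  expect_lt(abs(solar_ephemeris(as.Date("2010-04-15"))$equation_of_time), 2)
  expect_error(solar_ephemeris(as.Date("1850-01-01")), "1990-2100")
  # bounds over a sampled decade
  dates <- as.Date("2000-01-01") + seq(0, 3650, by = 17)
  e <- solar_ephemeris(dates)
  expect_true(all(abs(e$declination) <= 23.6))
  expect_true(all(abs(e$equation_of_time) <= 17))
})

test_that("forward twilight model honours symmetry and polar sentinels", {
  tw <- twilight_forward(0, 0, as.Date("2010-03-20"), sun_angle = 0)
  dl <- (tw$sunset - tw$sunrise) %% 24
  expect_lt(abs(dl - 12), 3 / 60)
  expect_lt(abs(((tw$sunrise + tw$sunset) / 2) %% 24 - 12), 10 / 60)

  expect_equal(twilight_forward(80, 0, as.Date("2010-12-15"))$polar, "night")
  expect_equal(twilight_forward(75.8, -96.3, as.Date("2010-06-25"))$polar, "day")
})

test_that("longitude comes from the twilight midpoint", {
  # mid-April: equation of time is ~0
  d <- as.Date("2010-04-15")
  expect_lt(abs(estimate_longitude(6, 18, d)), 0.2)
  expect_lt(abs(estimate_longitude(12, 0, d) - (-90)), 0.2)
  expect_true(is.na(estimate_longitude(NA, 18, d)))
})

test_that("latitude inversion flags the degenerate cases", {
  eq <- estimate_latitude(12, as.Date("2010-03-20"))
  expect_true(eq$equinox_flagged)
  pol <- estimate_latitude(24, as.Date("2010-06-21"))
  expect_true(pol$polar_flagged)
  est <- estimate_latitude(
    (twilight_forward(40, 0, as.Date("2010-11-15"))$sunset -
       twilight_forward(40, 0, as.Date("2010-11-15"))$sunrise) %% 24,
    as.Date("2010-11-15"))
  expect_lt(abs(est$lat - 40), 0.5)
  expect_false(est$equinox_flagged)
})

test_that("zero-noise round trip recovers position away from the equinox", {
  set.seed(31)
  n_ok <- 0
  for (i in 1:200) {
    lat <- runif(1, -65, 65)
    lon <- runif(1, -180, 179.9)
    date <- as.Date("2010-01-01") + sample(0:364, 1)
    if (abs(solar_ephemeris(date)$declination) <= 5) next
    tw <- twilight_forward(lat, lon, date)
    if (!is.na(tw$polar)) next
    lon_hat <- estimate_longitude(tw$sunrise, tw$sunset, date)
    lat_hat <- estimate_latitude((tw$sunset - tw$sunrise) %% 24, date)$lat
    expect_lt(abs(norm_lon(lon_hat - lon)), 0.2)
    expect_lt(abs(lat_hat - lat), 0.5)
    n_ok <- n_ok + 1
  }
  expect_gt(n_ok, 100)
})

test_that("longitude estimate does not depend on latitude", {
  date <- as.Date("2010-11-01")
  lons <- vapply(c(-60, -20, 0, 35, 70), function(lat) {
    tw <- twilight_forward(lat, -96.3, date)
    estimate_longitude(tw$sunrise, tw$sunset, date)
  }, 0)
  expect_lt(max(lons) - min(lons), 1e-6)
})

test_that("SST correction inverts a monotone field and keeps longitude", {
  grid <- glspipe:::new_sst_grid(as.Date("2010-09-06"), 8,
                                 lat_axis = seq(-10, 50, 1),
                                 lon_axis = seq(-88, -82, 1),
                                 values = matrix(rep(30 - 0.5 * seq(-10, 50, 1), 7),
                                                 ncol = 7))
  pos <- make_track(35, -85)[1, ]
  out <- sst_correct_latitude(pos, tag_sst = 20, grid, previous_lat = 30)
  expect_equal(out$lat, 20, tolerance = 1e-9)
  expect_equal(out$lon, pos$lon)
  expect_equal(out$source, "sst_corrected")
})

test_that("among several SST candidates the one nearest yesterday wins", {
  lat_axis <- seq(0, 40, 1)
  prof <- ifelse(lat_axis < 20, 25 - 0.5 * lat_axis, 15 + 0.5 * (lat_axis - 20))
  # tag 20 crosses at lat 10 and lat 30
  grid <- glspipe:::new_sst_grid(as.Date("2010-09-06"), 8, lat_axis,
                                 seq(-88, -82, 1),
                                 matrix(rep(prof, 7), ncol = 7))
  pos <- make_track(20, -85)[1, ]
  pos$equinox_flagged <- TRUE  # unbounded search band
  out <- sst_correct_latitude(pos, 20, grid, previous_lat = 12)
  expect_equal(out$lat, 10, tolerance = 1e-9)
  out2 <- sst_correct_latitude(pos, 20, grid, previous_lat = 27)
  expect_equal(out2$lat, 30, tolerance = 1e-9)
})

test_that("SST correction is a no-op without data and never moves the colony", {
  grid <- glspipe:::new_sst_grid(as.Date("2010-09-06"), 8, seq(-10, 50, 1),
                                 seq(-88, -82, 1),
                                 matrix(rep(30 - 0.5 * seq(-10, 50, 1), 7),
                                        ncol = 7))
  pos <- make_track(35, -85)[1, ]
  expect_identical(sst_correct_latitude(pos, NA, grid, 30), pos)
  expect_identical(sst_correct_latitude(pos, 20, NULL, 30), pos)
  colony <- make_track(75.8, -96.3, source = "fixed_colony")[1, ]
  expect_identical(sst_correct_latitude(colony, 20, grid, 30), colony)
})

test_that("geolocation flags polar and equinox days and anchors the colony", {
  it <- simulate_itinerary("b1", "PACIFIC", seed = 3)
  tw <- synthesize_twilights(it, noise_sd_minutes = 0, seed = 4)
  pos <- geolocate_twilights(tw)
  expect_equal(pos$source[1], "fixed_colony")
  expect_equal(pos$lat[1], 75.8)
  expect_equal(nrow(pos), nrow(tw) + 1)
  expect_true(any(pos$equinox_flagged))
  # every twilight day is accounted for: resolved, fixed, or flagged
  unresolved <- is.na(pos$lat) | is.na(pos$lon)
  expect_true(all(pos$polar_flagged[unresolved] | pos$equinox_flagged[unresolved]))
})
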