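test_that("itineraries are reproducible and respect the migration structure", {
  a <- simulate_itinerary("b1", "PACIFIC", seed = 21)
  b <- simulate_itinerary("b1", "PACIFIC", seed = 21)
  expect_identical(a, b)

  expect_s3_class(a, "itinerary")
  expect_true(all(diff(a$daily$date) == 1))
  expect_equal(a$daily$state[1], "STOPOVER")
  expect_equal(a$daily$lat[1], 75.8)
  expect_true(a$arrival > a$departure)
})

test_that("stopover and travel days bracket the threshold by construction", {
  for (seed in 22:24) {
    it <- simulate_itinerary("b1", sample(c("PACIFIC", "ATLANTIC"), 1),
                             sim_config(), seed = seed)
    d <- it$daily
    disp <- c(0, haversine_km(d$lat[-nrow(d)], d$lon[-nrow(d)],
                              d$lat[-1], d$lon[-1]))
    expect_true(all(disp[d$state == "TRAVEL"] > 100))
    expect_true(all(disp[d$state == "STOPOVER"] < 100))
  }
})

test_that("a direct constant-speed flight lasts ceiling(distance/speed) days", {
  colony <- c(75.8, -96.3); dest <- c(-10, -85)
  sim <- sim_config(speed_mean = 350, speed_sd = 0, speed_range = c(350, 350),
                    stopover_n_range = c(0, 0), burst_prob = 0,
                    routes = list(PACIFIC = rbind(colony, dest)))
  it <- simulate_itinerary("b1", "PACIFIC", sim, seed = 25)
  d_km <- haversine_km(colony[1], colony[2], dest[1], dest[2])
  expect_equal(sum(it$daily$state == "TRAVEL"), ceiling(d_km / 350))
  expect_equal(it$travel_km, d_km, tolerance = 1)
})

test_that("a destination at the colony degenerates to pure residency", {
  colony <- c(75.8, -96.3)
  sim <- sim_config(routes = list(PACIFIC = rbind(colony, colony)),
                    winter_center_jitter_km = 0)
  it <- simulate_itinerary("b1", "PACIFIC", sim, seed = 26)
  expect_true(all(it$daily$state == "STOPOVER"))
  expect_true(is.na(it$departure))
  expect_equal(it$travel_km, 0)
})

test_that("synthetic twilights honour noise, sentinels and reproducibility", {
  it <- simulate_itinerary("b1", "PACIFIC", seed = 27)
  tw0 <- synthesize_twilights(it, noise_sd_minutes = 0, seed = 1)
  tw0b <- synthesize_twilights(it, noise_sd_minutes = 0, seed = 1)
  expect_identical(tw0, tw0b)
  expect_true(any(tw0$polar == "day", na.rm = TRUE))  # polar colony in July
  # zero-noise inversion recovers truth away from the equinox
  ok <- is.na(tw0$polar)
  for (i in which(ok)[seq(1, sum(ok), by = 7)]) {
    if (abs(solar_ephemeris(tw0$date[i])$declination) <= 5) next
    lon_hat <- estimate_longitude(tw0$sunrise[i], tw0$sunset[i], tw0$date[i])
    truth <- it$daily[it$daily$date == tw0$date[i], ]
    expect_lt(abs(norm_lon(lon_hat - truth$lon)), 0.2)
  }
})

test_that("the synthetic SST field is monotone and sampled faithfully", {
  lin <- sst_field_spec(profile = "linear", base_temp = 30, gradient = -0.5,
                        seasonal_amp = 0)
  expect_equal(sst_field_value(lin, 20, as.Date("2010-10-01")), 20)
  lats <- seq(-45, 80, 1)
  expect_true(all(diff(sst_field_value(sst_field_spec(), lats,
                                       as.Date("2010-10-01"))) < 0))
  expect_true(all(diff(sst_field_value(sst_field_spec(profile = "logistic"),
                                       lats, as.Date("2010-10-01"))) < 0))
  expect_error(sst_field_spec(profile = "linear", gradient = 0), "gradient")
})

test_that("grid stacks cover the itinerary in 8-day composites", {
  sim <- sim_config()
  g <- synthesize_sst_grids(as.Date(c("2010-09-01", "2010-09-16")), sim)
  expect_equal(length(g), 2)
  expect_equal(as.numeric(g[[2]]$period_start - g[[1]]$period_start), 8)
  expect_true(all(diff(g[[1]]$lat) > 0))

  it <- simulate_itinerary("b1", "PACIFIC", seed = 28)
  ss <- synthesize_sst(it, sim, seed = 29)
  expect_true(all(ss$samples$min_sst >= -2 & ss$samples$min_sst <= 40,
                  na.rm = TRUE))
  expect_gt(mean(is.na(ss$samples$min_sst)), 0)
  # tag samples track the field at the true position
  ok <- !is.na(ss$samples$min_sst)
  truth <- sst_field_value(sim$field, it$daily$lat[ok], it$daily$date[ok])
  resid <- ss$samples$min_sst[ok] - pmin(pmax(truth, -2), 40)
  expect_lt(sd(resid), 3 * sim$tag_sst_sd)
  expect_lt(abs(mean(resid)), 0.1)
})

test_that("cohorts are seed-deterministic with the configured composition", {
  a <- simulate_cohort(2, 1, seed = 30)
  b <- simulate_cohort(2, 1, seed = 30)
  expect_identical(a$twilights, b$twilights)
  expect_identical(a$sst_samples, b$sst_samples)
  expect_identical(lapply(a$truth, `[[`, "daily"),
                   lapply(b$truth, `[[`, "daily"))
  expect_equal(a$birds$destination, c("PACIFIC", "PACIFIC", "ATLANTIC"))
})

test_that("route lengths and schedules emulate the study conditions", {
  sim <- sim_config()
  expect_equal(glspipe:::route_length_km(sim$routes$PACIFIC), 14633,
               tolerance = 0.01)
  expect_equal(glspipe:::route_length_km(sim$routes$ATLANTIC), 14657,
               tolerance = 0.01)
  durs <- vapply(31:50, function(s) {
    it <- simulate_itinerary("b", "PACIFIC", sim, seed = s)
    as.numeric(it$arrival - it$departure)
  }, 0)
  expect_gt(mean(durs), 58)
  expect_lt(mean(durs), 112)
})
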