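test_that("haversine distance matches closed forms and metric axioms", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  expect_equal(haversine_km(0, 0, 0, 90), pi / 2 * 6371, tolerance = 0.1)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 0.1)

  set.seed(13)
  for (i in 1:25) {
    a <- c(runif(1, -89, 89), runif(1, -180, 179))
    b <- c(runif(1, -89, 89), runif(1, -180, 179))
    c3 <- c(runif(1, -89, 89), runif(1, -180, 179))
    dab <- haversine_km(a[1], a[2], b[1], b[2])
    expect_equal(dab, haversine_km(b[1], b[2], a[1], a[2]))
    expect_lte(haversine_km(a[1], a[2], c3[1], c3[2]),
               dab + haversine_km(b[1], b[2], c3[1], c3[2]) + 1e-8)
  }
})

test_that("haversine agrees with the geosphere implementation", {
  skip_if_not_installed("geosphere")
  set.seed(14)
  lat1 <- runif(100, -89, 89); lon1 <- runif(100, -180, 179)
  lat2 <- runif(100, -89, 89); lon2 <- runif(100, -180, 179)
  ours <- haversine_km(lat1, lon1, lat2, lon2)
  ref <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                  r = 6371000) / 1000
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("daily rates divide by elapsed days and telescope", {
  tr <- make_track(lat = c(0, 300 / (6371 * pi / 180)), lon = c(0, 0),
                   dates = as.Date("2010-09-01") + c(0, 3))
  dd <- daily_km(tr)
  expect_equal(dd$daily_km, 100, tolerance = 1e-6)
  expect_equal(dd$date, tr$date[2])

  set.seed(15)
  tr <- make_track(lat = cumsum(rnorm(20, 0, 1)), lon = cumsum(rnorm(20, 0, 1)),
                   dates = as.Date("2010-09-01") + cumsum(sample(1:3, 20, TRUE)))
  dd <- daily_km(tr)
  expect_equal(sum(dd$daily_km * dd$days), sum(dd$km))
})

test_that("migration summary implements the travel-only distance definition", {
  # 4 colony days, 24 travel days at exactly 350 km/d (equator), a 6-day
  # stopover inserted mid-way, then 5 winter days
  step <- 350 / (6371 * pi / 180)
  lon <- c(rep(0, 4), cumsum(rep(step, 12)),
           rep(12 * step, 6), 12 * step + cumsum(rep(step, 12)),
           rep(24 * step, 5))
  tr <- make_track(lat = rep(0, length(lon)), lon = lon)
  states <- c(rep("STOPOVER", 4), rep("TRAVEL", 12), rep("STOPOVER", 6),
              rep("TRAVEL", 12), rep("STOPOVER", 5))
  phases <- list(phase = c(rep("BREEDING", 4), rep("FALL_MIGRATION", 30),
                           rep("WINTER", 5)),
                 departure = tr$date[5], arrival = tr$date[35],
                 has_migration = TRUE)
  s <- summarize_migration(tr, states, phases, "PACIFIC")
  expect_equal(s$travel_distance_km, 8400, tolerance = 0.5)
  expect_equal(s$travel_days, 24L)
  expect_equal(s$travel_speed_kmd, 350, tolerance = 0.05)
  expect_equal(s$duration_days, 30)
  expect_true(s$complete)

  # direction-only record keeps the basin, drops the metrics
  phases$arrival <- as.Date(NA)
  s2 <- summarize_migration(tr, states, phases, "ATLANTIC")
  expect_false(s2$complete)
  expect_equal(s2$basin, "ATLANTIC")
  expect_true(is.na(s2$travel_distance_km))
})

test_that("travel plus stopover movement equals total path length", {
  set.seed(16)
  tr <- make_track(lat = cumsum(rnorm(40, 0, 0.5)),
                   lon = cumsum(rnorm(40, 0, 0.5)))
  dd <- daily_km(tr)
  states <- sample(c("STOPOVER", "TRAVEL"), 40, replace = TRUE)
  later <- match(dd$date, tr$date)
  travel <- sum(dd$km[states[later] == "TRAVEL"])
  stopover <- sum(dd$km[states[later] == "STOPOVER"])
  expect_equal(travel + stopover, sum(dd$km))
})

test_that("Welch's t matches the closed forms and stats::t.test", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  w <- welch_t(x, y)
  expect_equal(w$statistic, -1.0954451, tolerance = 1e-6)
  expect_equal(w$df, 6)
  expect_equal(w$p_value, 0.3153336, tolerance = 1e-6)
  tt <- t.test(x, y)
  expect_equal(w$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(w$p_value, tt$p.value, tolerance = 1e-10)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  w10 <- welch_t(10 * x, 10 * y)
  expect_equal(w10$statistic, w$statistic)
  expect_equal(w10$p_value, w$p_value)

  expect_error(welch_t(1, c(1, 2)), "at least two")
})

test_that("one-way ANOVA carries the classical degrees of freedom", {
  set.seed(17)
  g <- rep(c("a", "b", "c"), c(10, 9, 9))
  v <- rnorm(28)
  a <- anova_oneway(v, g)
  expect_equal(a$df, c(2, 25))

  # identical groups: F = 0 and all Tukey p-values 1
  v0 <- rep(c(1, 2, 3, 4), 3)
  g0 <- rep(c("a", "b", "c"), each = 4)
  a0 <- anova_oneway(v0, g0)
  expect_equal(a0$statistic, 0)
  tk <- tukey_hsd(v0, g0)
  expect_true(all(abs(tk$p_adj - 1) < 1e-9))

  expect_error(anova_oneway(c(1, 2, 3), c("a", "a", "b")), "'b'")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(18)
  x <- rnorm(12, 0); y <- rnorm(15, 0.7)
  a <- anova_oneway(c(x, y), rep(c("x", "y"), c(12, 15)))
  t2 <- unname(t.test(x, y, var.equal = TRUE)$statistic)^2
  expect_equal(a$statistic, t2, tolerance = 1e-10)
})
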