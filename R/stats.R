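#' Daily movement rates along a track
#'
#' Great-circle distance between each adjacent pair of positions divided by
#' the number of elapsed days, assigned to the later date. Gaps therefore
#' yield per-day rates, not lump distances, so a multi-day gap cannot fake a
#' travel day.
#'
#' @param track Position data frame with `date`, `lat`, `lon`.
#' @param radius_km Sphere radius, km.
#' @return Data frame `date`, `km` (the raw pair distance), `days`,
#'   `daily_km` (rate), one row per adjacent pair.
#' @export
daily_km <- function(track, radius_km = 6371.0) {
  stopifnot(nrow(track) >= 2)
  d <- as.numeric(diff(track$date))
  if (any(d <= 0)) stop("non-increasing dates in track", call. = FALSE)
  n <- nrow(track)
  km <- haversine_km(track$lat[-n], track$lon[-n],
                     track$lat[-1], track$lon[-1], radius_km)
  data.frame(date = track$date[-1], km = km, days = d, daily_km = km / d)
}

#' Per-bird migration summary
#'
#' Travel distance is the sum of adjacent-pair distances whose later day is
#' a TRAVEL day inside fall migration (stopover movement is excluded);
#' travel speed is that distance divided by the number of travel days; the
#' migration duration spans departure to arrival. Incomplete tracks (no
#' arrival) report the basin and departure only.
#'
#' @param track Position data frame.
#' @param states State vector aligned with rows of `track`.
#' @param phases Output of [split_phases()].
#' @param basin `"PACIFIC"` or `"ATLANTIC"`.
#' @param radius_km Sphere radius, km.
#' @return One-row data frame: `bird_id`, `basin`, `departure`, `arrival`,
#'   `duration_days`, `travel_distance_km`, `travel_days`,
#'   `travel_speed_kmd`, `complete`.
#' @export
summarize_migration <- function(track, states, phases, basin,
                                radius_km = 6371.0) {
  complete <- phases$has_migration && !is.na(phases$arrival)
  if (!phases$has_migration) {
    return(data.frame(bird_id = track$bird_id[1], basin = basin,
                      departure = as.Date(NA), arrival = as.Date(NA),
                      duration_days = NA_real_, travel_distance_km = NA_real_,
                      travel_days = NA_integer_, travel_speed_kmd = NA_real_,
                      complete = FALSE, stringsAsFactors = FALSE))
  }
  dd <- daily_km(track, radius_km)
  later <- match(dd$date, track$date)
  in_fall <- phases$phase[later] == "FALL_MIGRATION"
  is_travel <- states[later] == "TRAVEL"
  sel <- in_fall & is_travel
  travel_distance <- if (complete) sum(dd$km[sel]) else NA_real_
  travel_days <- if (complete) sum(dd$days[sel]) else NA_integer_
  data.frame(bird_id = track$bird_id[1], basin = basin,
             departure = phases$departure, arrival = phases$arrival,
             duration_days = if (complete)
               as.numeric(phases$arrival - phases$departure) else NA_real_,
             travel_distance_km = travel_distance,
             travel_days = as.integer(travel_days),
             travel_speed_kmd = if (complete && travel_days > 0)
               travel_distance / travel_days else NA_real_,
             complete = complete, stringsAsFactors = FALSE)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value, computed from the closed forms.
#'
#' @param x,y Numeric samples of length >= 2.
#' @return List of class `gls_test`: `statistic`, `df`, `p_value`, `method`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("welch_t requires at least two observations per sample", call. = FALSE)
  }
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  if (vx + vy == 0) stop("both samples have zero variance", call. = FALSE)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  structure(list(statistic = t, df = df,
                 p_value = 2 * stats::pt(-abs(t), df),
                 method = "welch_t"),
            class = "gls_test")
}

#' One-way ANOVA
#'
#' Classic equal-variance one-way analysis of variance, F on (k-1, N-k)
#' degrees of freedom, via [stats::oneway.test()].
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor/vector, >= 2 groups of >= 2 observations.
#' @return List of class `gls_test`: `statistic`, `df` (length-2), `p_value`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  check_group_sizes(values, groups)
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  structure(list(statistic = unname(ft$statistic),
                 df = unname(ft$parameter),
                 p_value = unname(ft$p.value),
                 method = "oneway_anova"),
            class = "gls_test")
}

#' Tukey HSD pairwise comparisons
#'
#' Family-wise adjusted pairwise differences via the studentized-range
#' distribution ([stats::TukeyHSD()] on an [stats::aov()] fit).
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor/vector, >= 2 groups of >= 2 observations.
#' @return Data frame: `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- as.factor(groups)
  check_group_sizes(values, groups)
  tk <- stats::TukeyHSD(stats::aov(values ~ groups))$groups
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

check_group_sizes <- function(values, groups) {
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups", call. = FALSE)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    stop("group '", small[1], "' has fewer than two observations",
         call. = FALSE)
  }
  if (length(values) != length(groups)) {
    stop("values and groups differ in length", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.gls_test <- function(x, ...) {
  df <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g\n",
              x$method, x$statistic, df, x$p_value))
  invisible(x)
}
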