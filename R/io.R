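# File formats: plain-text CSV throughout, ISO-8601 dates, UTC times.
# Twilight times are written HH:MM:SS.mmm; polar sentinels are the strings
# POLAR_DAY / POLAR_NIGHT in the sunrise and sunset columns.

parse_hms <- function(x, line) {
  if (grepl("^[0-9]{1,2}:[0-9]{2}(:[0-9]{2}(\\.[0-9]+)?)?$", x)) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    h <- as.numeric(parts[1]) + as.numeric(parts[2]) / 60 +
      (if (length(parts) == 3) as.numeric(parts[3]) / 3600 else 0)
    if (h >= 0 && h < 24) return(h)
  }
  stop("unparseable time '", x, "' on line ", line, call. = FALSE)
}

format_hms <- function(h) {
  ifelse(is.na(h), NA_character_, {
    h <- h %% 24
    hh <- floor(h)
    mm <- floor((h - hh) * 60)
    ss <- (h - hh - mm / 60) * 3600
    sprintf("%02d:%02d:%06.3f", hh, mm, ss)
  })
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

#' Read twilight records
#'
#' CSV with header `bird_id,date,sunrise,sunset`. Times are `HH:MM[:SS]` UTC
#' or the sentinels `POLAR_DAY` / `POLAR_NIGHT`. Records are returned sorted
#' by bird and date; duplicate (bird, date) pairs are an error.
#'
#' @param path CSV file.
#' @return Data frame `bird_id`, `date` (`Date`), `sunrise`, `sunset` (UTC
#'   decimal hours, `NA` when polar), `polar`, `valid`.
#' @export
read_twilights <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  require_columns(df, c("bird_id", "date", "sunrise", "sunset"), "twilight")
  n <- nrow(df)
  out <- data.frame(bird_id = df$bird_id, date = as.Date(df$date),
                    sunrise = rep(NA_real_, n), sunset = rep(NA_real_, n),
                    polar = rep(NA_character_, n), valid = rep(TRUE, n),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$date))) {
    stop("unparseable date on line ", which(is.na(out$date))[1] + 1, call. = FALSE)
  }
  for (i in seq_len(n)) {
    for (col in c("sunrise", "sunset")) {
      v <- trimws(df[[col]][i])
      if (v %in% c("POLAR_DAY", "POLAR_NIGHT")) {
        out$polar[i] <- if (v == "POLAR_DAY") "day" else "night"
      } else {
        out[[col]][i] <- parse_hms(v, i + 1)
      }
    }
  }
  dup <- duplicated(out[, c("bird_id", "date")])
  if (any(dup)) {
    stop("duplicate twilight record for bird ", out$bird_id[dup][1],
         " on ", format(out$date[dup][1]), call. = FALSE)
  }
  out <- out[order(out$bird_id, out$date), ]
  rownames(out) <- NULL
  out
}

#' Write twilight records
#' @param twilights Twilight data frame (see [read_twilights()]).
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_twilights <- function(twilights, path) {
  sr <- ifelse(!is.na(twilights$polar),
               ifelse(twilights$polar == "day", "POLAR_DAY", "POLAR_NIGHT"),
               format_hms(twilights$sunrise))
  ss <- ifelse(!is.na(twilights$polar),
               ifelse(twilights$polar == "day", "POLAR_DAY", "POLAR_NIGHT"),
               format_hms(twilights$sunset))
  utils::write.csv(data.frame(bird_id = twilights$bird_id,
                              date = format(twilights$date),
                              sunrise = sr, sunset = ss),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

track_cols <- c("bird_id", "date", "lat", "lon", "source", "equinox_flagged",
                "polar_flagged", "speed_rejected", "unsmoothed_jump")

#' Write a track
#'
#' Full-precision CSV (coordinates at 17 significant digits, so a
#' write-then-read round trip reproduces every field exactly).
#'
#' @param track Position data frame.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  df <- track[, track_cols]
  df$date <- format(df$date)
  df$lat <- vapply(track$lat, format, "", digits = 17)
  df$lon <- vapply(track$lon, format, "", digits = 17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a track
#'
#' Validates coordinates (latitude out of [-90, 90] is an error; longitudes
#' outside [-180, 180) are normalised with a warning) and requires strictly
#' increasing dates per bird.
#'
#' @param path Track CSV written by [write_track()].
#' @return Position data frame.
#' @export
read_track <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, track_cols, "track")
  df$date <- as.Date(df$date)
  if (any(!is.na(df$lat) & abs(df$lat) > 90)) {
    stop("latitude out of range in ", path, call. = FALSE)
  }
  bad_lon <- !is.na(df$lon) & (df$lon < -180 | df$lon >= 180)
  if (any(bad_lon)) {
    warning("normalising ", sum(bad_lon), " longitude(s) to [-180, 180)",
            call. = FALSE)
    df$lon <- norm_lon(df$lon)
  }
  for (b in unique(df$bird_id)) {
    d <- df$date[df$bird_id == b]
    if (any(diff(d) <= 0)) {
      stop("dates not strictly increasing for bird ", b, call. = FALSE)
    }
  }
  for (col in c("equinox_flagged", "polar_flagged", "speed_rejected",
                "unsmoothed_jump")) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Read tag SST samples
#' @param path CSV with header `bird_id,date,min_sst` (empty cell = missing).
#' @return Data frame `bird_id`, `date`, `min_sst`.
#' @export
read_sst_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("bird_id", "date", "min_sst"), "SST sample")
  df$date <- as.Date(df$date)
  df$min_sst <- as.numeric(df$min_sst)
  bad <- !is.na(df$min_sst) & (df$min_sst < -2 | df$min_sst > 40)
  if (any(bad)) {
    stop("SST value outside [-2, 40] degC on line ", which(bad)[1] + 1,
         call. = FALSE)
  }
  df
}

#' Write tag SST samples
#' @param samples Data frame `bird_id`, `date`, `min_sst`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_sst_samples <- function(samples, path) {
  utils::write.csv(data.frame(bird_id = samples$bird_id,
                              date = format(samples$date),
                              min_sst = samples$min_sst),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

new_sst_grid <- function(period_start, period_days, lat_axis, lon_axis, values) {
  stopifnot(all(diff(lat_axis) > 0) || all(diff(lat_axis) < 0),
            all(diff(lon_axis) > 0))
  if (any(diff(lat_axis) < 0)) {
    lat_axis <- rev(lat_axis)
    values <- values[rev(seq_len(nrow(values))), , drop = FALSE]
  }
  structure(list(period_start = as.Date(period_start),
                 period_days = as.integer(period_days),
                 lat = lat_axis, lon = lon_axis,
                 values = values,
                 all_missing = all(is.na(values))),
            class = "sst_grid")
}

#' Read an SST composite grid
#'
#' Plain-text grid format: comment header lines `# period_start: YYYY-MM-DD`
#' and `# period_days: N`, then a CSV matrix whose first column is `lat` and
#' whose remaining column names are longitudes. Empty cells are missing.
#' Longitude axes on 0..360 are remapped to [-180, 180).
#'
#' @param path Grid file.
#' @return An `sst_grid`: `period_start`, `period_days`, `lat`, `lon`
#'   (strictly increasing degree axes), `values` (lat x lon matrix),
#'   `all_missing`.
#' @export
read_sst_grid <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  ps <- sub("^#\\s*period_start:\\s*", "", grep("period_start:", hdr, value = TRUE))
  if (length(ps) != 1 || is.na(as.Date(ps[1]))) {
    stop("grid file lacks period metadata; supply a '# period_start: ",
         "YYYY-MM-DD' header line", call. = FALSE)
  }
  pd <- sub("^#\\s*period_days:\\s*", "", grep("period_days:", hdr, value = TRUE))
  pd <- if (length(pd) == 1) as.integer(pd) else 8L
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "lat") stop("grid body must start with a 'lat' column",
                                  call. = FALSE)
  lat_axis <- as.numeric(df$lat)
  lon_axis <- as.numeric(names(df)[-1])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (any(lon_axis >= 180)) {
    lon_axis <- norm_lon(lon_axis)
    ord <- order(lon_axis)
    lon_axis <- lon_axis[ord]
    vals <- vals[, ord, drop = FALSE]
  }
  if (any(abs(lat_axis) > 90)) stop("grid latitude out of range", call. = FALSE)
  dimnames(vals) <- NULL
  new_sst_grid(as.Date(ps[1]), pd, lat_axis, lon_axis, vals)
}

#' Write an SST composite grid
#' @param grid An `sst_grid`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sst_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# sst_grid",
               paste0("# period_start: ", format(grid$period_start)),
               paste0("# period_days: ", grid$period_days)), con)
  df <- as.data.frame(grid$values)
  names(df) <- as.character(grid$lon)
  df <- cbind(lat = grid$lat, df)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' @export
print.sst_grid <- function(x, ...) {
  cat(sprintf("<sst_grid> %s (+%d d), %d x %d cells%s\n",
              format(x$period_start), x$period_days,
              length(x$lat), length(x$lon),
              if (x$all_missing) " [fully masked]" else ""))
  invisible(x)
}
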