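# Readers and writers: headered delimited text with ISO-8601 UTC
# timestamps throughout.

.fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
.parse_time <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write / read a light series
#'
#' Tab-separated text with columns `time` (ISO-8601 UTC) and `light`.
#'
#' @param x a `light_series`.
#' @param path file path.
#' @return `read_light_series` returns a `light_series`.
#' @export
write_light_series <- function(x, path) {
  df <- data.frame(time = .fmt_time(x$samples$time),
                   light = sprintf("%.4f", x$samples$light))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_light_series
#' @param bird_id,year identifiers to attach (not stored in the file).
#' @export
read_light_series <- function(path, bird_id = NA_character_, year = NA_integer_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- list(bird_id = bird_id, year = year,
              samples = data.frame(time = .parse_time(df$time),
                                   light = as.numeric(df$light)))
  class(out) <- "light_series"
  out
}

#' Write / read an immersion series
#'
#' Tab-separated text with columns `time` (ISO-8601 UTC) and `wet` (0/1).
#'
#' @param x an `immersion_series`.
#' @param path file path.
#' @export
write_immersion_series <- function(x, path) {
  df <- data.frame(time = .fmt_time(x$samples$time), wet = x$samples$wet)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_immersion_series
#' @param bird_id,year identifiers to attach.
#' @export
read_immersion_series <- function(path, bird_id = NA_character_,
                                  year = NA_integer_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  tt <- .parse_time(df$time)
  out <- list(bird_id = bird_id, year = year,
              interval_s = as.numeric(tt[2]) - as.numeric(tt[1]),
              samples = data.frame(time = tt, wet = as.integer(df$wet)))
  class(out) <- "immersion_series"
  out
}

#' Write a true itinerary as tidy tables
#'
#' Writes `<stem>_days.tsv` (per-day state, position, realised hours) and
#' `<stem>_summary.tsv` (the phenology scalars).
#'
#' @param itinerary a `true_itinerary`.
#' @param stem path stem.
#' @export
write_itinerary <- function(itinerary, stem) {
  d <- itinerary$days
  d$sunrise <- .fmt_time(d$sunrise); d$sunset <- .fmt_time(d$sunset)
  d$night_end <- .fmt_time(d$night_end)
  utils::write.table(d, paste0(stem, "_days.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- data.frame(bird_id = itinerary$bird_id, year = itinerary$year,
                  colony = itinerary$colony$name, lay_date = itinerary$lay_date,
                  departure_date = itinerary$departure_date,
                  arrival_date = itinerary$arrival_date,
                  duration = itinerary$duration,
                  stopover_days = itinerary$stopover_days,
                  n_stopovers = itinerary$n_stopovers)
  utils::write.table(s, paste0(stem, "_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' Write / read a chlorophyll grid as long-format CSV
#'
#' Columns `lon`, `lat`, `date`, `chlor_a`; missing (cloud-masked) cells
#' are written as empty fields.
#'
#' @param grid a `chl_grid`.
#' @param path file path.
#' @export
write_chl_grid <- function(grid, path) {
  df <- expand.grid(lon = grid$lon, lat = grid$lat,
                    date = as.character(grid$date), stringsAsFactors = FALSE)
  df$chlor_a <- as.vector(grid$values)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_chl_grid
#' @export
read_chl_grid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  date <- sort(unique(as.Date(df$date)))
  v <- array(NA_real_, c(length(lon), length(lat), length(date)))
  v[cbind(match(df$lon, lon), match(df$lat, lat),
          match(as.Date(df$date), date))] <- df$chlor_a
  out <- list(lon = lon, lat = lat, date = date, values = v)
  class(out) <- "chl_grid"
  out
}
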