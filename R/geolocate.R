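# Threshold-method light-level geolocation: twilight detection, bi-daily
# positions, sun-elevation calibration and migration-window detection.
#
# Longitude comes from the timing of local apparent noon/midnight (15
# degrees per hour, corrected by the equation of time); latitude from day
# length inverted at the calibrated sun elevation. Near the equinoxes day
# length is uninformative, so latitude is masked there; longitude is not,
# which is why phenology detection runs on smoothed longitude.

#' Geolocation configuration
#'
#' @param light_threshold light level defining twilight crossings (logger
#'   units; half the saturation maximum of the rendered loggers).
#' @param sun_elev sun elevation (degrees) assumed at the threshold.
#' @param smoothing_window rolling-mean window for daily longitude
#'   (days, odd).
#' @param equinox_halfwidth days around each equinox with latitude
#'   masked.
#' @param min_gap_hours light/dark intervals shorter than this are
#'   treated as shading/flash artifacts and merged away.
#' @param min_daily_lon_change westward smoothed-longitude change
#'   (degrees/day) that counts as migratory movement.
#' @param persistence_days consecutive qualifying days required to call
#'   migration start, and days inside the wintering band to call the end.
#' @param wintering_lon_band `c(min, max)` longitude band of the
#'   wintering region.
#' @return Object of class `geolocation_config`.
#' @export
geolocation_config <- function(light_threshold = 32, sun_elev = -4.5,
                               smoothing_window = 3, equinox_halfwidth = 15,
                               min_gap_hours = 4, min_daily_lon_change = 0.5,
                               persistence_days = 3,
                               wintering_lon_band = c(-66, -54)) {
  stopifnot(smoothing_window >= 1, smoothing_window %% 2 == 1,
            persistence_days >= 1)
  out <- as.list(environment())
  class(out) <- "geolocation_config"
  out
}

#' Detect twilight events from a light series
#'
#' Threshold crossings of the (lightly median-smoothed) light curve,
#' linearly interpolated between samples. Dark or light intervals shorter
#' than `min_gap_hours` are rejected as shading artifacts, which also
#' enforces the rule that a crossing cannot follow an accepted crossing
#' of the same type within that gap. Days with no crossing at all
#' (constant light) yield no events and are reported in the
#' `flagged_dates` attribute.
#'
#' @param light a `light_series`.
#' @param cfg a [geolocation_config()].
#' @return `data.frame` with `time` (`POSIXct` UTC) and `event`
#'   (`"sunrise"`/`"sunset"`), alternating; attribute `flagged_dates`
#'   lists dates without events.
#' @export
detect_twilights <- function(light, cfg = geolocation_config()) {
  s <- light$samples
  if (nrow(s) < 2 || as.numeric(difftime(s$time[nrow(s)], s$time[1],
                                         units = "hours")) < 24)
    stop("detect_twilights: need at least 24 h of data")
  lv <- stats::runmed(s$light, 3)
  above <- lv > cfg$light_threshold
  flips <- which(diff(above) != 0)
  if (length(flips)) {
    # linear interpolation of the crossing instant between samples
    t1 <- as.numeric(s$time[flips]); t2 <- as.numeric(s$time[flips + 1])
    y1 <- lv[flips]; y2 <- lv[flips + 1]
    tc <- t1 + (cfg$light_threshold - y1) / (y2 - y1) * (t2 - t1)
    ev <- ifelse(above[flips + 1], "sunrise", "sunset")
    # merge away intervals shorter than min_gap_hours (shading artifacts)
    repeat {
      if (length(tc) < 2) break
      gaps <- diff(tc) / 3600
      short <- which(gaps < cfg$min_gap_hours)
      if (!length(short)) break
      k <- short[which.min(gaps[short])]
      keep <- setdiff(seq_along(tc), c(k, k + 1))
      tc <- tc[keep]; ev <- ev[keep]
    }
  } else {
    tc <- numeric(0); ev <- character(0)
  }
  out <- data.frame(time = as.POSIXct(tc, origin = "1970-01-01", tz = "UTC"),
                    event = ev, stringsAsFactors = FALSE)
  all_dates <- unique(as.Date(s$time))
  attr(out, "flagged_dates") <- all_dates[!all_dates %in% as.Date(out$time)]
  out
}

#' Position from one twilight pair
#'
#' Longitude from the midpoint of the pair (local apparent noon for a
#' sunrise--sunset pair, local apparent midnight for sunset--sunrise),
#' corrected by the equation of time at 15 degrees/hour. Latitude from
#' the pair's implied day length inverted at `sun_elev`; `NA` within the
#' equinox mask or when the inversion has no root.
#'
#' @param t1,t2 `POSIXct` twilight instants, `t1 < t2`.
#' @param type `"day"` for sunrise--sunset, `"night"` for
#'   sunset--sunrise.
#' @param sun_elev sun elevation in degrees.
#' @param equinox_halfwidth days of latitude masking around the
#'   equinoxes.
#' @return `data.frame` with `date`, `half`, `lon`, `lat`,
#'   `equinox_flag`.
#' @export
estimate_position <- function(t1, t2, type = "day", sun_elev = -4.5,
                              equinox_halfwidth = 15) {
  if (any(t2 <= t1)) stop("estimate_position: twilights out of order")
  n <- length(t1)
  type <- rep_len(type, n)
  mid <- t1 + as.numeric(t2 - t1, units = "secs") / 2
  eot_h <- equation_of_time(mid) / 60
  hours <- (as.numeric(mid) / 3600) %% 24
  target <- ifelse(type == "day", 12, 24)
  lon <- (15 * (target - hours - eot_h) + 180) %% 360 - 180
  len <- as.numeric(t2 - t1, units = "hours")
  len <- ifelse(type == "day", len, 24 - len)
  date <- as.Date(mid)
  lat <- latitude_from_daylength(len, date, sun_elev)
  eq <- is_equinox(date, equinox_halfwidth)
  lat[eq] <- NA_real_
  data.frame(date = date, half = type, lon = lon, lat = lat,
             equinox_flag = eq | is.na(lat))
}

#' Dates within the equinox latitude mask
#'
#' @param date `Date` vector.
#' @param halfwidth mask half-width in days.
#' @return Logical vector.
#' @export
is_equinox <- function(date, halfwidth = 15) {
  yr <- as.integer(format(date, "%Y"))
  d1 <- abs(as.numeric(date - as.Date(paste0(yr, "-03-20"))))
  d2 <- abs(as.numeric(date - as.Date(paste0(yr, "-09-22"))))
  pmin(d1, d2) <= halfwidth
}

#' Build a position track from twilights
#'
#' Pairs alternating twilights into bi-daily positions (one per
#' sunrise--sunset pair, one per sunset--sunrise pair), aggregates them
#' into a daily longitude series, and smooths it with a centred rolling
#' mean.
#'
#' @param twilights output of [detect_twilights()].
#' @param cfg a [geolocation_config()].
#' @param bird_id,year identifiers carried through.
#' @return Object of class `position_track`: `positions` (half-day
#'   rows), `daily` (`date`, `lon`, `lon_smooth`, `lat`), identifiers,
#'   and (once [detect_migration_window()] has run) phenology fields.
#' @export
build_track <- function(twilights, cfg = geolocation_config(),
                        bird_id = NA_character_, year = NA_integer_) {
  tw <- twilights[order(twilights$time), ]
  n <- nrow(tw)
  if (n < 2) stop("build_track: fewer than two twilights")
  first <- tw$time[-n]; second <- tw$time[-1]
  type <- ifelse(tw$event[-n] == "sunrise", "day", "night")
  ok <- ifelse(type == "day", tw$event[-1] == "sunset",
               tw$event[-1] == "sunrise") &
    as.numeric(second - first, units = "hours") < 22
  pos <- estimate_position(first[ok], second[ok], type[ok], cfg$sun_elev,
                           cfg$equinox_halfwidth)
  daily <- stats::aggregate(cbind(lon, lat) ~ date, data = pos,
                            FUN = function(v) mean(v, na.rm = TRUE),
                            na.action = stats::na.pass)
  daily$lat[is.nan(daily$lat)] <- NA_real_
  daily <- daily[order(daily$date), ]
  daily$lon_smooth <- zoo::rollapply(daily$lon, cfg$smoothing_window, mean,
                                     partial = TRUE, align = "center")
  out <- list(bird_id = bird_id, year = year, positions = pos, daily = daily,
              migration_start = as.Date(NA), migration_end = as.Date(NA),
              complete = NA)
  class(out) <- "position_track"
  out
}

#' Calibrate the sun elevation angle against the colony
#'
#' For light recorded at a known colony, finds the elevation in
#' `candidates` that minimises the median absolute error of
#' day-length-derived latitude against the colony latitude over the
#' pre-departure window.
#'
#' @param light a `light_series` covering at least 14 pre-departure days.
#' @param colony_lat colony latitude (degrees).
#' @param until last date of the calibration window (default: all data).
#' @param candidates candidate elevations (degrees).
#' @param cfg a [geolocation_config()] (threshold used for twilights).
#' @return The calibrated elevation (degrees), with attribute `errors`.
#' @export
calibrate_sun_elevation <- function(light, colony_lat, until = NULL,
                                    candidates = seq(-7, -2, by = 0.25),
                                    cfg = geolocation_config()) {
  tw <- detect_twilights(light, cfg)
  if (!is.null(until)) tw <- tw[as.Date(tw$time) <= as.Date(until), ]
  n <- nrow(tw)
  first <- tw$time[-n]; second <- tw$time[-1]
  is_day <- tw$event[-n] == "sunrise" & tw$event[-1] == "sunset"
  if (sum(is_day) < 14)
    stop("calibrate_sun_elevation: need >= 14 pre-departure days")
  len <- as.numeric(second - first, units = "hours")[is_day]
  date <- as.Date(first[is_day])
  keep <- !is_equinox(date, cfg$equinox_halfwidth)
  if (sum(keep) >= 7) { len <- len[keep]; date <- date[keep] }
  err <- vapply(candidates, function(e) {
    lat <- latitude_from_daylength(len, date, e)
    if (all(is.na(lat))) return(NA_real_)
    stats::median(abs(lat - colony_lat), na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(err)))
    stop("calibrate_sun_elevation: no candidate yields finite latitudes")
  out <- candidates[which.min(err)]
  attr(out, "errors") <- data.frame(sun_elev = candidates, error = err)
  out
}

#' Detect the autumn migration window from smoothed longitude
#'
#' Start: the first date opening `persistence_days` consecutive days of
#' westward smoothed-longitude change of at least
#' `min_daily_lon_change` degrees/day. End: the first subsequent date
#' from which the smoothed longitude sits inside `wintering_lon_band`
#' *and* is stationary (daily change below `min_daily_lon_change`) for
#' `persistence_days` consecutive days -- i.e. the bird has arrived and
#' settled, not merely crossed into the band. Tracks without a
#' qualifying start or end are flagged incomplete (and excluded
#' downstream).
#'
#' @param track a `position_track`.
#' @param cfg a [geolocation_config()].
#' @param search_from,search_to bounds of the search window.
#' @return The track with `migration_start`, `migration_end`, `duration`
#'   and `complete` filled in.
#' @export
detect_migration_window <- function(track, cfg = geolocation_config(),
                                    search_from = NULL, search_to = NULL) {
  d <- track$daily
  yr <- format(d$date[1], "%Y")
  if (is.null(search_from)) search_from <- as.Date(paste0(yr, "-08-01"))
  if (is.null(search_to)) search_to <- as.Date(paste0(yr, "-12-31"))
  d <- d[d$date >= search_from & d$date <= search_to, ]
  track$migration_start <- as.Date(NA)
  track$migration_end <- as.Date(NA)
  track$complete <- FALSE
  if (nrow(d) < cfg$persistence_days + 1) return(track)
  # align to a full daily sequence so "consecutive days" is well-defined
  full <- data.frame(date = seq(min(d$date), max(d$date), by = "day"))
  full$lon <- d$lon_smooth[match(full$date, d$date)]
  chg <- diff(full$lon)  # westward movement is negative
  qual <- !is.na(chg) & chg <= -cfg$min_daily_lon_change
  run <- stats::filter(as.numeric(qual), rep(1, cfg$persistence_days),
                       sides = 1)
  hit <- which(run == cfg$persistence_days)
  if (!length(hit)) return(track)
  start_i <- hit[1] - cfg$persistence_days + 1
  # chg[i] is the step from day i to i+1; under a centred W-day rolling
  # mean a position change on day t first shows at step t - (W-1)/2 - 1,
  # so the departure day itself is step + (W-1)/2 + 1
  track$migration_start <- full$date[start_i] +
    (cfg$smoothing_window - 1) / 2 + 1
  # end: longitude has stabilised inside the wintering band (band entry
  # alone would lead true arrival by a travel-speed-dependent margin)
  calm <- c(!is.na(chg) & abs(chg) < cfg$min_daily_lon_change, FALSE)
  inband <- !is.na(full$lon) & full$lon >= cfg$wintering_lon_band[1] &
    full$lon <= cfg$wintering_lon_band[2]
  okday <- inband & calm
  okday[seq_len(min(start_i + 1, length(okday)))] <- FALSE
  brun <- stats::filter(as.numeric(okday), rep(1, cfg$persistence_days),
                        sides = 1)
  bhit <- which(!is.na(brun) & brun == cfg$persistence_days)
  if (!length(bhit)) return(track)
  end_i <- bhit[1] - cfg$persistence_days + 1
  track$migration_end <- full$date[end_i]
  track$duration <- as.numeric(track$migration_end - track$migration_start)
  track$complete <- TRUE
  track
}
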