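# Wet/dry immersion processing: 10-min summary scores, behavioural
# classification (dry = flight, intermediate = foraging, fully wet =
# rest), day/night splitting against detected twilights, and per
# bird-day/night activity metrics.

#' Immersion processing configuration
#'
#' @param bin_minutes summary bin width (minutes).
#' @param max_score score of a fully wet bin.
#' @param forage_bounds inclusive score interval classified as foraging.
#' @return Object of class `immersion_config`.
#' @export
immersion_config <- function(bin_minutes = 10, max_score = 200,
                             forage_bounds = c(1, 199)) {
  stopifnot(forage_bounds[1] > 0, forage_bounds[1] <= forage_bounds[2],
            forage_bounds[2] < max_score)
  out <- as.list(environment())
  class(out) <- "immersion_config"
  out
}

#' Sum raw wet/dry samples into clock-aligned scores
#'
#' Counts wet samples per `bin_minutes` bin aligned to the UTC clock
#' (hh:00, hh:10, ...) and scales the count to `[0, max_score]`. Bins
#' with fewer samples than expected are flagged missing and excluded
#' from downstream hour sums.
#'
#' @param raw an `immersion_series` (regular sampling whose interval
#'   divides the bin width).
#' @param cfg an [immersion_config()].
#' @return `data.frame` with `bin_start` (`POSIXct`), `score`, `missing`;
#'   attribute `bin_seconds`.
#' @export
bin_scores <- function(raw, cfg = immersion_config()) {
  bin_s <- cfg$bin_minutes * 60
  interval <- raw$interval_s
  if (is.null(interval))
    interval <- as.numeric(raw$samples$time[2]) - as.numeric(raw$samples$time[1])
  if (bin_s %% interval != 0)
    stop("bin_scores: sampling interval must divide the bin width")
  n_per_bin <- bin_s / interval
  t <- as.numeric(raw$samples$time)
  bin <- floor(t / bin_s)
  wet <- tapply(raw$samples$wet, bin, sum)
  cnt <- tapply(raw$samples$wet, bin, length)
  bins <- as.numeric(names(wet))
  score <- as.numeric(wet) * (cfg$max_score / n_per_bin)
  out <- data.frame(
    bin_start = as.POSIXct(bins * bin_s, origin = "1970-01-01", tz = "UTC"),
    score = score, missing = as.numeric(cnt) < n_per_bin)
  out$score[out$missing] <- NA_real_
  out <- out[order(out$bin_start), ]
  rownames(out) <- NULL
  attr(out, "bin_seconds") <- bin_s
  out
}

#' Classify a summary score into a behaviour
#'
#' Fully dry bins are flight, fully wet bins are rest (sitting on the
#' water), intermediate scores are foraging.
#'
#' @param score numeric score(s) in `[0, max_score]`; `NA` passes
#'   through.
#' @param cfg an [immersion_config()].
#' @return Character vector: `"flight"`, `"forage"` or `"rest"`.
#' @export
classify_bin <- function(score, cfg = immersion_config()) {
  ok <- is.na(score) | (score >= 0 & score <= cfg$max_score)
  if (!all(ok)) stop("classify_bin: score outside [0, max_score]")
  out <- rep(NA_character_, length(score))
  out[!is.na(score) & score < cfg$forage_bounds[1]] <- "flight"
  out[!is.na(score) & score >= cfg$forage_bounds[1] &
        score <= cfg$forage_bounds[2]] <- "forage"
  out[!is.na(score) & score > cfg$forage_bounds[2]] <- "rest"
  out
}

#' Split scored bins into day and night phases
#'
#' Assigns each bin to the day phase (between a sunrise and the following
#' sunset) or the night phase (sunset to next sunrise) it falls in; bins
#' straddling a twilight are split pro-rata. Day phases are dated by
#' their sunrise, night phases by their sunset.
#'
#' @param bins output of [bin_scores()].
#' @param twilights alternating twilight events ([detect_twilights()]).
#' @return `data.frame` with one row per bin x phase overlap: `bin_start`,
#'   `date`, `phase` (`"day"`/`"night"`), `hours`, `score`, `missing`.
#' @export
split_day_night <- function(bins, twilights) {
  tw <- twilights[order(twilights$time), ]
  bt <- as.numeric(tw$time)
  if (length(bt) < 2) stop("split_day_night: need twilights covering the bins")
  bin_s <- attr(bins, "bin_seconds")
  if (is.null(bin_s)) bin_s <- 600
  s <- as.numeric(bins$bin_start)
  e <- s + bin_s

  interval_info <- function(k) {
    # phase and date of the interval that starts at twilight k (k >= 1);
    # k == 0 is the lead-in before the first twilight
    if (k == 0) {
      if (tw$event[1] == "sunrise") list(phase = "night", date = as.Date(tw$time[1]) - 1)
      else list(phase = "day", date = as.Date(tw$time[1]))
    } else if (tw$event[k] == "sunrise") {
      list(phase = "day", date = as.Date(tw$time[k]))
    } else {
      list(phase = "night", date = as.Date(tw$time[k]))
    }
  }
  ks <- sort(unique(c(findInterval(s, bt), findInterval(e - 1e-6, bt))))
  info <- lapply(ks, interval_info)
  names(info) <- as.character(ks)

  i1 <- findInterval(s, bt)
  i2 <- findInterval(e - 1e-6, bt)
  rows <- vector("list", 2)
  # part lying in the bin's opening interval
  cut <- ifelse(i2 > i1, bt[pmin(i2, length(bt))], e)
  h1 <- (pmin(cut, e) - s) / 3600
  ph1 <- vapply(i1, function(k) info[[as.character(k)]]$phase, character(1))
  dt1 <- as.Date(vapply(i1, function(k) as.character(info[[as.character(k)]]$date),
                        character(1)))
  rows[[1]] <- data.frame(bin_start = bins$bin_start, date = dt1, phase = ph1,
                          hours = h1, score = bins$score,
                          missing = bins$missing)
  straddle <- which(i2 > i1)
  if (length(straddle)) {
    h2 <- (e[straddle] - bt[i2[straddle]]) / 3600
    ph2 <- vapply(i2[straddle], function(k) info[[as.character(k)]]$phase,
                  character(1))
    dt2 <- as.Date(vapply(i2[straddle],
                          function(k) as.character(info[[as.character(k)]]$date),
                          character(1)))
    rows[[2]] <- data.frame(bin_start = bins$bin_start[straddle], date = dt2,
                            phase = ph2, hours = h2,
                            score = bins$score[straddle],
                            missing = bins$missing[straddle])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[out$hours > 1e-9, ]
  out[order(out$bin_start), ]
}

#' Per bird-day/night activity metrics
#'
#' Aggregates phase-labelled classified bins into one row per (date,
#' phase): hours in flight and foraging, covered phase length, and the
#' flight proportion. The longest run of consecutive fully-dry bins
#' (not broken at midnight or twilight) is returned as the
#' `max_continuous_flight_h` attribute.
#'
#' @param split_bins output of [split_day_night()].
#' @param cfg an [immersion_config()].
#' @return `data.frame`: `date`, `phase`, `flight_hours`, `forage_hours`,
#'   `phase_length`, `flight_proportion`; attribute
#'   `max_continuous_flight_h`.
#' @export
daily_metrics <- function(split_bins, cfg = immersion_config()) {
  sb <- split_bins
  sb$behaviour <- classify_bin(sb$score, cfg)
  ok <- !sb$missing & !is.na(sb$behaviour)
  agg <- function(sel, name) {
    if (!any(sel)) return(NULL)
    x <- stats::aggregate(hours ~ date + phase, data = sb[sel, ,
                          drop = FALSE], FUN = sum)
    names(x)[3] <- name
    x
  }
  out <- agg(ok, "phase_length")
  if (is.null(out)) stop("daily_metrics: no usable bins")
  for (piece in list(agg(ok & sb$behaviour == "flight", "flight_hours"),
                     agg(ok & sb$behaviour == "forage", "forage_hours"))) {
    if (!is.null(piece)) out <- merge(out, piece, all.x = TRUE)
  }
  for (col in c("flight_hours", "forage_hours")) {
    if (is.null(out[[col]])) out[[col]] <- 0
    out[[col]][is.na(out[[col]])] <- 0
  }
  out$flight_proportion <- ifelse(out$phase_length > 0,
                                  out$flight_hours / out$phase_length, NA)
  out <- out[order(out$date, out$phase), ]
  rownames(out) <- NULL

  # longest continuous flight across the unsplit bin sequence
  b <- sb[!duplicated(sb$bin_start), ]
  b <- b[order(b$bin_start), ]
  beh <- classify_bin(b$score, cfg)
  contig <- c(TRUE, diff(as.numeric(b$bin_start)) == (cfg$bin_minutes * 60))
  grp <- cumsum(!contig)
  mcf <- 0
  for (g in split(beh, grp)) {
    r <- rle(!is.na(g) & g == "flight")
    if (any(r$values)) mcf <- max(mcf, max(r$lengths[r$values]))
  }
  attr(out, "max_continuous_flight_h") <- mcf * cfg$bin_minutes / 60
  out
}

#' Build the bird-day/night modelling table
#'
#' Joins activity metrics to the position track: adds the night's moon
#' illumination (at the middle of the dark period) and the fraction of
#' the night with the moon risen (at the bird's estimated position), the
#' departure-date covariate (days since 1 August of the detected
#' migration start) and per-day track state flags. `is_stopover_day` is
#' left `NA` for the stopover module to fill.
#'
#' @param metrics output of [daily_metrics()].
#' @param twilights twilight events used for the split.
#' @param track a `position_track` with migration window detected.
#' @param bird_id,year identifiers.
#' @return `data.frame` (one row per date x phase) -- the modelling unit.
#' @export
birdday_table <- function(metrics, twilights, track,
                          bird_id = track$bird_id, year = track$year) {
  out <- metrics
  out$bird_id <- bird_id
  out$year <- year
  # night interval per date from twilights
  tw <- twilights[order(twilights$time), ]
  ss <- tw[tw$event == "sunset", ]
  sr <- tw[tw$event == "sunrise", ]
  nights <- data.frame(date = as.Date(ss$time), start = ss$time)
  nxt <- vapply(nights$start, function(t0) {
    cand <- sr$time[sr$time > t0]
    if (length(cand)) as.numeric(cand[1]) else NA_real_
  }, numeric(1))
  nights$end <- as.POSIXct(nxt, origin = "1970-01-01", tz = "UTC")
  nights <- nights[!is.na(nights$end), ]
  mid <- nights$start + (as.numeric(nights$end) - as.numeric(nights$start)) / 2
  nights$night_moon <- moon_illumination(mid)
  d <- track$daily
  lat_f <- zoo::na.approx(d$lat, x = as.numeric(d$date), rule = 2,
                          na.rm = FALSE)
  if (all(is.na(lat_f))) lat_f <- rep(0, nrow(d))
  idx <- match(nights$date, d$date)
  lon_n <- d$lon_smooth[idx]
  lat_n <- lat_f[idx]
  fallback <- is.na(lon_n)
  if (any(fallback)) {
    lon_n[fallback] <- stats::approx(as.numeric(d$date), d$lon_smooth,
                                     xout = as.numeric(nights$date[fallback]),
                                     rule = 2)$y
    lat_n[fallback] <- stats::approx(as.numeric(d$date), lat_f,
                                     xout = as.numeric(nights$date[fallback]),
                                     rule = 2)$y
  }
  nights$moon_up <- moon_up_fraction(nights$start, nights$end, lon_n, lat_n)
  m <- match(out$date, nights$date)
  out$night_moon <- ifelse(out$phase == "night", nights$night_moon[m], NA)
  out$moon_up <- ifelse(out$phase == "night", nights$moon_up[m], NA)
  if (!is.na(track$migration_start)) {
    aug1 <- as.Date(paste0(format(track$migration_start, "%Y"), "-08-01"))
    out$dep_days_aug1 <- as.numeric(track$migration_start - aug1)
    out$in_migration <- out$date >= track$migration_start &
      out$date < track$migration_end
  } else {
    out$dep_days_aug1 <- NA_real_
    out$in_migration <- FALSE
  }
  out$is_stopover_day <- NA
  out
}
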