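# Render raw sensor streams (light, wet/dry immersion) and gridded
# chlorophyll fields from a true itinerary.

#' Render a geolocator light series from a true itinerary
#'
#' Light is a saturating logistic function of sun altitude at the bird's
#' true position, so the threshold at half the saturation maximum crosses
#' exactly at the configured sun elevation. Optional multiplicative
#' noise and random shading events (dark intervals, as when the sensor is
#' covered) can be added.
#'
#' @param itinerary a `true_itinerary` from [simulate_population()].
#' @param sample_interval_s sampling interval in seconds (default 600,
#'   i.e. 10 min).
#' @param max_light saturation maximum in logger units.
#' @param sun_elev sun elevation (degrees) mapped to half saturation.
#' @param logistic_width width (degrees) of the light transition.
#' @param noise_sd log-scale SD of multiplicative noise (0 = noise-free).
#' @param shading_prob per-day probability of one 20--60 min shading
#'   event.
#' @param seed integer seed for the noise.
#' @return Object of class `light_series`: list with `bird_id`, `year`
#'   and `samples` (`data.frame`: `time`, `light`).
#' @export
render_light <- function(itinerary, sample_interval_s = 600, max_light = 64,
                         sun_elev = -4.5, logistic_width = 1.5,
                         noise_sd = 0, shading_prob = 0, seed = 1) {
  set.seed(as.integer(seed))
  d <- itinerary$days
  t0 <- as.POSIXct(paste(as.character(d$date[1]), "00:00:00"), tz = "UTC")
  n_per_day <- 86400 / sample_interval_s
  n <- nrow(d) * n_per_day
  times <- t0 + (seq_len(n) - 1) * sample_interval_s
  di <- rep(seq_len(nrow(d)), each = n_per_day)
  alt <- sun_altitude(times, d$lon[di], d$lat[di])
  light <- max_light / (1 + exp(-(alt - sun_elev) / logistic_width))
  if (noise_sd > 0) light <- light * exp(stats::rnorm(n, 0, noise_sd))
  if (shading_prob > 0) {
    shaded_day <- which(stats::runif(nrow(d)) < shading_prob)
    for (i in shaded_day) {
      len <- sample(2:6, 1)  # 20-60 min at 10-min sampling
      s <- (i - 1) * n_per_day + sample.int(n_per_day - len, 1)
      light[s:(s + len - 1)] <- light[s:(s + len - 1)] * 0.05
    }
  }
  light <- pmin(pmax(light, 0), max_light)
  out <- list(bird_id = itinerary$bird_id, year = itinerary$year,
              samples = data.frame(time = times, light = light),
              max_light = max_light)
  class(out) <- "light_series"
  out
}

#' Render a wet/dry immersion series from a true itinerary
#'
#' Flight bins are fully dry, rest bins fully wet, and foraging bins get
#' a wet fraction drawn strictly inside (0, 1) so the summed 10-min score
#' is always intermediate.
#'
#' @param itinerary a `true_itinerary`.
#' @param sample_interval_s sampling interval in seconds; must divide 600.
#' @param seed integer seed.
#' @return Object of class `immersion_series`: list with `bird_id`,
#'   `year`, `interval_s` and `samples` (`data.frame`: `time`, `wet`
#'   0/1).
#' @export
render_immersion <- function(itinerary, sample_interval_s = 3, seed = 1) {
  if (600 %% sample_interval_s != 0)
    stop("sample_interval_s must divide 600 seconds")
  set.seed(as.integer(seed))
  bins <- itinerary$bins
  npb <- 600 / sample_interval_s
  wet_counts <- integer(nrow(bins))
  wet_counts[bins$behaviour == 3L] <- npb
  fg <- bins$behaviour == 2L
  wet_counts[fg] <- pmin(npb - 1L, pmax(1L, round(
    stats::runif(sum(fg), 0.05, 0.95) * npb)))
  # place the wet samples at a random offset run within each bin
  off <- integer(nrow(bins))
  need <- wet_counts > 0L & wet_counts < npb
  off[need] <- vapply(npb - wet_counts[need] + 1L,
                      function(m) sample.int(m, 1) - 1L, integer(1))
  n <- nrow(bins) * npb
  wet <- integer(n)
  pos <- rep((seq_len(nrow(bins)) - 1L) * npb, times = wet_counts) +
    sequence(wet_counts) + rep(off, times = wet_counts)
  wet[pos] <- 1L
  times <- rep(as.numeric(bins$start), each = npb) +
    (seq_len(npb) - 1) * sample_interval_s
  out <- list(bird_id = itinerary$bird_id, year = itinerary$year,
              interval_s = sample_interval_s,
              samples = data.frame(
                time = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
                wet = wet))
  class(out) <- "immersion_series"
  out
}

# Fast equivalent of render_immersion + bin_scores: per-bin scores
# without materialising sub-minute samples. Tested to agree with the
# two-step route; used by the pipeline on long multi-bird runs.
.render_immersion_scores <- function(itinerary, max_score = 200, seed = 1) {
  set.seed(as.integer(seed))
  bins <- itinerary$bins
  score <- integer(nrow(bins))
  score[bins$behaviour == 3L] <- max_score
  fg <- bins$behaviour == 2L
  score[fg] <- pmin(max_score - 1L, pmax(1L, round(
    stats::runif(sum(fg), 0.05, 0.95) * max_score)))
  data.frame(bin_start = bins$start, score = score)
}

#' Render a synthetic daily chlorophyll-a grid
#'
#' A regular lon/lat/day grid (mg m^-3) with configurable latitudinal and
#' seasonal linear gradients, optional random cloud masking, and values
#' floored at zero.
#'
#' @param extent list with `lon = c(min, max)`, `lat = c(min, max)` and
#'   `res` (cell size, degrees).
#' @param dates `Date` vector of grid days.
#' @param gradient_params list: `base` (level at `ref_lat`/`ref_date`),
#'   `lat_slope` (per degree), `seasonal_slope` (per day), `ref_lat`,
#'   `ref_date`, `noise_sd`, `missing_frac` (cloud-masked cell fraction).
#' @param seed integer seed.
#' @return Object of class `chl_grid`: list with `lon`, `lat`, `date`
#'   coordinate vectors and a `[lon, lat, date]` value array.
#' @export
render_chl_grid <- function(extent, dates,
                            gradient_params = list(), seed = 1) {
  if (extent$lon[1] >= extent$lon[2] || extent$lat[1] >= extent$lat[2])
    stop("empty extent")
  gp <- utils::modifyList(list(base = 0.5, lat_slope = 0, seasonal_slope = 0,
                               ref_lat = 0, ref_date = dates[1],
                               noise_sd = 0, missing_frac = 0), gradient_params)
  set.seed(as.integer(seed))
  lon <- seq(extent$lon[1] + extent$res / 2, extent$lon[2], by = extent$res)
  lat <- seq(extent$lat[1] + extent$res / 2, extent$lat[2], by = extent$res)
  dates <- as.Date(dates)
  lat_term <- gp$base + gp$lat_slope * (lat - gp$ref_lat)
  v <- array(rep(rep(lat_term, each = length(lon)), times = length(dates)),
             dim = c(length(lon), length(lat), length(dates)))
  tshift <- gp$seasonal_slope * as.numeric(dates - as.Date(gp$ref_date))
  v <- sweep(v, 3, tshift, "+")
  if (gp$noise_sd > 0)
    v <- v + array(stats::rnorm(length(v), 0, gp$noise_sd), dim(v))
  v <- pmax(v, 0)
  if (gp$missing_frac > 0)
    v[stats::runif(length(v)) < gp$missing_frac] <- NA_real_
  out <- list(lon = lon, lat = lat, date = dates, values = v)
  class(out) <- "chl_grid"
  out
}
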