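# Population parameters for the synthetic migration generator.
#
# Defaults encode the study conditions the pipeline is validated against:
# a multi-colony population of trans-equatorial migrants whose departure
# date is driven by lay date, whose stopover budget and migration
# duration shrink with later departure, and whose night flight increases
# with moon illumination. Because the day/night and the moonlight flight
# equations describe one underlying process, the night-flight intercept
# and departure slope are parameterised relative to the day equation (via
# `day_night_flight_offset` and `night_flight_dep_interaction`) with the
# moon terms centred at half illumination, so that both projections of
# the process recover their nominal coefficients.

.DEFAULT_COLONIES <- data.frame(
  name = c("Copeland", "Lundy", "Ramsey", "Rum", "Skomer"),
  lon = c(-5.53, -4.67, -5.29, -6.33, -5.29),
  lat = c(54.68, 51.18, 51.74, 57.01, 51.74),
  stringsAsFactors = FALSE
)

.colony_fx <- function(lundy, ramsey, rum, skomer) {
  c(Copeland = 0, Lundy = lundy, Ramsey = ramsey, Rum = rum, Skomer = skomer)
}

#' Parameters for a synthetic population of migrating birds
#'
#' Builds a validated parameter list for [simulate_population()]. All
#' rate parameters are in the units of the model suite: dates as days,
#' flight and foraging in hours, moon illumination as a 0--1 fraction,
#' the departure-date covariate as days since 1 August.
#'
#' @param n_birds number of birds (each tracked for `n_years` seasons).
#' @param n_years tracked seasons per bird.
#' @param years calendar years of the tracked seasons.
#' @param colonies `data.frame` with `name`, `lon`, `lat`; birds are
#'   assigned round-robin. Baseline level for colony effects is the first
#'   row.
#' @param lay_date_range earliest/latest lay date (month-day, applied to
#'   each year).
#' @param mean_departure month-day of the population mean departure.
#' @param slope_departure_on_lay days of departure delay per day of lay
#'   delay.
#' @param departure_bird_sd,departure_year_sd,departure_resid_sd random
#'   effect / residual SDs of departure date (days).
#' @param stopover_days_intercept,slope_stopover_days_on_departure,stopover_days_resid_sd
#'   total-stopover-days equation (days; slope per day of departure delay).
#' @param duration_intercept,duration_moon_effect,slope_duration_on_departure,duration_moon_dep_interaction,duration_resid_sd
#'   migration-duration equation; the moon covariate is the mean nightly
#'   illuminated fraction over travelling nights.
#' @param day_flight_intercept,day_flight_dep_slope daytime flight-hours
#'   equation on travelling days.
#' @param day_night_flight_offset hours of night flight minus day flight
#'   at half illumination.
#' @param night_flight_dep_interaction additional departure-date slope of
#'   night (vs day) flight hours.
#' @param night_flight_moon_effect hours of night flight per unit
#'   illuminated fraction.
#' @param night_flight_moon_dep_interaction interaction of the moon
#'   effect with departure date.
#' @param forage_night_intercept,forage_night_moon_effect,forage_night_dep_slope,forage_night_moon_dep_interaction
#'   night foraging-hours equation on travelling nights.
#' @param stopover_forage_intercept,stopover_forage_dep_slope,stopover_forage_resid_sd
#'   whole-day foraging hours on stopover days.
#' @param stopover_flighthours_mean,stopover_flighthours_sd whole-day
#'   flight hours on stopover days (the low mixture component).
#' @param bird_random_sd,year_random_sd,residual_sd random-intercept and
#'   residual SDs of the flight/foraging-hours equations (hours).
#' @param colony_effects named list of per-model colony effect vectors
#'   (`flight`, `stopover_days`, `duration`, `forage_night`,
#'   `forage_stopover`), each named by colony with the baseline at 0.
#' @param wintering_box `c(lon_min, lon_max, lat_min, lat_max)` of the
#'   over-wintering region; the route targets its centre.
#' @param moon_window_nights nights after departure over which the mean
#'   moon covariate of the duration equation is averaged (a fixed window
#'   keeps the covariate exogenous to the realised duration).
#' @param stopover_mean_block_length mean length (days) of a contiguous
#'   stopover block.
#' @param min_travel_lead,min_travel_trail minimum travelling days before
#'   the first and after the last stopover.
#' @param sun_elev_threshold sun elevation (degrees) separating day from
#'   night, matched to the light threshold of the rendered loggers.
#' @param immersion_interval_s wet/dry sampling interval (seconds); must
#'   divide 600. The default 3 s gives 200 samples per 10-min bin so the
#'   summed score spans 0--200 exactly.
#' @param start_buffer_days,end_buffer_days rendered days before 1 August
#'   and after arrival.
#' @return Object of class `population_params`.
#' @export
population_params <- function(
    n_birds = 100,
    n_years = 2,
    years = seq(2014, length.out = n_years),
    colonies = .DEFAULT_COLONIES,
    lay_date_range = c("04-26", "06-06"),
    mean_departure = "09-14",
    slope_departure_on_lay = 0.566,
    departure_bird_sd = 2.5,
    departure_year_sd = 0.3,
    departure_resid_sd = 1.5,
    stopover_days_intercept = 15.158,
    slope_stopover_days_on_departure = -0.156,
    stopover_days_resid_sd = 1.0,
    duration_intercept = 50.217,
    duration_moon_effect = -15.633,
    slope_duration_on_departure = -0.323,
    duration_moon_dep_interaction = -0.228,
    duration_resid_sd = 1.5,
    day_flight_intercept = 7.016,
    day_flight_dep_slope = 0.001,
    day_night_flight_offset = -3.827,
    night_flight_dep_interaction = 0.028,
    night_flight_moon_effect = 3.245,
    night_flight_moon_dep_interaction = 0.018,
    forage_night_intercept = 6.134,
    forage_night_moon_effect = -2.846,
    forage_night_dep_slope = 0,
    forage_night_moon_dep_interaction = -0.003,
    stopover_forage_intercept = 12.556,
    stopover_forage_dep_slope = 0.010,
    stopover_forage_resid_sd = 1.0,
    stopover_flighthours_mean = 2.0,
    stopover_flighthours_sd = 0.75,
    bird_random_sd = 0.5,
    year_random_sd = 0.1,
    residual_sd = 1.0,
    colony_effects = list(
      flight = .colony_fx(0.000, 0.218, -0.031, -0.267),
      stopover_days = .colony_fx(0.362, -2.239, 2.164, 0.892),
      duration = .colony_fx(-1.735, -0.656, 4.757, 1.905),
      forage_night = .colony_fx(0.280, 0.196, -0.133, -0.023),
      forage_stopover = .colony_fx(1.524, 1.271, 1.090, 0.638)
    ),
    wintering_box = c(lon_min = -66, lon_max = -54, lat_min = -46, lat_max = -36),
    moon_window_nights = 15,
    stopover_mean_block_length = 2.69,
    min_travel_lead = 3,
    min_travel_trail = 3,
    sun_elev_threshold = -4.5,
    immersion_interval_s = 3,
    start_buffer_days = 12,
    end_buffer_days = 15) {
  p <- as.list(environment())
  class(p) <- "population_params"
  validate_population_params(p)
  p
}

#' @rdname population_params
#' @param p a `population_params` object.
#' @export
validate_population_params <- function(p) {
  stopifnot(inherits(p, "population_params"))
  if (p$n_birds < 1) stop("n_birds must be >= 1")
  if (p$n_years < 1 || length(p$years) != p$n_years) stop("bad years")
  sds <- c(p$departure_bird_sd, p$departure_year_sd, p$departure_resid_sd,
           p$stopover_days_resid_sd, p$duration_resid_sd,
           p$stopover_forage_resid_sd, p$stopover_flighthours_sd,
           p$bird_random_sd, p$year_random_sd, p$residual_sd)
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  ld <- .monthday_to_date(p$lay_date_range, p$years[1])
  if (ld[1] > ld[2]) stop("lay_date_range must be ordered")
  wb <- p$wintering_box
  if (wb[1] >= wb[2] || wb[3] >= wb[4]) stop("wintering_box must be ordered")
  if (600 %% p$immersion_interval_s != 0)
    stop("immersion_interval_s must divide 600 seconds")
  # feasibility: expected duration must exceed stopover days plus minimum
  # travel for departures across the lay-date range
  lay_c <- as.numeric(ld - mean(ld))
  dep0 <- .monthday_to_date(p$mean_departure, p$years[1])
  D <- as.numeric(dep0 - as.Date(paste0(p$years[1], "-08-01"))) +
    p$slope_departure_on_lay * lay_c
  S <- p$stopover_days_intercept + p$slope_stopover_days_on_departure * D
  Tdur <- p$duration_intercept + p$duration_moon_effect * 0.5 +
    (p$slope_duration_on_departure + 0.5 * p$duration_moon_dep_interaction) * D
  if (any(S < 0))
    stop("infeasible parameters: stopover days negative for in-range departures")
  if (any(Tdur - S < p$min_travel_lead + p$min_travel_trail))
    stop("infeasible parameters: migration duration leaves no travelling days")
  invisible(p)
}

.monthday_to_date <- function(md, year) {
  as.Date(ifelse(grepl("^\\d{4}-", md), md, paste0(year, "-", md)))
}

#' Read population parameters from a YAML config file
#'
#' Keys mirror the arguments of [population_params()]; `colonies` may be
#' given as a list of `{name, lon, lat}` records and `colony_effects` as
#' nested maps.
#'
#' @param path YAML file path.
#' @return A `population_params` object.
#' @export
read_population_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$colonies))
    cfg$colonies <- do.call(rbind, lapply(cfg$colonies, as.data.frame))
  if (!is.null(cfg$colony_effects))
    cfg$colony_effects <- lapply(cfg$colony_effects, unlist)
  if (!is.null(cfg$wintering_box)) cfg$wintering_box <- unlist(cfg$wintering_box)
  do.call(population_params, cfg)
}
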