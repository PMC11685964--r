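# Shared fixtures, built once per test run.

.fixtures <- new.env()

# A small multi-colony population with ground truth.
small_pop <- function() {
  if (is.null(.fixtures$pop))
    .fixtures$pop <- simulate_population(
      population_params(n_birds = 4, n_years = 1), seed = 42)
  .fixtures$pop
}

# A medium pipeline run shared by stopover / models / pipeline tests.
# Lay dates observed for all birds so the full model suite fits.
medium_run <- function() {
  if (is.null(.fixtures$run)) {
    cfg <- run_config(params = population_params(n_birds = 8, n_years = 2),
                      n_boot = 200, seed = 5, lay_colonies = NULL)
    .fixtures$run <- suppressMessages(run_all(cfg))
    .fixtures$run_pop <- simulate_population(cfg$params, seed = 5)
  }
  list(res = .fixtures$run, pop = .fixtures$run_pop)
}

# The full-scale recovery run: the multi-colony study population with
# Table-2 generating coefficients, run end-to-end through the pipeline.
recovery_run <- function() {
  if (is.null(.fixtures$big)) {
    cfg <- run_config(params = population_params(n_birds = 100, n_years = 2),
                      n_boot = 200, seed = 1, with_chl = FALSE,
                      models = c(1, 2, 5, 7))
    .fixtures$big <- suppressMessages(run_all(cfg))
    .fixtures$big_pop <- simulate_population(cfg$params, seed = 1)
  }
  list(res = .fixtures$big, pop = .fixtures$big_pop)
}

# Single-colony population with observed lay dates (the lay-date models).
skomer_run <- function() {
  if (is.null(.fixtures$skomer)) {
    skomer <- .DEFAULT_COLONIES[.DEFAULT_COLONIES$name == "Skomer", ]
    cfg <- run_config(params = population_params(n_birds = 89, n_years = 1,
                                                 colonies = skomer),
                      n_boot = 200, seed = 1, with_chl = FALSE,
                      models = c(8, 9), lay_colonies = "Skomer")
    .fixtures$skomer <- suppressMessages(run_all(cfg))
  }
  .fixtures$skomer
}

# Minimal stationary itinerary (constant position) for render tests:
# only the fields the renderers use.
stationary_itinerary <- function(lon = 0, lat = 0,
                                 from = as.Date("2014-08-20"),
                                 n_days = 10, sun_elev = -4.5) {
  dates <- seq(from, by = "day", length.out = n_days)
  tw <- twilight_times(c(dates, max(dates) + 1), lon, lat, sun_elev)
  days <- data.frame(date = dates, state = "breeding", lon = lon, lat = lat,
                     sunrise = tw$sunrise[seq_len(n_days)],
                     sunset = tw$sunset[seq_len(n_days)],
                     night_end = tw$sunrise[seq_len(n_days) + 1])
  t0 <- as.POSIXct(paste(as.character(dates[1]), "00:00:00"), tz = "UTC")
  starts <- t0 + (seq_len(n_days * 144) - 1) * 600
  it <- list(bird_id = "t01", year = as.integer(format(from, "%Y")),
             days = days,
             bins = data.frame(start = starts,
                               behaviour = rep(3L, length(starts))))
  class(it) <- "true_itinerary"
  it
}

# Itinerary whose bins follow a prescribed behaviour vector.
scripted_itinerary <- function(behaviour, from = as.Date("2014-08-20"),
                               lon = 0, lat = 0) {
  n_days <- ceiling(length(behaviour) / 144)
  it <- stationary_itinerary(lon, lat, from, n_days)
  it$bins$behaviour <- rep_len(behaviour, nrow(it$bins))
  it
}
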