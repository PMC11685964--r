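# Synthetic-data generator: parameter handling, generating-model
# consistency, sensor rendering.

test_that("lay dates stay inside the configured range", {
  pop <- small_pop()
  ld <- .monthday_to_date(pop$params$lay_date_range, pop$params$years[1])
  expect_true(all(pop$birds$lay_date >= ld[1] & pop$birds$lay_date <= ld[2]))
})

test_that("degenerate no-effect population departs on one date", {
  p <- population_params(n_birds = 6, n_years = 1,
                         slope_departure_on_lay = 0,
                         departure_bird_sd = 0, departure_year_sd = 0,
                         departure_resid_sd = 0)
  pop <- simulate_population(p, seed = 3)
  expect_equal(length(unique(pop$birds$departure_date)), 1L)
})

test_that("regressing true departure on lay recovers the configured slope", {
  p <- population_params(n_birds = 50)
  pop <- simulate_population(p, seed = 1)
  b <- pop$birds
  lay <- as.numeric(b$lay_date - as.Date(paste0(b$year, "-04-26")))
  dep <- as.numeric(b$departure_date - as.Date(paste0(b$year, "-08-01")))
  slope <- unname(coef(lm(dep ~ lay))[2])
  expect_lt(abs(slope - p$slope_departure_on_lay), 0.05)
})

test_that("simulation is deterministic given seed and params", {
  p <- population_params(n_birds = 3, n_years = 1)
  expect_identical(simulate_population(p, seed = 9),
                   simulate_population(p, seed = 9))
  expect_false(identical(simulate_population(p, seed = 9),
                         simulate_population(p, seed = 10)))
})

test_that("generated flight hours respect phase lengths", {
  pop <- small_pop()
  for (it in pop$itineraries) {
    d <- it$days
    expect_true(all(d$flight_night_h >= 0))
    expect_true(all(d$flight_night_h <= d$night_length + 1 / 6))
    expect_true(all(d$flight_day_h <= d$day_length + 1 / 6))
    expect_true(all(d$flight_day_h + d$forage_day_h <= d$day_length + 1 / 3))
  }
})

test_that("stopover days have fewer flight hours than travel days", {
  pop <- small_pop()
  d <- do.call(rbind, lapply(pop$itineraries, function(it) it$days))
  tot <- d$flight_day_h + d$flight_night_h
  expect_lt(max(tot[d$state == "stopover"]), min(tot[d$state == "migrating"]))
})

test_that("infeasible parameterisations error out", {
  expect_error(population_params(slope_stopover_days_on_departure = -2),
               "infeasible")
  expect_error(population_params(lay_date_range = c("06-06", "04-26")),
               "ordered")
  expect_error(population_params(immersion_interval_s = 7), "divide")
})

test_that("rendered light matches equinox and twilight geometry", {
  it <- stationary_itinerary(lon = 0, lat = 0, from = as.Date("2014-09-18"),
                             n_days = 6)
  ls1 <- render_light(it, noise_sd = 0, shading_prob = 0)
  # equatorial equinox: light above threshold about 12 h of each 24 h
  frac <- mean(ls1$samples$light > 32)
  expect_lt(abs(frac - 0.5), 0.03)
  # twilight-derived day length matches the ephemeris day length
  tw <- detect_twilights(ls1, geolocation_config())
  n <- nrow(tw)
  is_day <- tw$event[-n] == "sunrise" & tw$event[-1] == "sunset"
  len <- as.numeric(tw$time[-1] - tw$time[-n], units = "hours")[is_day]
  pred <- day_length(as.Date(tw$time[-n][is_day]), 0, -4.5)
  expect_true(all(abs(len - pred) < 600 / 3600))
})

test_that("shading events are detected and rejected", {
  it <- stationary_itinerary(lon = -5, lat = 50, from = as.Date("2014-08-05"),
                             n_days = 30)
  clean <- render_light(it, noise_sd = 0, shading_prob = 0)
  shaded <- render_light(it, noise_sd = 0, shading_prob = 0.2, seed = 7)
  expect_gt(sum(abs(shaded$samples$light - clean$samples$light) > 1), 0)
  tw_clean <- detect_twilights(clean)
  tw_shaded <- detect_twilights(shaded)
  expect_equal(nrow(tw_shaded), nrow(tw_clean))
  expect_true(all(abs(as.numeric(tw_shaded$time) -
                        as.numeric(tw_clean$time)) < 1200))
})

test_that("immersion rendering maps behaviours to scores exactly", {
  # all-flight day -> all scores 0; all-rest day -> all scores 200
  it_f <- scripted_itinerary(rep(1L, 144))
  it_r <- scripted_itinerary(rep(3L, 144))
  cfg <- immersion_config()
  sc_f <- bin_scores(render_immersion(it_f, 3, seed = 1), cfg)
  sc_r <- bin_scores(render_immersion(it_r, 3, seed = 1), cfg)
  expect_true(all(sc_f$score == 0))
  expect_true(all(sc_r$score == 200))
  # forage bins score strictly inside [1, 199]
  it_g <- scripted_itinerary(rep(2L, 144))
  sc_g <- bin_scores(render_immersion(it_g, 3, seed = 3), cfg)
  expect_true(all(sc_g$score >= 1 & sc_g$score <= 199))
  expect_error(render_immersion(it_g, 7), "divide")
})

test_that("fast score rendering agrees with the raw-sample route", {
  it <- scripted_itinerary(rep(c(1L, 2L, 3L), each = 48))
  via_raw <- bin_scores(render_immersion(it, 3, seed = 11))
  fast <- .render_immersion_scores(it, seed = 11)
  expect_equal(via_raw$score[via_raw$score %in% c(0, 200)],
               fast$score[fast$score %in% c(0, 200)])
  # forage bins differ in draw but stay in the same class
  expect_true(all((via_raw$score %in% 1:199) == (fast$score %in% 1:199)))
})

test_that("chlorophyll grids honour gradients and masking", {
  dates <- seq(as.Date("2014-09-01"), by = "day", length.out = 3)
  ext <- list(lon = c(-10, 10), lat = c(-10, 10), res = 1)
  uni <- render_chl_grid(ext, dates, list(base = 1), seed = 1)
  expect_true(all(uni$values == 1))
  expect_error(render_chl_grid(list(lon = c(1, 1), lat = c(0, 1), res = 1),
                               dates), "empty")
  # 30% missing cells: box means use available cells only
  msk <- render_chl_grid(ext, dates, list(base = 2, missing_frac = 0.3),
                         seed = 11)
  expect_true(anyNA(msk$values))
  m <- box_mean(msk, c(-5, 5, -5, 5), dates)
  # enumeration oracle
  li <- which(msk$lon > -5 & msk$lon < 5)
  la <- which(msk$lat > -5 & msk$lat < 5)
  v <- msk$values[li, la, ]
  expect_equal(m, sum(v[!is.na(v)]) / sum(!is.na(v)))
  expect_false(is.na(m))
})

test_that("sensor series survive a write/read round trip", {
  it <- scripted_itinerary(rep(c(1L, 3L), 72), from = as.Date("2014-08-20"))
  ls1 <- render_light(it, noise_sd = 0.05, seed = 2)
  f1 <- tempfile(fileext = ".tsv")
  write_light_series(ls1, f1)
  back <- read_light_series(f1, "t01", 2014L)
  expect_equal(back$samples$time, ls1$samples$time)
  expect_equal(back$samples$light, ls1$samples$light, tolerance = 1e-4)

  im <- render_immersion(it, 30, seed = 2)
  f2 <- tempfile(fileext = ".tsv")
  write_immersion_series(im, f2)
  back2 <- read_immersion_series(f2)
  expect_identical(back2$samples$wet, im$samples$wet)
  expect_equal(back2$interval_s, 30)

  g <- render_chl_grid(list(lon = c(0, 4), lat = c(0, 4), res = 1),
                       seq(as.Date("2014-09-01"), by = "day", length.out = 2),
                       list(base = 0.7, lat_slope = 0.05, missing_frac = 0.2),
                       seed = 4)
  f3 <- tempfile(fileext = ".csv")
  write_chl_grid(g, f3)
  back3 <- read_chl_grid(f3)
  expect_equal(back3$values, g$values, tolerance = 1e-8)
  unlink(c(f1, f2, f3))
})

test_that("population config can be read from YAML", {
  f <- tempfile(fileext = ".yml")
  writeLines(c("n_birds: 5", "n_years: 1",
               "slope_departure_on_lay: 0.4",
               "wintering_box:", "  lon_min: -66", "  lon_max: -54",
               "  lat_min: -46", "  lat_max: -36"), f)
  p <- read_population_config(f)
  expect_s3_class(p, "population_params")
  expect_equal(p$n_birds, 5)
  expect_equal(p$slope_departure_on_lay, 0.4)
  unlink(f)
})
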