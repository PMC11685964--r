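# Threshold geolocation: twilights, positions, calibration, migration
# window.

test_that("twilights from noise-free light match ephemeris predictions", {
  it <- stationary_itinerary(lon = -5.29, lat = 51.74,
                             from = as.Date("2014-08-05"), n_days = 8)
  tw <- detect_twilights(render_light(it), geolocation_config())
  expect_true(all(tw$event[seq(1, nrow(tw), 2)] == tw$event[1]))
  pred <- twilight_times(unique(as.Date(tw$time)), -5.29, 51.74, -4.5)
  for (i in seq_len(nrow(pred))) {
    got_r <- tw$time[tw$event == "sunrise" & as.Date(tw$time) == pred$date[i]]
    if (length(got_r) == 1)
      expect_lt(abs(as.numeric(got_r - pred$sunrise[i], units = "secs")), 600)
    got_s <- tw$time[tw$event == "sunset" & as.Date(tw$time) == pred$date[i]]
    if (length(got_s) == 1)
      expect_lt(abs(as.numeric(got_s - pred$sunset[i], units = "secs")), 600)
  }
})

test_that("an injected mid-day shading event is rejected", {
  it <- stationary_itinerary(lon = 0, lat = 45, from = as.Date("2014-08-10"),
                             n_days = 4)
  ls1 <- render_light(it)
  n_before <- nrow(detect_twilights(ls1))
  # 30 min of darkness around local noon on day 2
  sel <- ls1$samples$time >= as.POSIXct("2014-08-11 12:00:00", tz = "UTC") &
    ls1$samples$time < as.POSIXct("2014-08-11 12:30:00", tz = "UTC")
  ls1$samples$light[sel] <- 0.5
  tw <- detect_twilights(ls1)
  expect_equal(nrow(tw), n_before)
})

test_that("a constant-light day yields no events but a flag", {
  it <- stationary_itinerary(lon = 0, lat = 45, from = as.Date("2014-08-10"),
                             n_days = 3)
  ls1 <- render_light(it)
  dark <- as.Date(ls1$samples$time) == as.Date("2014-08-11")
  ls1$samples$light[dark] <- 0
  tw <- detect_twilights(ls1)
  expect_false(as.Date("2014-08-11") %in% as.Date(tw$time))
  expect_true(as.Date("2014-08-11") %in% attr(tw, "flagged_dates"))
})

test_that("position estimation follows noon-timing and day-length rules", {
  # solar noon at 12:00 UTC on a near-zero equation-of-time date -> lon 0
  d <- as.Date("2014-09-01")
  eot_h <- equation_of_time(as.POSIXct(paste(d, "12:00:00"), tz = "UTC")) / 60
  t1 <- as.POSIXct(paste(d, "05:30:00"), tz = "UTC") - eot_h * 3600
  t2 <- as.POSIXct(paste(d, "18:30:00"), tz = "UTC") - eot_h * 3600
  pos <- estimate_position(t1, t2, "day", -4.5)
  expect_lt(abs(pos$lon), 0.4)
  # solar noon at 15:26 UTC -> lon ~ -51.5
  mid <- as.POSIXct(paste(d, "15:26:00"), tz = "UTC") - eot_h * 3600
  pos2 <- estimate_position(mid - 6.5 * 3600, mid + 6.5 * 3600, "day", -4.5)
  expect_lt(abs(pos2$lon - (-51.5)), 0.4)
  # ~12 h day at the equinox: latitude masked
  pos3 <- estimate_position(as.POSIXct("2014-09-22 06:00:00", tz = "UTC"),
                            as.POSIXct("2014-09-22 18:00:00", tz = "UTC"),
                            "day", -4.5)
  expect_true(is.na(pos3$lat))
  expect_true(pos3$equinox_flag)
  expect_error(estimate_position(t2, t1), "order")
})

test_that("sun-elevation calibration recovers the generating threshold", {
  it <- stationary_itinerary(lon = -5.29, lat = 51.74,
                             from = as.Date("2014-06-20"), n_days = 20)
  ls1 <- render_light(it, sun_elev = -4.5)
  cal <- calibrate_sun_elevation(ls1, 51.74)
  expect_lt(abs(cal - (-4.5)), 0.5)
  # determinism: same data twice -> identical calibration
  expect_identical(as.numeric(cal),
                   as.numeric(calibrate_sun_elevation(ls1, 51.74)))
  # a range containing the generating value beats one that excludes it
  err <- attr(cal, "errors")
  in_err <- min(err$error[abs(err$sun_elev + 4.5) <= 0.5])
  out_err <- min(err$error[abs(err$sun_elev + 4.5) > 1.5])
  expect_lt(in_err, out_err)
})

test_that("longitude smoothing leaves a constant track unchanged", {
  # twilights generated at a fixed position give near-constant longitude;
  # the rolling mean must not move it
  dates <- seq(as.Date("2014-08-01"), by = "day", length.out = 12)
  tw <- twilight_times(dates, -20, 40, -4.5)
  twl <- data.frame(time = as.POSIXct(c(rbind(as.numeric(tw$sunrise),
                                              as.numeric(tw$sunset))),
                                      origin = "1970-01-01", tz = "UTC"),
                    event = rep(c("sunrise", "sunset"), length(dates)))
  tr <- build_track(twl, geolocation_config())
  expect_lt(max(abs(tr$daily$lon_smooth - tr$daily$lon)), 0.05)
  expect_lt(max(abs(tr$daily$lon - (-20))), 0.3)
})

test_that("migration window detection matches generator truth", {
  run <- medium_run()
  for (b in run$res$birds) {
    it <- run$pop$itineraries[[b$itinerary_index]]
    expect_lte(abs(as.numeric(b$track$migration_start - it$departure_date)),
               2)
    expect_lte(abs(as.numeric(b$track$migration_end - it$arrival_date)), 3)
  }
})

test_that("a stationary bird is flagged incomplete", {
  it <- stationary_itinerary(lon = -5.29, lat = 51.74,
                             from = as.Date("2014-08-01"), n_days = 60)
  tr <- detect_migration_window(build_track(detect_twilights(render_light(it)),
                                            geolocation_config()))
  expect_false(tr$complete)
  expect_true(is.na(tr$migration_start))
})

test_that("a long mid-route stopover still yields an end date", {
  # hand-built daily longitudes: depart Sep 14, 5 days westward, a
  # 22-day stopover, then onward to the wintering band
  dates <- seq(as.Date("2014-08-01"), as.Date("2014-12-15"), by = "day")
  lon <- rep(-5.3, length(dates))
  dep <- which(dates == as.Date("2014-09-14"))
  i <- dep
  for (k in 1:5) { lon[i] <- lon[i - 1] - 2.6; i <- i + 1 }
  for (k in 1:22) { lon[i] <- lon[i - 1]; i <- i + 1 }
  while (lon[i - 1] > -60 && i <= length(dates)) {
    lon[i] <- max(-60, lon[i - 1] - 2.6); i <- i + 1
  }
  lon[i:length(dates)] <- -60
  daily <- data.frame(date = dates, lon = lon, lat = NA_real_)
  daily$lon_smooth <- zoo::rollapply(daily$lon, 3, mean, partial = TRUE,
                                     align = "center")
  tr <- structure(list(bird_id = "x", year = 2014L, daily = daily,
                       migration_start = as.Date(NA),
                       migration_end = as.Date(NA), complete = NA),
                  class = "position_track")
  tr <- detect_migration_window(tr, geolocation_config())
  expect_true(tr$complete)
  expect_lte(abs(as.numeric(tr$migration_start - as.Date("2014-09-14"))), 2)
  # the 22 stopover days are inside the window
  expect_gt(tr$duration, 22 + 5)
  # invariance to adding pre-August data
  daily2 <- rbind(data.frame(date = seq(as.Date("2014-07-01"),
                                        as.Date("2014-07-31"), by = "day"),
                             lon = -5.3, lat = NA_real_, lon_smooth = -5.3),
                  daily)
  tr2 <- structure(list(bird_id = "x", year = 2014L, daily = daily2,
                        migration_start = as.Date(NA),
                        migration_end = as.Date(NA), complete = NA),
                   class = "position_track")
  tr2 <- detect_migration_window(tr2, geolocation_config())
  expect_identical(tr$migration_start, tr2$migration_start)
  expect_identical(tr$migration_end, tr2$migration_end)
})

test_that("round-trip position recovery is accurate away from equinox", {
  pop <- small_pop()
  it <- pop$itineraries[[1]]
  cfg <- geolocation_config()
  tr <- build_track(detect_twilights(render_light(it), cfg), cfg)
  m <- merge(tr$daily, it$days[, c("date", "lon", "lat")], by = "date",
             suffixes = c("_est", "_true"))
  expect_lt(sqrt(mean((m$lon_est - m$lon_true)^2)), 0.5)
  ne <- !is.na(m$lat_est)
  expect_lt(sqrt(mean((m$lat_est[ne] - m$lat_true[ne])^2)), 2)
  # latitude is masked within the equinox window
  expect_true(all(is.na(m$lat_est[is_equinox(m$date, cfg$equinox_halfwidth)])))
})
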