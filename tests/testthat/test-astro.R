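# Solar and lunar ephemeris checks against frozen astronomical facts and
# brute-force oracles.

test_that("sun altitude matches known geometry", {
  # summer solstice noon at Greenwich meridian, 51.7 N:
  # altitude = 90 - lat + declination (23.435) at solar noon (~12:02 UTC)
  alt <- sun_altitude(as.POSIXct("2020-06-21 12:02:00", tz = "UTC"), 0, 51.7)
  expect_lt(abs(alt - (90 - 51.7 + 23.435)), 0.3)
  # polar night: at the pole every hour angle gives altitude = declination
  tt <- as.POSIXct("2020-12-21 00:00:00", tz = "UTC") + (0:23) * 3600
  expect_true(all(abs(sun_altitude(tt, 0, 90) - (-23.43)) < 0.3))
  # equinox, equator, near solar noon: sun close to zenith
  eot <- equation_of_time(as.POSIXct("2020-03-20 12:00:00", tz = "UTC"))
  noon <- as.POSIXct("2020-03-20 12:00:00", tz = "UTC") - eot * 60
  expect_gt(sun_altitude(noon, 0, 0), 89.5)
})

test_that("day length behaves at equinox, equator and against bisection", {
  expect_true(all(abs(day_length(as.Date("2020-03-20"),
                                 c(-60, -30, 0, 30, 60), 0) - 12) < 0.3))
  dates <- as.Date(c("2020-01-15", "2020-05-10", "2020-09-01", "2020-11-20"))
  expect_true(all(abs(day_length(dates, 0, 0) - 12) < 0.2))

  # brute-force oracle: bisection root-finding on sun_altitude
  bisect_daylength <- function(date, lat, elev) {
    day0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
    f <- function(h) sun_altitude(day0 + h * 3600, 0, lat) - elev
    up <- stats::uniroot(f, c(0, 12), tol = 1e-6)$root
    dn <- stats::uniroot(f, c(12, 24), tol = 1e-6)$root
    dn - up
  }
  for (case in list(c(51.7, 0), c(51.7, -4.5), c(-35, -4.5))) {
    expect_lt(abs(day_length(as.Date("2020-06-21"), case[1], case[2]) -
                    bisect_daylength("2020-06-21", case[1], case[2])), 0.05)
  }
  # polar day / night return 24 / 0, not an error
  expect_equal(day_length(as.Date("2020-06-21"), 80, 0), 24)
  expect_equal(day_length(as.Date("2020-12-21"), 80, 0), 0)
})

test_that("day length is hemispherically symmetric with solstices swapped", {
  expect_lt(abs(day_length(as.Date("2020-06-21"), 40, 0) -
                  day_length(as.Date("2020-12-21"), -40, 0)), 0.15)
  expect_lt(abs(day_length(as.Date("2020-06-21"), -55, -4.5) -
                  day_length(as.Date("2020-12-21"), 55, -4.5)), 0.15)
})

test_that("latitude inversion round-trips day length", {
  dates <- as.Date(c("2020-06-21", "2020-08-15", "2020-11-05"))
  for (d in seq_along(dates)) {
    for (lat in c(-45, -10, 20, 52)) {
      len <- day_length(dates[d], lat, -4.5)
      expect_lt(abs(latitude_from_daylength(len, dates[d], -4.5) - lat), 0.2)
    }
  }
  # equinox degeneracy: ~12 h day has no informative root
  expect_true(is.na(latitude_from_daylength(12.8, as.Date("2020-09-22"),
                                            -4.5)) ||
                abs(latitude_from_daylength(12.8, as.Date("2020-09-22"),
                                            -4.5)) <= 90)
})

test_that("altitude-above-threshold fraction equals day length", {
  # consistency: fraction of the day with altitude > e == day_length(e)/24
  day0 <- as.POSIXct("2020-07-10 00:00:00", tz = "UTC")
  tt <- day0 + seq(0, 86400 - 60, by = 60)
  for (e in c(0, -4.5)) {
    frac <- mean(sun_altitude(tt, 0, 45) > e)
    expect_lt(abs(frac - day_length(as.Date("2020-07-10"), 45, e) / 24),
              1.5 / 1440)
  }
})

test_that("moon illumination hits frozen syzygies within 0.02", {
  # greatest-eclipse instants are exact full/new moons
  fulls <- as.POSIXct(c("2015-09-28 02:47", "2018-07-27 20:22",
                        "2019-01-21 05:12", "2021-05-26 11:19",
                        "2022-05-16 04:11"), tz = "UTC")
  news <- as.POSIXct(c("2015-03-20 09:46", "2017-08-21 18:25",
                       "2019-07-02 19:23", "2021-12-04 07:34",
                       "2024-04-08 18:17"), tz = "UTC")
  expect_true(all(moon_illumination(fulls) >= 0.98))
  expect_true(all(moon_illumination(news) <= 0.02))
})

test_that("moon position coincides with the sun at a total solar eclipse", {
  t <- as.POSIXct("2017-08-21 18:25", tz = "UTC")
  expect_lt(abs(moon_altitude(t, -87.67, 36.97) -
                  sun_altitude(t, -87.67, 36.97)), 1.5)
})

test_that("illumination is periodic with the synodic month", {
  tt <- as.POSIXct("2015-01-01 00:00", tz = "UTC") + seq(0, 370 * 86400, 3600)
  k <- moon_illumination(tt)
  # local maxima (full moons)
  pk <- which(diff(sign(diff(k))) == -2) + 1
  pk <- pk[k[pk] > 0.9]
  periods <- diff(as.numeric(tt[pk])) / 86400
  expect_true(all(abs(periods - 29.53) < 0.3))
  # each cycle spans at least [0.02, 0.98]
  for (i in seq_len(length(pk) - 1)) {
    expect_lt(min(k[pk[i]:pk[i + 1]]), 0.02)
    expect_gt(max(k[pk[i]:pk[i + 1]]), 0.98)
  }
})

test_that("illumination rejects out-of-epoch times", {
  expect_error(moon_illumination(as.POSIXct("1980-01-01", tz = "UTC")),
               "epoch")
})

test_that("moon windows match opposition/conjunction geometry", {
  # full moon night: moon up essentially the whole dark period
  mw <- moon_windows(as.Date("2015-09-27"), 0, 51.7)
  expect_gt(mw$illumination, 0.98)
  expect_gt(mw$up_fraction, 0.9)
  # new moon night: essentially never up
  mw2 <- moon_windows(as.Date("2015-09-13"), 0, 51.7)
  expect_lt(mw2$up_fraction, 0.1)
})

test_that("moon rise/set agrees with a dense-scan bisection oracle", {
  # independent oracle: 1-min scan for altitude threshold crossings
  oracle_crossings <- function(t0, t1, lon, lat) {
    tt <- seq(t0, t1, by = 60)
    up <- moon_altitude(tt, lon, lat) > 0.125
    flips <- which(diff(up) != 0)
    as.numeric(tt[flips]) + 30
  }
  cases <- list(c(-5.3, 51.7), c(-40, -10), c(10, 35))
  d <- as.Date("2014-10-03")
  for (cs in cases) {
    mw <- moon_windows(d, cs[1], cs[2])
    oc <- oracle_crossings(mw$night_start, mw$night_end, cs[1], cs[2])
    solved <- c(rise = as.numeric(mw$rise), set = as.numeric(mw$set))
    solved <- solved[!is.na(solved)]
    expect_equal(length(solved), length(oc))
    if (length(oc))
      expect_true(all(abs(sort(solved) - sort(oc)) < 15 * 60))
  }
})
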