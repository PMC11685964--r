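# Solar and lunar ephemeris (truncated Meeus-style series).
#
# Accuracy is amply sufficient for light-level geolocation work: sun
# position good to ~0.01 deg, moon position to ~0.1 deg, illuminated
# fraction to ~0.005, rise/set to a few minutes -- all far below the
# positional error of threshold geolocation itself.

.DEG <- pi / 180

.jd <- function(time) as.numeric(time) / 86400 + 2440587.5

.jcent <- function(time) (.jd(time) - 2451545.0) / 36525

.wrap360 <- function(x) x %% 360

# Low-precision solar coordinates. Returns a list of numeric vectors:
# apparent ecliptic longitude, right ascension, declination (degrees),
# equation of time (minutes, apparent - mean), distance (km).
.sun_coords <- function(time) {
  T <- .jcent(time)
  L0 <- .wrap360(280.46646 + 36000.76983 * T + 0.0003032 * T^2)
  M <- .wrap360(357.52911 + 35999.05029 * T - 0.0001537 * T^2)
  e <- 0.016708634 - 0.000042037 * T - 0.0000001267 * T^2
  Mr <- M * .DEG
  C <- (1.914602 - 0.004817 * T - 0.000014 * T^2) * sin(Mr) +
    (0.019993 - 0.000101 * T) * sin(2 * Mr) +
    0.000289 * sin(3 * Mr)
  true_lon <- L0 + C
  nu <- Mr + C * .DEG
  dist_au <- 1.000001018 * (1 - e^2) / (1 + e * cos(nu))
  omega <- (125.04 - 1934.136 * T) * .DEG
  app_lon <- true_lon - 0.00569 - 0.00478 * sin(omega)
  eps0 <- 23 + 26 / 60 + 21.448 / 3600 -
    (46.8150 * T + 0.00059 * T^2 - 0.001813 * T^3) / 3600
  eps <- (eps0 + 0.00256 * cos(omega)) * .DEG
  lam <- app_lon * .DEG
  ra <- atan2(cos(eps) * sin(lam), cos(lam)) / .DEG
  dec <- asin(sin(eps) * sin(lam)) / .DEG
  y <- tan(eps / 2)^2
  L0r <- L0 * .DEG
  E <- y * sin(2 * L0r) - 2 * e * sin(Mr) + 4 * e * y * sin(Mr) * cos(2 * L0r) -
    0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * Mr)
  list(app_lon = .wrap360(app_lon), ra = .wrap360(ra), dec = dec,
       eqtime_min = 4 * E / .DEG, dist_km = dist_au * 149597870.7)
}

.gmst_deg <- function(time) {
  jd <- .jd(time)
  T <- (jd - 2451545.0) / 36525
  .wrap360(280.46061837 + 360.98564736629 * (jd - 2451545.0) +
             0.000387933 * T^2 - T^3 / 38710000)
}

.altitude <- function(ra, dec, time, lon, lat) {
  H <- (.gmst_deg(time) + lon - ra) * .DEG
  phi <- lat * .DEG
  d <- dec * .DEG
  asin(pmin(1, pmax(-1, sin(phi) * sin(d) + cos(phi) * cos(d) * cos(H)))) / .DEG
}

#' Solar altitude above the horizon
#'
#' Geocentric apparent altitude of the sun's centre, without refraction.
#' Vectorised over all arguments.
#'
#' @param time `POSIXct` instant(s), UTC.
#' @param lon,lat position in decimal degrees (longitude west-negative).
#' @return Altitude in degrees, in `[-90, 90]`.
#' @export
sun_altitude <- function(time, lon, lat) {
  stopifnot(all(abs(lat) <= 90))
  s <- .sun_coords(time)
  .altitude(s$ra, s$dec, time, lon, lat)
}

#' Equation of time
#'
#' @param time `POSIXct` instant(s), UTC.
#' @return Apparent minus mean solar time, in minutes.
#' @export
equation_of_time <- function(time) .sun_coords(time)$eqtime_min

#' Solar declination
#'
#' @param time `POSIXct` instant(s), UTC.
#' @return Declination in degrees.
#' @export
solar_declination <- function(time) .sun_coords(time)$dec

.noon_dec_eot <- function(date) {
  t <- as.POSIXct(paste(as.character(date), "12:00:00"), tz = "UTC")
  s <- .sun_coords(t)
  list(dec = s$dec, eot = s$eqtime_min)
}

#' Day length at a reference sun elevation
#'
#' Time per 24 h with the sun above `sun_elev`. Polar day/night return
#' 24/0 rather than an error. `sun_elev = "horizon"` applies the standard
#' -0.833 degree rise/set adjustment (refraction plus solar radius);
#' numeric elevations (e.g. the -4.5 degree geolocation threshold) are
#' used as-is.
#'
#' @param date `Date` (or coercible) vector.
#' @param lat latitude in degrees.
#' @param sun_elev reference sun elevation in degrees, or `"horizon"`.
#' @return Hours in `[0, 24]`.
#' @export
day_length <- function(date, lat, sun_elev = 0) {
  stopifnot(all(abs(lat) <= 90))
  if (identical(sun_elev, "horizon")) sun_elev <- -0.833
  nd <- .noon_dec_eot(as.Date(date))
  cosH0 <- (sin(sun_elev * .DEG) - sin(lat * .DEG) * sin(nd$dec * .DEG)) /
    (cos(lat * .DEG) * cos(nd$dec * .DEG))
  out <- numeric(length(cosH0))
  out[cosH0 <= -1] <- 24
  out[cosH0 >= 1] <- 0
  mid <- cosH0 > -1 & cosH0 < 1
  out[mid] <- 2 * acos(cosH0[mid]) / .DEG / 15
  out
}

#' Invert day length to latitude
#'
#' Solves for the latitude at which a day of the given length (above
#' `sun_elev`) occurs on `date`. Near the equinoxes day length is ~12 h at
#' every latitude and the inversion is degenerate; `NA` is returned when
#' no root exists.
#'
#' @param len_hours observed day length in hours.
#' @param date `Date` vector.
#' @param sun_elev reference sun elevation (degrees).
#' @return Latitude in degrees, or `NA` when the inversion has no root.
#' @export
latitude_from_daylength <- function(len_hours, date, sun_elev = -4.5) {
  date <- as.Date(date)
  n <- max(length(len_hours), length(date))
  len_hours <- rep_len(len_hours, n)
  date <- rep_len(date, n)
  dec <- .noon_dec_eot(date)$dec * .DEG
  H0 <- len_hours * 15 / 2 * .DEG
  se <- sin(sun_elev * .DEG)
  A <- sin(dec)
  B <- cos(dec) * cos(H0)
  R <- sqrt(A^2 + B^2)
  out <- rep(NA_real_, n)
  ok <- R > 0 & abs(se / R) <= 1
  if (any(ok)) {
    gam <- atan2(B[ok], A[ok])
    s <- asin(se / R[ok])
    cand1 <- (s - gam) / .DEG
    cand2 <- (pi - s - gam) / .DEG
    cand2 <- ifelse(cand2 > 180, cand2 - 360, cand2)
    # pick the admissible root that reproduces the observed day length
    pick <- function(c1, c2, d, L) {
      cands <- c(c1, c2)
      cands <- cands[abs(cands) <= 90]
      if (!length(cands)) return(NA_real_)
      err <- abs(day_length(rep(d, length(cands)), cands, sun_elev) - L)
      cands[which.min(err)]
    }
    out[ok] <- mapply(pick, cand1, cand2, as.character(date[ok]), len_hours[ok])
  }
  out
}

#' Sunrise and sunset times
#'
#' Threshold crossing times of the sun at `sun_elev`, by solar-noon
#' geometry with one refinement pass. Vectorised; polar day/night yield
#' `NA` rise/set.
#'
#' @inheritParams day_length
#' @param lon longitude in degrees (west negative).
#' @param sun_elev reference elevation in degrees or `"horizon"`.
#' @return `data.frame` with columns `date`, `sunrise`, `sunset`
#'   (`POSIXct` UTC) and `day_length` (hours).
#' @export
twilight_times <- function(date, lon, lat, sun_elev = -4.5) {
  if (identical(sun_elev, "horizon")) sun_elev <- -0.833
  date <- as.Date(date)
  n <- max(length(date), length(lon), length(lat))
  date <- rep_len(date, n); lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  day0 <- as.POSIXct(paste(as.character(date), "00:00:00"), tz = "UTC")

  halfarc <- function(t_ref) {
    s <- .sun_coords(t_ref)
    cosH0 <- (sin(sun_elev * .DEG) - sin(lat * .DEG) * sin(s$dec * .DEG)) /
      (cos(lat * .DEG) * cos(s$dec * .DEG))
    list(H0 = ifelse(abs(cosH0) <= 1, acos(pmin(1, pmax(-1, cosH0))) / .DEG, NA_real_),
         eot = s$eqtime_min, polar_day = cosH0 < -1, polar_night = cosH0 > 1)
  }

  h <- halfarc(day0 + 12 * 3600)
  noon_h <- 12 - lon / 15 - h$eot / 60
  rise_h <- noon_h - h$H0 / 15
  set_h <- noon_h + h$H0 / 15
  # refine with declination/EoT at first-pass event times
  for (k in 1:2) {
    hr <- halfarc(day0 + ifelse(is.na(rise_h), 6, rise_h) * 3600)
    hs <- halfarc(day0 + ifelse(is.na(set_h), 18, set_h) * 3600)
    noon_r <- 12 - lon / 15 - hr$eot / 60
    noon_s <- 12 - lon / 15 - hs$eot / 60
    rise_h <- noon_r - hr$H0 / 15
    set_h <- noon_s + hs$H0 / 15
  }
  sunrise <- day0 + rise_h * 3600
  sunset <- day0 + set_h * 3600
  data.frame(date = date, sunrise = sunrise, sunset = sunset,
             day_length = as.numeric(difftime(sunset, sunrise, units = "hours")))
}

#' Local solar midnight
#'
#' The UTC instant of the local solar midnight following local noon of
#' `date` at longitude `lon` (i.e. the middle of the night that starts on
#' `date`).
#'
#' @param date `Date` vector.
#' @param lon longitude in degrees (west negative).
#' @return `POSIXct` UTC.
#' @export
local_solar_midnight <- function(date, lon) {
  date <- as.Date(date)
  day0 <- as.POSIXct(paste(as.character(date), "00:00:00"), tz = "UTC")
  eot <- .sun_coords(day0 + 12 * 3600)$eqtime_min
  day0 + (24 - lon / 15 - eot / 60) * 3600
}

# ---- Moon -------------------------------------------------------------

# Truncated ELP-style series for the moon's geocentric ecliptic
# coordinates and distance.
.moon_coords <- function(time) {
  T <- .jcent(time)
  Lp <- .wrap360(218.3164477 + 481267.88123421 * T - 0.0015786 * T^2)
  D <- (297.8501921 + 445267.1114034 * T - 0.0018819 * T^2) * .DEG
  M <- (357.5291092 + 35999.0502909 * T - 0.0001536 * T^2) * .DEG
  Mp <- (134.9633964 + 477198.8675055 * T + 0.0087414 * T^2) * .DEG
  F <- (93.2720950 + 483202.0175233 * T - 0.0036539 * T^2) * .DEG

  sl <- 6.288774 * sin(Mp) + 1.274027 * sin(2 * D - Mp) + 0.658314 * sin(2 * D) +
    0.213618 * sin(2 * Mp) - 0.185116 * sin(M) - 0.114332 * sin(2 * F) +
    0.058793 * sin(2 * D - 2 * Mp) + 0.057066 * sin(2 * D - M - Mp) +
    0.053322 * sin(2 * D + Mp) + 0.045758 * sin(2 * D - M) -
    0.040923 * sin(M - Mp) - 0.034720 * sin(D) - 0.030383 * sin(M + Mp) +
    0.015327 * sin(2 * D - 2 * F) - 0.012528 * sin(Mp + 2 * F) +
    0.010980 * sin(Mp - 2 * F) + 0.010675 * sin(4 * D - Mp) +
    0.010034 * sin(3 * Mp) + 0.008548 * sin(4 * D - 2 * Mp) -
    0.007888 * sin(2 * D + M - Mp) - 0.006766 * sin(2 * D + M) -
    0.005163 * sin(D - Mp)
  sb <- 5.128122 * sin(F) + 0.280602 * sin(Mp + F) + 0.277693 * sin(Mp - F) +
    0.173237 * sin(2 * D - F) + 0.055413 * sin(2 * D - Mp + F) +
    0.046271 * sin(2 * D - Mp - F) + 0.032573 * sin(2 * D + F) +
    0.017198 * sin(2 * Mp + F) + 0.009266 * sin(2 * D + Mp - F) +
    0.008822 * sin(2 * Mp - F) + 0.008216 * sin(2 * D - M - F) +
    0.004324 * sin(2 * D - 2 * Mp - F)
  dist <- 385000.56 - 20905.355 * cos(Mp) - 3699.111 * cos(2 * D - Mp) -
    2955.968 * cos(2 * D) - 569.925 * cos(2 * Mp) + 48.888 * cos(M) -
    3.149 * cos(2 * F) + 246.158 * cos(2 * D - 2 * Mp) -
    152.138 * cos(2 * D - M - Mp) - 170.733 * cos(2 * D + Mp) -
    204.586 * cos(2 * D - M) - 129.620 * cos(M - Mp) + 108.743 * cos(D) +
    104.755 * cos(M + Mp) + 10.321 * cos(2 * D - 2 * F)

  lam <- .wrap360(Lp + sl)
  beta <- sb
  eps <- (23.4392911 - 0.0130042 * T) * .DEG
  lr <- lam * .DEG; br <- beta * .DEG
  ra <- atan2(sin(lr) * cos(eps) - tan(br) * sin(eps), cos(lr)) / .DEG
  dec <- asin(sin(br) * cos(eps) + cos(br) * sin(eps) * sin(lr)) / .DEG
  list(lon_ecl = lam, lat_ecl = beta, ra = .wrap360(ra), dec = dec,
       dist_km = dist)
}

#' Geocentric moon altitude
#'
#' @inheritParams sun_altitude
#' @return Altitude in degrees.
#' @export
moon_altitude <- function(time, lon, lat) {
  m <- .moon_coords(time)
  .altitude(m$ra, m$dec, time, lon, lat)
}

#' Illuminated fraction of the moon's disc
#'
#' 0 at new moon, 1 at full moon; position-independent (geocentric).
#' Supported epoch 1990--2050 (the truncated series is tuned for the
#' decades around J2000).
#'
#' @param time `POSIXct` instant(s), UTC.
#' @return Fraction in `[0, 1]`.
#' @export
moon_illumination <- function(time) {
  yr <- as.integer(format(time, "%Y"))
  if (any(yr < 1990 | yr > 2050))
    stop("moon_illumination: time outside supported epoch 1990-2050")
  s <- .sun_coords(time)
  m <- .moon_coords(time)
  psi <- acos(pmin(1, pmax(-1,
    cos(m$lat_ecl * .DEG) * cos((m$lon_ecl - s$app_lon) * .DEG))))
  i <- atan2(s$dist_km * sin(psi), m$dist_km - s$dist_km * cos(psi))
  (1 + cos(i)) / 2
}

# Standard rise/set altitude for the moon's centre: mean parallax
# (+0.95 * 0.7275 deg) minus refraction+semidiameter (0.566 deg).
.MOON_H0 <- 0.125

#' Moon state through one night
#'
#' Discretises the night that starts at sunset of `date` (dark period at
#' the geolocation sun elevation) into bins, flags whether the moon is
#' risen in each, and reports rise/set crossings (bisection-refined) plus
#' the illuminated fraction at the middle of the night.
#'
#' @param date `Date`: the night is `sunset(date)` to `sunrise(date + 1)`.
#' @param lon,lat position in degrees.
#' @param sun_elev sun elevation defining darkness (degrees).
#' @param step_min bin width in minutes.
#' @return A list with `bins` (`data.frame`: `start`, `risen`),
#'   `night_start`, `night_end`, `rise`, `set` (`POSIXct` or `NA`),
#'   `illumination`, and `up_fraction` (fraction of night bins risen).
#' @export
moon_windows <- function(date, lon, lat, sun_elev = -4.5, step_min = 10) {
  date <- as.Date(date)
  tw0 <- twilight_times(date, lon, lat, sun_elev)
  tw1 <- twilight_times(date + 1, lon, lat, sun_elev)
  n0 <- tw0$sunset
  n1 <- tw1$sunrise
  if (is.na(n0) || is.na(n1) || n1 <= n0)
    stop("moon_windows: no dark period on this date at this latitude")
  starts <- seq(n0, n1, by = step_min * 60)
  if (tail(starts, 1) >= n1) starts <- starts[starts < n1]
  mids <- starts + pmin(step_min * 60, as.numeric(n1) - as.numeric(starts)) / 2
  alt <- moon_altitude(mids, lon, lat)
  risen <- alt > .MOON_H0

  refine <- function(t0, t1) {
    for (k in 1:25) {
      tm <- t0 + as.numeric(t1 - t0, units = "secs") / 2
      if ((moon_altitude(tm, lon, lat) > .MOON_H0) ==
          (moon_altitude(t0, lon, lat) > .MOON_H0)) t0 <- tm else t1 <- tm
    }
    t0 + as.numeric(t1 - t0, units = "secs") / 2
  }
  rise <- set <- as.POSIXct(NA, tz = "UTC")
  if (length(mids) > 1) {
    flips <- which(diff(risen) != 0)
    for (f in flips) {
      tc <- refine(mids[f], mids[f + 1])
      if (risen[f + 1]) rise <- tc else set <- tc
    }
  }
  list(bins = data.frame(start = starts, risen = risen),
       night_start = n0, night_end = n1, rise = rise, set = set,
       illumination = moon_illumination(n0 + as.numeric(n1 - n0, units = "secs") / 2),
       up_fraction = mean(risen))
}

#' Fraction of a night interval with the moon risen
#'
#' Vectorised helper for covariate construction: evaluates the moon on a
#' regular sub-grid of each `[start, end]` interval.
#'
#' @param start,end `POSIXct` night interval bounds (UTC).
#' @param lon,lat position in degrees (vectorised with the intervals).
#' @param n_sub number of evaluation points per interval.
#' @return Fraction in `[0, 1]` per interval.
#' @export
moon_up_fraction <- function(start, end, lon, lat, n_sub = 36) {
  n <- length(start)
  stopifnot(length(end) == n)
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  frac <- (seq_len(n_sub) - 0.5) / n_sub
  tt <- rep(as.numeric(start), each = n_sub) +
    rep(frac, times = n) * rep(as.numeric(end) - as.numeric(start), each = n_sub)
  alt <- moon_altitude(as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
                       rep(lon, each = n_sub), rep(lat, each = n_sub))
  colMeans(matrix(alt > .MOON_H0, nrow = n_sub))
}
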