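# Synthetic population generator: known-truth itineraries, behavioural
# states and covariates for pipeline validation.

.largest_remainder <- function(weights, total, mins) {
  # integer allocation of `total` over length(weights) cells with floors
  extra <- total - sum(mins)
  if (extra < 0) stop("allocation infeasible")
  w <- weights / sum(weights)
  raw <- w * extra
  base <- floor(raw)
  rem <- extra - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  mins + base
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a population of migrating birds with known ground truth
#'
#' Draws lay dates, departure dates, stopover schedules, great-circle
#' trajectories and per-10-minute behavioural states (flight / forage /
#' rest) for every bird-year, following the generating equations held in
#' `params`. The output is the ground truth that [render_light()] and
#' [render_immersion()] turn into raw sensor streams.
#'
#' @param params a [population_params()] object.
#' @param seed integer seed; identical seed and params give identical
#'   output.
#' @return An object of class `itinerary_set`: a list with `params`,
#'   `birds` (one summary row per bird-year) and `itineraries` (a list of
#'   `true_itinerary` objects).
#' @export
simulate_population <- function(params, seed = 1) {
  validate_population_params(params)
  set.seed(as.integer(seed))
  p <- params
  ncol_ <- nrow(p$colonies)
  colony_of <- p$colonies$name[((seq_len(p$n_birds) - 1) %% ncol_) + 1]

  # random intercepts shared across a bird's years / a year's birds
  bird_fx <- stats::rnorm(p$n_birds, 0, p$bird_random_sd)
  bird_dep_fx <- stats::rnorm(p$n_birds, 0, p$departure_bird_sd)
  year_fx <- stats::rnorm(p$n_years, 0, p$year_random_sd)
  year_dep_fx <- stats::rnorm(p$n_years, 0, p$departure_year_sd)

  itineraries <- vector("list", p$n_birds * p$n_years)
  idx <- 0
  for (b in seq_len(p$n_birds)) {
    for (yi in seq_len(p$n_years)) {
      idx <- idx + 1
      itineraries[[idx]] <- .simulate_bird_year(
        p, bird_id = sprintf("b%03d", b), year = p$years[yi],
        colony = p$colonies[p$colonies$name == colony_of[b], ],
        b_flight = bird_fx[b], b_dep = bird_dep_fx[b],
        y_flight = year_fx[yi], y_dep = year_dep_fx[yi])
    }
  }
  birds <- do.call(rbind, lapply(itineraries, function(it)
    data.frame(bird_id = it$bird_id, year = it$year, colony = it$colony$name,
               lay_date = it$lay_date, departure_date = it$departure_date,
               arrival_date = it$arrival_date, duration = it$duration,
               stopover_days = it$stopover_days, n_stopovers = it$n_stopovers,
               mean_moon = it$mean_moon, stringsAsFactors = FALSE)))
  out <- list(params = p, birds = birds, itineraries = itineraries)
  class(out) <- "itinerary_set"
  out
}

.simulate_bird_year <- function(p, bird_id, year, colony,
                                b_flight, b_dep, y_flight, y_dep) {
  aug1 <- as.Date(paste0(year, "-08-01"))
  ld <- .monthday_to_date(p$lay_date_range, year)
  lay <- ld[1] + sample.int(as.numeric(ld[2] - ld[1]) + 1, 1) - 1
  mean_dep <- .monthday_to_date(p$mean_departure, year)
  dep_off <- p$slope_departure_on_lay * as.numeric(lay - mean(ld)) +
    b_dep + y_dep + stats::rnorm(1, 0, p$departure_resid_sd)
  departure <- mean_dep + round(dep_off)
  D <- as.numeric(departure - aug1)

  cf <- function(which) unname(p$colony_effects[[which]][colony$name])
  S <- max(1L, as.integer(round(
    p$stopover_days_intercept + p$slope_stopover_days_on_departure * D +
      cf("stopover_days") + stats::rnorm(1, 0, p$stopover_days_resid_sd))))
  k <- max(1L, min(S, as.integer(round(S / p$stopover_mean_block_length))))
  block_len <- if (k == 1) S else {
    cuts <- sort(sample.int(S - 1, k - 1))
    diff(c(0L, cuts, S))
  }
  gap_w <- stats::rexp(k + 1)
  eps_dur <- stats::rnorm(1, 0, p$duration_resid_sd)
  # duration covariate: mean nightly illumination over a fixed window of
  # nights from departure -- exogenous given the departure date (the
  # realised migration window would make the covariate depend on the
  # response). Illumination is geocentric; the colony meridian only sets
  # the midnight instant.
  mM <- mean(moon_illumination(local_solar_midnight(
    departure + seq_len(p$moon_window_nights) - 1, colony$lon)))
  min_T <- S + p$min_travel_lead + p$min_travel_trail + (k - 1L)
  Tdur <- max(min_T, as.integer(round(
    p$duration_intercept + p$duration_moon_effect * mM +
      p$slope_duration_on_departure * D +
      p$duration_moon_dep_interaction * mM * D + cf("duration") + eps_dur)))
  Ttr <- Tdur - S
  mins <- c(p$min_travel_lead, rep(1L, k - 1), p$min_travel_trail)
  gaps <- .largest_remainder(gap_w, Ttr, mins)
  states_mig <- character(0)
  for (i in seq_len(k)) {
    states_mig <- c(states_mig, rep("migrating", gaps[i]),
                    rep("stopover", block_len[i]))
  }
  states_mig <- c(states_mig, rep("migrating", gaps[k + 1]))
  arrival <- departure + Tdur

  start_date <- aug1 - p$start_buffer_days
  end_date <- arrival + p$end_buffer_days
  dates <- seq(start_date, end_date, by = "day")
  nd <- length(dates)
  state <- rep("wintering", nd)
  state[dates < departure] <- "breeding"
  mig_idx <- match(seq(departure, arrival - 1, by = "day"), dates)
  state[mig_idx] <- states_mig

  # great-circle route traversed at constant displacement on travel days
  wb <- p$wintering_box
  dest <- c(mean(wb[1:2]), mean(wb[3:4]))
  travel_cum <- cumsum(state == "migrating" & dates >= departure)
  frac <- .clamp(travel_cum / max(travel_cum[dates == arrival - 1], 1), 0, 1)
  frac[dates >= arrival] <- 1
  frac[dates < departure] <- 0
  path <- geosphere::gcIntermediate(c(colony$lon, colony$lat), dest,
                                    n = 199, addStartEnd = TRUE)
  pidx <- pmin(nrow(path), 1 + round(frac * (nrow(path) - 1)))
  lon <- path[pidx, 1]
  lat <- path[pidx, 2]

  tw <- twilight_times(c(dates, end_date + 1), c(lon, lon[nd]), c(lat, lat[nd]),
                       p$sun_elev_threshold)
  sunrise <- tw$sunrise[seq_len(nd)]
  sunset <- tw$sunset[seq_len(nd)]
  night_end <- tw$sunrise[seq_len(nd) + 1]
  day_len <- as.numeric(difftime(sunset, sunrise, units = "hours"))
  night_len <- as.numeric(difftime(night_end, sunset, units = "hours"))
  midn <- sunset + as.numeric(difftime(night_end, sunset, units = "secs")) / 2
  moon <- moon_illumination(midn)

  # per-day behavioural targets (hours)
  eps <- matrix(stats::rnorm(4 * nd, 0, p$residual_sd), nd, 4)
  Fd <- Fn <- Gd <- Gn <- numeric(nd)
  trav <- state == "migrating"
  stopv <- state == "stopover"
  base_f <- cf("flight") + b_flight + y_flight
  Fd[trav] <- p$day_flight_intercept + p$day_flight_dep_slope * D + base_f +
    eps[trav, 1]
  Fn[trav] <- p$day_flight_intercept + p$day_night_flight_offset +
    (p$day_flight_dep_slope + p$night_flight_dep_interaction) * D +
    p$night_flight_moon_effect * (moon[trav] - 0.5) +
    p$night_flight_moon_dep_interaction * (moon[trav] - 0.5) * D +
    base_f + eps[trav, 2]
  Gn[trav] <- p$forage_night_intercept +
    p$forage_night_moon_effect * moon[trav] +
    p$forage_night_dep_slope * D +
    p$forage_night_moon_dep_interaction * moon[trav] * D +
    cf("forage_night") + b_flight + y_flight + eps[trav, 3]
  Gd[trav] <- 4 + eps[trav, 4]
  if (any(stopv)) {
    ftot <- .clamp(stats::rnorm(sum(stopv), p$stopover_flighthours_mean,
                                p$stopover_flighthours_sd), 0.1, 6)
    gtot <- .clamp(p$stopover_forage_intercept +
                     p$stopover_forage_dep_slope * D + cf("forage_stopover") +
                     stats::rnorm(sum(stopv), 0, p$stopover_forage_resid_sd),
                   0, 20)
    Fd[stopv] <- 0.8 * ftot
    Fn[stopv] <- 0.2 * ftot
    Gd[stopv] <- 0.75 * gtot
    Gn[stopv] <- 0.25 * gtot
  }
  breed <- state == "breeding"
  wint <- state == "wintering"
  Fd[breed] <- 2; Gd[breed] <- 8; Fn[breed] <- 0.5; Gn[breed] <- 2
  Fd[wint] <- 1.5; Gd[wint] <- 6; Fn[wint] <- 0.5; Gn[wint] <- 3
  Fd <- .clamp(Fd, 0, day_len)
  Fn <- .clamp(Fn, 0, night_len)
  Gd <- .clamp(Gd, 0, day_len - Fd)
  Gn <- .clamp(Gn, 0, night_len - Fn)

  bins <- .allocate_bins(dates, sunrise, sunset, Fd, Fn, Gd, Gn)

  days <- data.frame(date = dates, state = state, lon = lon, lat = lat,
                     sunrise = sunrise, sunset = sunset, night_end = night_end,
                     day_length = day_len, night_length = night_len,
                     night_moon = moon,
                     flight_day_h = bins$real[, 1], flight_night_h = bins$real[, 2],
                     forage_day_h = bins$real[, 3], forage_night_h = bins$real[, 4],
                     stringsAsFactors = FALSE)

  blocks <- rle(states_mig)
  ends <- cumsum(blocks$lengths)
  sb <- which(blocks$values == "stopover")
  stopovers <- data.frame(
    start = departure + (ends[sb] - blocks$lengths[sb]),
    end = departure + ends[sb] - 1)
  stopovers$length <- as.numeric(stopovers$end - stopovers$start) + 1
  ctr <- t(vapply(seq_len(nrow(stopovers)), function(i) {
    sel <- dates >= stopovers$start[i] & dates <= stopovers$end[i]
    c(mean(lon[sel]), mean(lat[sel]))
  }, numeric(2)))
  stopovers$lon <- ctr[, 1]
  stopovers$lat <- ctr[, 2]

  out <- list(bird_id = bird_id, year = year, colony = colony,
              lay_date = lay, departure_date = departure,
              arrival_date = arrival, duration = Tdur,
              stopover_days = S, n_stopovers = k, stopovers = stopovers,
              mean_moon = mM,
              dep_days_aug1 = D, days = days, bins = bins$bins)
  class(out) <- "true_itinerary"
  out
}

# Assign each 10-min UTC-aligned bin a true behaviour so that realised
# per-phase flight/forage hours match the targets to bin resolution.
# Flight occupies one contiguous run per phase (so continuous-flight
# metrics are meaningful); forage fills the slots that follow it.
.allocate_bins <- function(dates, sunrise, sunset, Fd, Fn, Gd, Gn) {
  nd <- length(dates)
  t0 <- as.POSIXct(paste(as.character(dates[1]), "00:00:00"), tz = "UTC")
  n_bins <- nd * 144
  starts <- t0 + (seq_len(n_bins) - 1) * 600
  mids <- as.numeric(starts) + 300
  bounds <- as.numeric(rbind(as.numeric(sunrise), as.numeric(sunset)))
  phase_id <- findInterval(mids, bounds)  # odd = day i, even = night i
  behaviour <- rep(3L, n_bins)  # rest by default
  real <- matrix(0, nd, 4)

  place <- function(slots, Fh, Gh) {
    L <- length(slots)
    if (!L) return(NULL)
    nf <- min(round(Fh * 6), L)
    ng <- min(round(Gh * 6), L - nf)
    beh <- rep(3L, L)
    if (nf > 0) {
      s <- sample.int(L - nf + 1, 1) - 1
      beh[(s + 1):(s + nf)] <- 1L
      rem <- which(beh == 3L)
      rem <- rem[order((rem - (s + nf) - 1) %% L)]
    } else rem <- seq_len(L)
    if (ng > 0) beh[rem[seq_len(ng)]] <- 2L
    list(beh = beh, nf = nf, ng = ng)
  }

  for (i in seq_len(nd)) {
    dslots <- which(phase_id == 2L * i - 1L)
    nslots <- which(phase_id == 2L * i)
    pd <- place(dslots, Fd[i], Gd[i])
    if (!is.null(pd)) {
      behaviour[dslots] <- pd$beh
      real[i, c(1, 3)] <- c(pd$nf, pd$ng) / 6
    }
    pn <- place(nslots, Fn[i], Gn[i])
    if (!is.null(pn)) {
      behaviour[nslots] <- pn$beh
      real[i, c(2, 4)] <- c(pn$nf, pn$ng) / 6
    }
  }
  list(bins = data.frame(start = starts, behaviour = behaviour),
       real = real)
}

#' @export
print.itinerary_set <- function(x, ...) {
  cat("Synthetic itinerary set:", nrow(x$birds), "bird-years,",
      length(unique(x$birds$bird_id)), "birds,",
      length(unique(x$birds$colony)), "colonies\n")
  cat("Departure:", format(min(x$birds$departure_date)), "to",
      format(max(x$birds$departure_date)), "\n")
  invisible(x)
}
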