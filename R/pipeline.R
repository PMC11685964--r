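# End-to-end orchestration: synthetic population -> sensor rendering ->
# geolocation -> activity classification -> stopover detection ->
# chlorophyll ratios -> model suite.

#' Run configuration
#'
#' @param params a [population_params()].
#' @param geo a [geolocation_config()].
#' @param imm an [immersion_config()].
#' @param stop a [stopover_config()].
#' @param chl a [chl_config()].
#' @param seed global seed (drives simulation, rendering and bootstrap).
#' @param n_boot bootstrap resamples for the model suite.
#' @param lay_colonies colonies whose birds have observed lay dates
#'   (`NULL` = all birds).
#' @param with_chl compute chlorophyll ratios (renders a synthetic grid
#'   unless one is supplied to [run_all()]).
#' @param light_noise_sd,shading_prob light-rendering noise settings.
#' @param models model ids to fit.
#' @param out_dir optional output directory for tables and manifest.
#' @return Object of class `run_config`.
#' @export
run_config <- function(params = population_params(),
                       geo = geolocation_config(),
                       imm = immersion_config(),
                       stop = stopover_config(),
                       chl = chl_config(),
                       seed = 1, n_boot = 1000,
                       lay_colonies = "Skomer",
                       with_chl = TRUE,
                       light_noise_sd = 0, shading_prob = 0,
                       models = 1:10, out_dir = NULL) {
  out <- as.list(environment())
  class(out) <- "run_config"
  out
}

#' Process one bird-year's sensor streams
#'
#' Twilights, position track, migration window, activity metrics and the
#' bird-day/night table for one bird.
#'
#' @param light a `light_series`.
#' @param scores binned immersion scores ([bin_scores()] output or
#'   equivalent with `bin_start`, `score`, `missing`).
#' @param geo,imm module configurations.
#' @param bird_id,year identifiers.
#' @return List with `track`, `birdday`, `twilights`,
#'   `max_continuous_flight_h`.
#' @export
process_bird <- function(light, scores, geo = geolocation_config(),
                         imm = immersion_config(),
                         bird_id = light$bird_id, year = light$year) {
  tw <- detect_twilights(light, geo)
  track <- build_track(tw, geo, bird_id, year)
  track <- detect_migration_window(track, geo)
  if (is.null(attr(scores, "bin_seconds")))
    attr(scores, "bin_seconds") <- imm$bin_minutes * 60
  sp <- split_day_night(scores, tw)
  met <- daily_metrics(sp, imm)
  bd <- birdday_table(met, tw, track, bird_id, year)
  list(track = track, birdday = bd, twilights = tw,
       max_continuous_flight_h = attr(met, "max_continuous_flight_h"))
}

#' Filter incomplete migrations
#'
#' Removes bird-years whose track lacks a detected migration start or
#' end, with a machine-readable exclusion log.
#'
#' @param birds list of per-bird results (each with a `track`).
#' @return List with `keep` (the retained list) and `excluded`
#'   (`data.frame`: `bird_id`, `year`, `reason`).
#' @export
qc_filter <- function(birds) {
  if (!length(birds))
    return(list(keep = list(),
                excluded = data.frame(bird_id = character(0),
                                      year = integer(0),
                                      reason = character(0))))
  ok <- vapply(birds, function(b) isTRUE(b$track$complete), logical(1))
  excluded <- do.call(rbind, lapply(birds[!ok], function(b) data.frame(
    bird_id = b$track$bird_id, year = b$track$year,
    reason = if (is.na(b$track$migration_start)) "no migration start detected"
             else "no migration end detected")))
  if (is.null(excluded))
    excluded <- data.frame(bird_id = character(0), year = integer(0),
                           reason = character(0))
  list(keep = birds[ok], excluded = excluded)
}

#' Default synthetic chlorophyll grid for a pipeline run
#'
#' A 0.5-degree daily field covering the migration corridor, richer at
#' the wintering latitudes and declining slowly through the season.
#'
#' @param dates grid days.
#' @param seed integer seed.
#' @return A `chl_grid`.
#' @export
default_chl_grid <- function(dates, seed = 1) {
  render_chl_grid(
    extent = list(lon = c(-75, 5), lat = c(-50, 58), res = 0.5),
    dates = dates,
    gradient_params = list(base = 1.0, lat_slope = -0.012, ref_lat = -41,
                           seasonal_slope = -0.002, ref_date = dates[1],
                           noise_sd = 0.05, missing_frac = 0.1),
    seed = seed)
}

#' Run the full pipeline on a synthetic population
#'
#' Simulates the population, renders light and immersion, geolocates,
#' classifies activity, detects stopovers (pooled EM mixture over whole-
#' day flight hours within the migration windows), extracts chlorophyll
#' ratios and fits the model suite. Deterministic given the config seed.
#'
#' @param config a [run_config()].
#' @param pop optionally a pre-simulated `itinerary_set` (must match
#'   `config$params`).
#' @param grid optionally a pre-rendered `chl_grid`.
#' @return Object of class `pipeline_result`: `birds` (per-bird results),
#'   `exclusions`, `mixture`, `stopovers` (per bird-year), `birdday`
#'   (stacked table), `tracks` (per-track modelling table), `suite`,
#'   `table1`, `manifest`.
#' @export
run_all <- function(config = run_config(), pop = NULL, grid = NULL) {
  seed <- as.integer(config$seed)
  if (is.null(pop)) pop <- simulate_population(config$params, seed = seed)

  birds <- vector("list", length(pop$itineraries))
  for (i in seq_along(pop$itineraries)) {
    it <- pop$itineraries[[i]]
    light <- render_light(it, sun_elev = config$geo$sun_elev,
                          max_light = config$geo$light_threshold * 2,
                          noise_sd = config$light_noise_sd,
                          shading_prob = config$shading_prob,
                          seed = seed + 7919 + i)
    scores <- .render_immersion_scores(it, max_score = config$imm$max_score,
                                       seed = seed + 104729 + i)
    names(scores)[1] <- "bin_start"
    scores$missing <- FALSE
    b <- process_bird(light, scores, config$geo, config$imm,
                      it$bird_id, it$year)
    b$itinerary_index <- i
    birds[[i]] <- b
  }
  qc <- qc_filter(birds)
  birds <- qc$keep

  # pooled mixture over whole-day flight hours within migration windows
  dayflight <- do.call(rbind, lapply(birds, function(b) {
    bd <- b$birdday[b$birdday$in_migration, ]
    if (!nrow(bd)) return(NULL)
    agg <- stats::aggregate(flight_hours ~ date, data = bd, FUN = sum)
    data.frame(bird_id = b$track$bird_id, year = b$track$year,
               date = agg$date, flight = agg$flight_hours)
  }))
  cfg_stop <- config$stop
  cfg_stop$seed <- seed + 13
  mixture <- fit_mixture_em(dayflight$flight, cfg_stop)
  dayflight$stopover <- assign_stopover_days(mixture, dayflight$flight,
                                             cfg_stop)

  grid_days <- NULL
  if (config$with_chl && is.null(grid)) {
    rng <- range(dayflight$date)
    grid <- default_chl_grid(seq(rng[1], rng[2], by = "day"),
                             seed = seed + 29)
  }

  lay_lookup <- pop$birds
  tracks <- list()
  stopsets <- list()
  for (j in seq_along(birds)) {
    b <- birds[[j]]
    key <- dayflight$bird_id == b$track$bird_id & dayflight$year == b$track$year
    df <- dayflight[key, ]
    sset <- segment_stopovers(df$date, df$stopover, b$track)
    stopsets[[j]] <- sset
    # push stopover flags back into the bird-day table
    b$birdday$is_stopover_day <- b$birdday$date %in% df$date[df$stopover]
    b$birdday$is_stopover_day[!b$birdday$in_migration] <- NA
    birds[[j]] <- b

    bd <- b$birdday
    mign <- bd[bd$in_migration & bd$phase == "night" &
                 !is.na(bd$is_stopover_day) & !bd$is_stopover_day, ]
    so_days <- bd[bd$in_migration & !is.na(bd$is_stopover_day) &
                    bd$is_stopover_day, ]
    so_forage <- if (nrow(so_days)) {
      per_day <- stats::aggregate(forage_hours ~ date, data = so_days,
                                  FUN = sum)
      mean(per_day$forage_hours)
    } else NA_real_
    meta <- lay_lookup[lay_lookup$bird_id == b$track$bird_id &
                         lay_lookup$year == b$track$year, ]
    lay_known <- is.null(config$lay_colonies) ||
      meta$colony %in% config$lay_colonies
    aug1 <- as.Date(paste0(b$track$year, "-08-01"))
    apr26 <- as.Date(paste0(b$track$year, "-04-26"))
    ratio <- NA_real_
    if (config$with_chl && sset$n_stopovers > 0)
      ratio <- stopover_chl_ratio(sset$stopovers, grid, config$chl)$mean_ratio
    tracks[[j]] <- data.frame(
      bird_id = b$track$bird_id, year = b$track$year, colony = meta$colony,
      migration_start = b$track$migration_start,
      migration_end = b$track$migration_end,
      dep_days_aug1 = as.numeric(b$track$migration_start - aug1),
      duration = as.numeric(b$track$migration_end - b$track$migration_start),
      total_stopover_days = sset$total_stopover_days,
      n_stopovers = sset$n_stopovers,
      mean_stopover_length = if (sset$n_stopovers)
        mean(sset$stopovers$length) else NA_real_,
      mean_gap = if (length(sset$gaps)) mean(sset$gaps) else NA_real_,
      mean_moon = {
        # fixed-window covariate, mirroring the duration model: mean
        # nightly illumination over the first nights of the migration
        wd <- b$track$migration_start +
          seq_len(config$params$moon_window_nights) - 1
        lon0 <- b$track$daily$lon_smooth[match(b$track$migration_start,
                                               b$track$daily$date)]
        if (is.na(lon0)) lon0 <- 0
        mean(moon_illumination(local_solar_midnight(wd, lon0)))
      },
      stopover_forage_hours = so_forage,
      mean_chl_ratio = ratio,
      max_continuous_flight_h = b$max_continuous_flight_h,
      lay_days = if (lay_known)
        as.numeric(meta$lay_date - apr26) else NA_real_,
      breeding_period = if (lay_known)
        as.numeric(b$track$migration_start - meta$lay_date) else NA_real_,
      stringsAsFactors = FALSE)
  }
  tracks <- do.call(rbind, tracks)
  birdday <- do.call(rbind, lapply(birds, function(b) {
    bd <- b$birdday
    meta <- lay_lookup[lay_lookup$bird_id == b$track$bird_id &
                         lay_lookup$year == b$track$year, ]
    bd$colony <- meta$colony
    bd
  }))

  suite <- run_model_suite(birdday, tracks, n_boot = config$n_boot,
                           seed = seed + 101, models = config$models)
  table1 <- .phenology_summary(tracks)
  manifest <- list(seed = seed,
                   n_birds = config$params$n_birds,
                   n_years = config$params$n_years,
                   n_tracks_complete = nrow(tracks),
                   n_excluded = nrow(qc$excluded),
                   config_hash = .config_hash(config))
  out <- list(birds = birds, exclusions = qc$excluded, mixture = mixture,
              stopovers = stopsets, birdday = birdday, tracks = tracks,
              suite = suite, table1 = table1, manifest = manifest)
  class(out) <- "pipeline_result"
  if (!is.null(config$out_dir)) .write_bundle(out, config$out_dir)
  out
}

.phenology_summary <- function(tracks) {
  met <- function(x, fmt = identity) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(mean = NA, min = NA, max = NA))
    c(mean = mean(x), min = min(x), max = max(x))
  }
  num <- rbind(
    migration_start = met(as.numeric(tracks$migration_start -
                                       as.Date(paste0(tracks$year, "-01-01")))),
    migration_end = met(as.numeric(tracks$migration_end -
                                     as.Date(paste0(tracks$year, "-01-01")))),
    duration_days = met(tracks$duration),
    stopover_number = met(tracks$n_stopovers),
    total_stopover_days = met(tracks$total_stopover_days),
    stopover_length_days = met(tracks$mean_stopover_length),
    days_between_stopovers = met(tracks$mean_gap),
    max_continuous_flight_h = met(tracks$max_continuous_flight_h),
    lay_days_apr26 = met(tracks$lay_days))
  as.data.frame(num)
}

.config_hash <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL
  txt <- paste(utils::capture.output(utils::str(cfg, digits.d = 12)),
               collapse = "\n")
  f <- tempfile()
  writeLines(txt, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

.write_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(
    wt(result$tracks, "tracks.tsv"),
    wt(result$birdday, "birdday.tsv"),
    wt(result$suite$report, "model_report.tsv"),
    wt(cbind(metric = rownames(result$table1), result$table1),
       "phenology_summary.tsv"),
    wt(result$exclusions, "exclusions.tsv"))
  mix <- result$mixture
  writeLines(c(sprintf("mean_low\t%.6f", mix$means[1]),
               sprintf("mean_high\t%.6f", mix$means[2]),
               sprintf("sd_low\t%.6f", mix$sds[1]),
               sprintf("sd_high\t%.6f", mix$sds[2]),
               sprintf("weight_low\t%.6f", mix$weight_low),
               sprintf("loglik\t%.6f", mix$loglik),
               sprintf("iterations\t%d", mix$iterations),
               sprintf("converged\t%s", mix$converged)),
             file.path(out_dir, "mixture_fit.tsv"))
  paths <- c(paths, file.path(out_dir, "mixture_fit.tsv"))
  manifest <- result$manifest
  manifest$files <- lapply(stats::setNames(as.list(paths), basename(paths)),
                           function(p) unname(tools::md5sum(p)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", nrow(x$tracks), "complete tracks (",
      nrow(x$exclusions), "excluded )\n")
  cat("Mixture components (whole-day flight hours): low",
      round(x$mixture$means[1], 2), "/ high", round(x$mixture$means[2], 2),
      "\n")
  cat("Phenology summary:\n")
  print(round(x$table1, 2))
  invisible(x)
}
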