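# Stopover-site chlorophyll extraction: box means over a gridded daily
# field and the stopover / over-wintering ratio.

#' Chlorophyll extraction configuration
#'
#' @param stopover_box_halfwidth half-width (degrees) of the square box
#'   around each stopover centroid.
#' @param wintering_box `c(lon_min, lon_max, lat_min, lat_max)` of the
#'   over-wintering reference region.
#' @param weight_wintering cosine-latitude weight the wintering-box mean
#'   (the box spans 10 degrees of latitude; the small stopover boxes are
#'   never weighted).
#' @return Object of class `chl_config`.
#' @export
chl_config <- function(stopover_box_halfwidth = 0.08,
                       wintering_box = c(lon_min = -66, lon_max = -54,
                                         lat_min = -46, lat_max = -36),
                       weight_wintering = TRUE) {
  stopifnot(stopover_box_halfwidth > 0,
            wintering_box[1] < wintering_box[2],
            wintering_box[3] < wintering_box[4])
  out <- as.list(environment())
  class(out) <- "chl_config"
  out
}

#' Mean chlorophyll over a box and date range
#'
#' Unweighted (optionally cosine-latitude weighted) mean over all
#' available (non-missing) cells intersecting the box, across the given
#' dates. Cells count as inside when their area overlaps the box, so a
#' box smaller than one cell still uses the cell containing it.
#'
#' @param grid a `chl_grid`.
#' @param box `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param dates `Date` vector (must intersect the grid's days).
#' @param cos_lat_weight weight cells by the cosine of their latitude.
#' @return Mean in mg m^-3, or `NA` if every cell is missing.
#' @export
box_mean <- function(grid, box, dates, cos_lat_weight = FALSE) {
  res_lon <- if (length(grid$lon) > 1) diff(grid$lon[1:2]) else
    2 * (box[2] - box[1])
  res_lat <- if (length(grid$lat) > 1) diff(grid$lat[1:2]) else
    2 * (box[4] - box[3])
  li <- which(grid$lon + res_lon / 2 > box[1] & grid$lon - res_lon / 2 < box[2])
  la <- which(grid$lat + res_lat / 2 > box[3] & grid$lat - res_lat / 2 < box[4])
  di <- which(grid$date %in% as.Date(dates))
  if (!length(li) || !length(la)) stop("box_mean: box does not intersect grid")
  if (!length(di)) stop("box_mean: no grid days in the requested dates")
  v <- grid$values[li, la, di, drop = FALSE]
  if (all(is.na(v))) return(NA_real_)
  if (!cos_lat_weight) return(mean(v, na.rm = TRUE))
  w <- array(rep(rep(cos(grid$lat[la] * pi / 180), each = length(li)),
                 times = length(di)), dim = dim(v))
  sum(w * v, na.rm = TRUE) / sum(w[!is.na(v)])
}

#' Stopover / over-wintering chlorophyll ratios
#'
#' For each stopover: the mean chlorophyll in a small box around its
#' centroid over its days, divided by the wintering-box mean over the
#' same days. The per-bird value is the mean ratio over its stopovers.
#' Stopovers whose centroid latitude is unavailable (all days
#' equinox-masked) get a missing ratio rather than a guessed one.
#'
#' @param stopovers `data.frame` with `start`, `end`, `lon`, `lat` (a
#'   `stopover_set$stopovers`).
#' @param grid a `chl_grid`.
#' @param cfg a [chl_config()].
#' @return List with `per_stopover` (the input plus `ratio`) and
#'   `mean_ratio`.
#' @export
stopover_chl_ratio <- function(stopovers, grid, cfg = chl_config()) {
  so <- stopovers
  so$ratio <- NA_real_
  hw <- cfg$stopover_box_halfwidth
  for (i in seq_len(nrow(so))) {
    if (is.na(so$lon[i]) || is.na(so$lat[i])) next
    dates <- seq(so$start[i], so$end[i], by = "day")
    wmean <- box_mean(grid, cfg$wintering_box, dates,
                      cos_lat_weight = cfg$weight_wintering)
    if (is.na(wmean) || wmean == 0)
      stop("stopover_chl_ratio: wintering mean missing or zero")
    smean <- box_mean(grid, c(so$lon[i] - hw, so$lon[i] + hw,
                              so$lat[i] - hw, so$lat[i] + hw), dates)
    so$ratio[i] <- smean / wmean
  }
  list(per_stopover = so,
       mean_ratio = if (all(is.na(so$ratio))) NA_real_ else
         mean(so$ratio, na.rm = TRUE))
}
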