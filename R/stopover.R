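# Stopover detection: a two-component normal mixture over daily flight
# hours (pooled across all bird-days) fitted by EM, posterior-probability
# assignment of low-flight days, and run-length segmentation into
# stopovers.

#' Stopover detection configuration
#'
#' @param posterior_threshold posterior probability of the low-flight
#'   component above which (strictly) a day is called a stopover.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param n_random_starts number of EM starts (first deterministic, rest
#'   jittered).
#' @param seed seed for the jittered restarts.
#' @return Object of class `stopover_config`.
#' @export
stopover_config <- function(posterior_threshold = 0.66, max_iter = 500,
                            tol = 1e-8, n_random_starts = 5, seed = 1) {
  stopifnot(posterior_threshold > 0.5, posterior_threshold < 1, tol > 0)
  out <- as.list(environment())
  class(out) <- "stopover_config"
  out
}

.mix_loglik <- function(x, m, s, w) {
  sum(log(w * stats::dnorm(x, m[1], s[1]) +
            (1 - w) * stats::dnorm(x, m[2], s[2])))
}

#' Fit a two-component normal mixture by EM
#'
#' Expectation-maximisation for a univariate two-component Gaussian
#' mixture, initialised at the 25th/75th percentiles (plus jittered
#' restarts), with components labelled low/high by mean. The
#' log-likelihood is asserted non-decreasing at every iteration.
#'
#' @param x pooled daily flight hours (>= 10 values, nonzero variance).
#' @param cfg a [stopover_config()].
#' @return Object of class `mixture_fit`: `means`, `sds`, `weight_low`,
#'   `loglik`, `loglik_trace`, `iterations`, `converged`.
#' @export
fit_mixture_em <- function(x, cfg = stopover_config()) {
  x <- x[!is.na(x)]
  if (length(x) < 10) stop("fit_mixture_em: need at least 10 values")
  if (stats::sd(x) < 1e-10) stop("fit_mixture_em: degenerate zero-variance input")
  set.seed(as.integer(cfg$seed))
  sd0 <- stats::sd(x) / 2
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  starts <- list(list(m = q, s = c(sd0, sd0), w = 0.5))
  if (cfg$n_random_starts > 1) {
    for (i in seq_len(cfg$n_random_starts - 1)) {
      starts[[i + 1]] <- list(
        m = sort(stats::runif(2, min(x), max(x))),
        s = sd0 * stats::runif(2, 0.5, 1.5),
        w = stats::runif(1, 0.2, 0.8))
    }
  }
  best <- NULL
  for (st in starts) {
    m <- st$m; s <- pmax(st$s, 1e-4); w <- st$w
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(cfg$max_iter)) {
      d1 <- w * stats::dnorm(x, m[1], s[1])
      d2 <- (1 - w) * stats::dnorm(x, m[2], s[2])
      tot <- d1 + d2
      tot[tot < 1e-300] <- 1e-300
      r <- d1 / tot
      ll <- sum(log(tot))
      if (ll < ll_old - 1e-9)
        stop("fit_mixture_em: log-likelihood decreased (internal error)")
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) < cfg$tol) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      n1 <- sum(r)
      w <- n1 / length(x)
      m[1] <- sum(r * x) / n1
      m[2] <- sum((1 - r) * x) / (length(x) - n1)
      s[1] <- sqrt(sum(r * (x - m[1])^2) / n1)
      s[2] <- sqrt(sum((1 - r) * (x - m[2])^2) / (length(x) - n1))
      s <- pmax(s, 1e-4)
    }
    cand <- list(m = m, s = s, w = w, ll = ll, trace = ll_trace,
                 iter = it, converged = converged)
    if (is.null(best) || cand$ll > best$ll) best <- cand
  }
  if (best$m[1] > best$m[2]) {  # label low/high by mean
    best$m <- rev(best$m); best$s <- rev(best$s); best$w <- 1 - best$w
  }
  out <- list(means = best$m, sds = best$s, weight_low = best$w,
              loglik = best$ll, loglik_trace = best$trace,
              iterations = best$iter, converged = best$converged)
  class(out) <- "mixture_fit"
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Two-component normal mixture (EM, %d iterations%s)\n",
              x$iterations, if (x$converged) "" else ", NOT converged"))
  cat(sprintf("  low:  mean %.3f sd %.3f weight %.3f\n",
              x$means[1], x$sds[1], x$weight_low))
  cat(sprintf("  high: mean %.3f sd %.3f weight %.3f\n",
              x$means[2], x$sds[2], 1 - x$weight_low))
  cat(sprintf("  log-likelihood %.4f\n", x$loglik))
  invisible(x)
}

#' Posterior probability of the low-flight component
#'
#' @param fit a `mixture_fit`.
#' @param x daily flight hours.
#' @return Posterior responsibilities of the low-mean component.
#' @export
posterior_low <- function(fit, x) {
  d1 <- fit$weight_low * stats::dnorm(x, fit$means[1], fit$sds[1])
  d2 <- (1 - fit$weight_low) * stats::dnorm(x, fit$means[2], fit$sds[2])
  d1 / (d1 + d2)
}

#' Flag stopover days from a fitted mixture
#'
#' A day is a stopover when its posterior probability of belonging to the
#' low-flight component strictly exceeds the threshold.
#'
#' @param fit a `mixture_fit`.
#' @param x daily flight hours per bird-day.
#' @param cfg a [stopover_config()].
#' @return Logical vector (`NA` where `x` is `NA`).
#' @export
assign_stopover_days <- function(fit, x, cfg = stopover_config()) {
  p <- posterior_low(fit, x)
  # strictly greater: a posterior numerically equal to the threshold is
  # not a stopover (guard against representation noise at equality)
  out <- p > cfg$posterior_threshold + 1e-12
  out[is.na(x)] <- NA
  out
}

#' Segment flagged days into stopovers
#'
#' Maximal runs of consecutive flagged days become stopovers; gaps are
#' the travelling days between consecutive stopovers. Centroids are the
#' mean smoothed longitude and mean non-masked latitude over each
#' stopover's days.
#'
#' @param dates `Date` vector of migration-window days (sorted).
#' @param flags logical stopover flags aligned with `dates`.
#' @param track optional `position_track` for centroids.
#' @return Object of class `stopover_set`: `stopovers` (`data.frame`:
#'   `start`, `end`, `length`, `lon`, `lat`), `total_stopover_days`,
#'   `n_stopovers`, `gaps` (days between consecutive stopovers).
#' @export
segment_stopovers <- function(dates, flags, track = NULL) {
  stopifnot(length(dates) == length(flags))
  ord <- order(dates)
  dates <- dates[ord]; flags <- flags[ord]
  f <- !is.na(flags) & flags
  # runs must be consecutive calendar days
  grp <- cumsum(c(TRUE, diff(dates) != 1 | diff(f) != 0))
  segs <- lapply(split(seq_along(dates), grp), function(ix) {
    if (!f[ix[1]]) return(NULL)
    data.frame(start = dates[ix[1]], end = dates[ix[length(ix)]],
               length = length(ix))
  })
  segs <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
  if (is.null(segs)) {
    segs <- data.frame(start = as.Date(character(0)),
                       end = as.Date(character(0)), length = numeric(0),
                       lon = numeric(0), lat = numeric(0))
  } else {
    segs$lon <- NA_real_; segs$lat <- NA_real_
    if (!is.null(track)) {
      d <- track$daily
      for (i in seq_len(nrow(segs))) {
        sel <- d$date >= segs$start[i] & d$date <= segs$end[i]
        segs$lon[i] <- mean(d$lon_smooth[sel], na.rm = TRUE)
        lt <- d$lat[sel]
        segs$lat[i] <- if (all(is.na(lt))) NA_real_ else mean(lt, na.rm = TRUE)
      }
    }
  }
  gaps <- if (nrow(segs) > 1)
    as.numeric(segs$start[-1] - segs$end[-nrow(segs)]) - 1 else numeric(0)
  out <- list(stopovers = segs, total_stopover_days = sum(segs$length),
              n_stopovers = nrow(segs), gaps = gaps)
  class(out) <- "stopover_set"
  out
}

#' @export
print.stopover_set <- function(x, ...) {
  cat(sprintf("%d stopovers, %d days total\n", x$n_stopovers,
              x$total_stopover_days))
  if (x$n_stopovers) print(x$stopovers)
  invisible(x)
}
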