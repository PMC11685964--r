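# The mixed-effects model suite: ten gaussian linear mixed models fitted
# by maximum likelihood, likelihood-ratio tests against reduced models,
# parametric bootstrap confidence intervals, and intra-class
# correlations for the random intercepts (bird and year).

#' Fit a gaussian linear mixed model by maximum likelihood
#'
#' Random intercepts are included for each grouping in `random` that has
#' at least two levels in the data (others are dropped with a message);
#' if none remain the model is an ordinary ML linear model. Factor terms
#' with fewer than two levels are removed. Singular fits are retained at
#' the boundary and flagged.
#'
#' @param response response column name.
#' @param fixed_terms character vector of fixed-effect terms (may include
#'   `a:b` interactions).
#' @param data model data.
#' @param random candidate random-intercept groupings.
#' @return Object of class `model_fit`: the fitted model plus
#'   coefficient table, covariance, log-likelihood, and bookkeeping.
#' @export
fit_lmm <- function(response, fixed_terms, data,
                    random = c("bird_id", "year")) {
  data <- droplevels(data[!is.na(data[[response]]), , drop = FALSE])
  # drop factor terms that cannot be estimated
  keep <- vapply(fixed_terms, function(tm) {
    vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
    all(vapply(vars, function(v) {
      x <- data[[v]]
      !(is.character(x) || is.factor(x)) || length(unique(x[!is.na(x)])) >= 2
    }, logical(1)))
  }, logical(1))
  fixed_terms <- fixed_terms[keep]
  random_used <- random[vapply(random, function(g)
    length(unique(data[[g]])) >= 2, logical(1))]
  if (length(random_used) < length(random))
    message("fit_lmm: dropping random intercept(s) with < 2 levels: ",
            paste(setdiff(random, random_used), collapse = ", "))
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  if (length(random_used)) {
    f <- stats::as.formula(paste(
      response, "~", rhs, "+",
      paste(sprintf("(1 | %s)", random_used), collapse = " + ")))
    # boundary (singular) fits are expected and reported via the
    # `singular` flag; optimizer chatter is not useful to callers
    model <- suppressWarnings(suppressMessages(lme4::lmer(
      f, data = data, REML = FALSE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  check.nobs.vs.nlev = "ignore",
                                  check.nobs.vs.nRE = "ignore",
                                  calc.derivs = FALSE))))
    beta <- lme4::fixef(model)
    V <- as.matrix(stats::vcov(model))
    singular <- lme4::isSingular(model)
    vc <- as.data.frame(lme4::VarCorr(model))
    ranvar <- stats::setNames(vc$vcov[vc$grp != "Residual"],
                              vc$grp[vc$grp != "Residual"])
    resid_var <- vc$vcov[vc$grp == "Residual"]
  } else {
    f <- stats::as.formula(paste(response, "~", rhs))
    model <- stats::lm(f, data = data)
    beta <- stats::coef(model)
    V <- stats::vcov(model)
    singular <- FALSE
    ranvar <- numeric(0)
    # ML residual variance
    resid_var <- sum(stats::residuals(model)^2) / stats::nobs(model)
  }
  ll <- as.numeric(stats::logLik(model))
  out <- list(model = model, response = response, fixed_terms = fixed_terms,
              coefficients = beta, vcov = V, loglik = ll,
              n_params = attr(stats::logLik(model), "df"),
              random_used = random_used, random_variances = ranvar,
              residual_variance = resid_var, singular = singular,
              n_obs = stats::nobs(model), data = data)
  class(out) <- "model_fit"
  out
}

#' Refit a model with one term dropped
#'
#' Drops `term` (and, if it is a main effect, nothing else: interactions
#' stay, matching a single-term likelihood-ratio test) and refits on the
#' same data.
#'
#' @param fit a `model_fit`.
#' @param term the fixed term to drop.
#' @return A `model_fit`.
#' @export
drop_term <- function(fit, term) {
  if (!term %in% fit$fixed_terms) stop("drop_term: term not in model")
  fit_lmm(fit$response, setdiff(fit$fixed_terms, term), fit$data,
          random = fit$random_used)
}

#' Likelihood-ratio test between nested ML fits
#'
#' @param full,reduced `model_fit` objects on the same data, `reduced`
#'   nested in `full`.
#' @return List with `chisq`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  if (!all(reduced$fixed_terms %in% full$fixed_terms) ||
      full$n_obs != reduced$n_obs)
    stop("lrt: models are not nested on the same data")
  chisq <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- full$n_params - reduced$n_params
  if (df < 0) stop("lrt: reduced model has more parameters than full")
  p <- if (df == 0) 1 else stats::pchisq(chisq, df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p)
}

#' Parametric bootstrap confidence intervals for fixed effects
#'
#' Resamples coefficient vectors from the estimated sampling
#' distribution of the fixed effects (multivariate normal at the ML
#' estimate with the model's covariance) and returns percentile
#' intervals, in the style of arm::sim.
#'
#' @param fit a `model_fit`.
#' @param n_boot number of resamples.
#' @param seed integer seed.
#' @param level confidence level.
#' @return `data.frame`: `term`, `estimate`, `ci_lo`, `ci_hi`.
#' @export
bootstrap_ci <- function(fit, n_boot = 1000, seed = 1, level = 0.95) {
  set.seed(as.integer(seed))
  beta <- fit$coefficients
  V <- (fit$vcov + t(fit$vcov)) / 2
  draws <- MASS::mvrnorm(n_boot, mu = beta, Sigma = V)
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = length(beta))
  a <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a))
  data.frame(term = names(beta), estimate = unname(beta),
             ci_lo = unname(qs[1, ]), ci_hi = unname(qs[2, ]),
             row.names = NULL)
}

#' Intra-class correlation of a random-intercept grouping
#'
#' The grouping's variance share of the total random variance
#' (all random intercepts plus residual).
#'
#' @param fit a `model_fit`.
#' @param grouping grouping factor name.
#' @return Fraction in `[0, 1]` (0 if the grouping was dropped).
#' @export
icc <- function(fit, grouping) {
  tot <- sum(fit$random_variances) + fit$residual_variance
  v <- fit$random_variances[grouping]
  if (is.na(v)) return(0)
  unname(v / tot)
}

# ---- the model suite ---------------------------------------------------

.MODEL_SPECS <- list(
  list(id = 1, response = "flight_hours", data = "phases",
       terms = c("phase", "dep_days_aug1", "phase:dep_days_aug1", "colony"),
       label = "Hours of flight per day/night"),
  list(id = 2, response = "flight_hours", data = "nights",
       terms = c("night_moon", "dep_days_aug1", "night_moon:dep_days_aug1",
                 "colony"),
       label = "Hours of night flight"),
  list(id = 3, response = "flight_proportion", data = "nights",
       terms = c("moon_up", "colony"),
       label = "Proportion of night spent flying"),
  list(id = 4, response = "forage_hours", data = "nights",
       terms = c("night_moon", "dep_days_aug1", "night_moon:dep_days_aug1",
                 "colony"),
       label = "Hours of night foraging"),
  list(id = 5, response = "total_stopover_days", data = "tracks",
       terms = c("dep_days_aug1", "colony"),
       label = "Total stopover days"),
  list(id = 6, response = "stopover_forage_hours", data = "tracks",
       terms = c("dep_days_aug1", "colony"),
       label = "Daily foraging hours at stopovers"),
  list(id = 7, response = "duration", data = "tracks",
       terms = c("mean_moon", "dep_days_aug1", "mean_moon:dep_days_aug1",
                 "colony"),
       label = "Migration duration (days)"),
  list(id = 8, response = "dep_days_aug1", data = "lay_tracks",
       terms = c("lay_days", "colony"),
       label = "Departure date (days since 1 Aug)"),
  list(id = 9, response = "breeding_period", data = "lay_tracks",
       terms = c("lay_days", "colony"),
       label = "Breeding period (days)"),
  list(id = 10, response = "mean_chl_ratio", data = "tracks",
       terms = c("dep_days_aug1", "colony"),
       label = "Stopover / wintering chlorophyll ratio")
)

.prep_colony <- function(df, reference = "Copeland") {
  if (!"colony" %in% names(df)) return(df)
  lv <- unique(df$colony)
  if (reference %in% lv) lv <- c(reference, sort(setdiff(lv, reference)))
  df$colony <- factor(df$colony, levels = lv)
  df
}

#' Fit the full ten-model suite
#'
#' Fits the ten phenology/behaviour models on the bird-day/night table
#' and the per-track summary, with random intercepts for bird and year,
#' a likelihood-ratio test per fixed term (whole factor for colony), and
#' parametric bootstrap confidence intervals.
#'
#' Model data: models 1--4 use travelling (non-stopover) days within the
#' migration window (model 1 both phases, 2--4 nights); models 5--7 and
#' 10 per-track summaries; models 8--9 the tracks with known lay dates.
#'
#' @param phases bird-day/night table rows ([birdday_table()]) restricted
#'   to the migration window, stopover days flagged.
#' @param tracks per-track summary (one row per bird-year).
#' @param n_boot bootstrap resamples per model.
#' @param seed integer seed.
#' @param models model ids to fit.
#' @return Object of class `model_suite`: `fits` (per model: fit, lrt per
#'   term, ci), and `report` -- a tidy table with one row per
#'   coefficient: `model_id`, `response`, `term`, `estimate`, `ci_lo`,
#'   `ci_hi`, `chisq`, `df`, `p`.
#' @export
run_model_suite <- function(phases, tracks, n_boot = 1000, seed = 1,
                            models = 1:10) {
  mig <- phases[phases$in_migration & !is.na(phases$is_stopover_day) &
                  !phases$is_stopover_day, , drop = FALSE]
  nights <- mig[mig$phase == "night", , drop = FALSE]
  lay_tracks <- tracks[!is.na(tracks$lay_days), , drop = FALSE]
  datasets <- list(phases = .prep_colony(mig), nights = .prep_colony(nights),
                   tracks = .prep_colony(tracks),
                   lay_tracks = .prep_colony(lay_tracks))
  fits <- list()
  rows <- list()
  for (spec in .MODEL_SPECS) {
    if (!spec$id %in% models) next
    dat <- datasets[[spec$data]]
    have <- spec$response %in% names(dat) &&
      any(!is.na(dat[[spec$response]]))
    if (!have || nrow(dat) < 10) {
      fits[[as.character(spec$id)]] <- list(skipped = TRUE,
                                            reason = "insufficient data")
      next
    }
    fit <- fit_lmm(spec$response, spec$terms, dat)
    ci <- bootstrap_ci(fit, n_boot = n_boot, seed = seed + spec$id)
    tests <- lapply(fit$fixed_terms, function(tm)
      lrt(fit, drop_term(fit, tm)))
    names(tests) <- fit$fixed_terms
    fits[[as.character(spec$id)]] <- list(fit = fit, ci = ci, tests = tests,
                                          label = spec$label)
    term_of <- function(coef_name) {
      for (tm in rev(fit$fixed_terms)) {
        vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
        pat <- paste0("^", paste(vars, collapse = ".*:.*"))
        if (grepl(":", coef_name) == grepl(":", tm) &&
            all(vapply(vars, function(v) grepl(v, coef_name, fixed = TRUE),
                       logical(1))))
          return(tm)
      }
      NA_character_
    }
    tm_map <- vapply(ci$term, term_of, character(1))
    rows[[length(rows) + 1]] <- data.frame(
      model_id = spec$id, response = spec$label, term = ci$term,
      estimate = ci$estimate, ci_lo = ci$ci_lo, ci_hi = ci$ci_hi,
      chisq = vapply(tm_map, function(tm)
        if (is.na(tm)) NA_real_ else tests[[tm]]$chisq, numeric(1)),
      df = vapply(tm_map, function(tm)
        if (is.na(tm)) NA_real_ else tests[[tm]]$df, numeric(1)),
      p = vapply(tm_map, function(tm)
        if (is.na(tm)) NA_real_ else tests[[tm]]$p, numeric(1)),
      icc_bird = icc(fit, "bird_id"), icc_year = icc(fit, "year"),
      singular = fit$singular, row.names = NULL)
  }
  out <- list(fits = fits, report = do.call(rbind, rows))
  class(out) <- "model_suite"
  out
}

#' @export
print.model_suite <- function(x, digits = 3, ...) {
  r <- x$report
  r$estimate <- round(r$estimate, digits)
  r$ci_lo <- round(r$ci_lo, digits)
  r$ci_hi <- round(r$ci_hi, digits)
  r$chisq <- round(r$chisq, 2)
  r$p <- signif(r$p, 2)
  print(r[, c("model_id", "term", "estimate", "ci_lo", "ci_hi", "chisq", "p")])
  invisible(x)
}
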