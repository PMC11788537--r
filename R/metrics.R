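# threshold-crossing season metrics on phenology curves

# first grid day with p > tau (NA if never); vectorised scan
first_exceed <- function(doy, p, tau) {
  i <- first_which(p > tau)
  if (is.na(i)) NA_real_ else doy[i]
}

# first grid day after the post-start maximum with p < tau;
# censored at the domain end if the curve never drops below tau
first_drop_after_max <- function(doy, p, tau, start_day) {
  if (is.na(start_day)) return(list(day = NA_real_, censored = FALSE))
  from <- first_which(doy >= start_day)
  imax <- from - 1L + which.max(p[from:length(p)])
  if (imax < length(p)) {
    rel <- which(p[(imax + 1L):length(p)] < tau)
    if (length(rel))
      return(list(day = doy[imax + rel[1L]], censored = FALSE))
  }
  list(day = doy[length(doy)], censored = TRUE)
}

#' Start of the breeding season from a phenology curve
#'
#' The start day is the first day of the grid on which the expected
#' proportion of likely-breeding observations exceeds the threshold `tau`
#' (5% by default). The point estimate is computed on the posterior-mean
#' curve; the same rule applied to each posterior draw yields the
#' uncertainty distribution.
#'
#' @param curve A `phenology_curve` from [expected_proportion_curve()].
#' @param tau Threshold on the expected proportion.
#' @return List of class `season_crossing`: `day` (NA if the mean curve
#'   never exceeds `tau`, with `defined = FALSE`), `defined`, `draws`
#'   (per-draw crossing days, NA where a draw never exceeds), and `ci`
#'   (2.5/97.5% quantiles of the draws).
#' @export
extract_start <- function(curve, tau = 0.05) {
  stopifnot(inherits(curve, "phenology_curve"))
  day <- first_exceed(curve$doy, curve$mean, tau)
  draws <- apply(curve$draws, 1, function(p) first_exceed(curve$doy, p, tau))
  structure(list(day = day, defined = !is.na(day), censored = FALSE,
                 draws = draws,
                 ci = if (all(is.na(draws))) c(NA_real_, NA_real_)
                      else stats::quantile(draws, c(0.025, 0.975), na.rm = TRUE,
                                           names = FALSE),
                 tau = tau, what = "start"),
            class = "season_crossing")
}

#' End of the breeding season from a phenology curve
#'
#' The end day is the first day after the curve's post-start maximum on
#' which the expected proportion drops below `tau`. Anchoring the search
#' after the maximum keeps early dips of wiggly fitted curves from being
#' mistaken for the season end. If the curve never drops below `tau` before
#' the domain end the end day is censored at the domain end and flagged.
#'
#' @inheritParams extract_start
#' @param start Optional precomputed [extract_start()] result; computed
#'   from `curve` if missing.
#' @return A `season_crossing` list (see [extract_start()]) with a
#'   `censored` flag.
#' @export
extract_end <- function(curve, tau = 0.05, start = NULL) {
  stopifnot(inherits(curve, "phenology_curve"))
  if (is.null(start)) start <- extract_start(curve, tau)
  mean_end <- first_drop_after_max(curve$doy, curve$mean, tau, start$day)
  draws <- rep(NA_real_, nrow(curve$draws))
  n_cens <- 0L
  for (i in seq_len(nrow(curve$draws))) {
    s <- start$draws[i]
    if (is.na(s)) next
    e <- first_drop_after_max(curve$doy, curve$draws[i, ], tau, s)
    draws[i] <- e$day
    n_cens <- n_cens + e$censored
  }
  structure(list(day = mean_end$day, defined = !is.na(mean_end$day),
                 censored = mean_end$censored,
                 draws = draws,
                 ci = if (all(is.na(draws))) c(NA_real_, NA_real_)
                      else stats::quantile(draws, c(0.025, 0.975), na.rm = TRUE,
                                           names = FALSE),
                 tau = tau, what = "end"),
            class = "season_crossing")
}

#' @export
print.season_crossing <- function(x, ...) {
  lab <- if (x$defined)
    sprintf("day %g (95%% CrI %g-%g)%s", x$day, x$ci[1], x$ci[2],
            if (x$censored) ", censored at domain end" else "")
  else "undefined (curve never exceeds threshold)"
  cat(sprintf("Season %s at threshold %g: %s\n", x$what, x$tau, lab))
  invisible(x)
}

#' Breeding season duration
#'
#' Days between season start and end; undefined when either crossing is.
#'
#' @param start,end `season_crossing` objects (or numbers).
#' @return Numeric duration in days (NA if undefined).
#' @export
season_duration <- function(start, end) {
  s <- if (inherits(start, "season_crossing")) start$day else start
  e <- if (inherits(end, "season_crossing")) end$day else end
  if (is.na(s) || is.na(e)) return(NA_real_)
  e - s
}

#' Phenology metrics for a set of curves
#'
#' Applies [extract_start()], [extract_end()] and [season_duration()] to
#' each year x region curve.
#'
#' @param curves List of `phenology_curve` objects (as from
#'   [fit_phenology_all()]).
#' @param tau Threshold.
#' @return Data frame with one row per curve: `year`, `region`, `tau`,
#'   `start`, `end`, `duration`, 95% interval bounds for each, and the
#'   flags `start_defined`, `end_censored`.
#' @export
phenology_metrics <- function(curves, tau = 0.05) {
  rows <- lapply(curves, function(cv) {
    st <- extract_start(cv, tau)
    en <- extract_end(cv, tau, start = st)
    dur_draws <- en$draws - st$draws
    dur_ci <- if (all(is.na(dur_draws))) c(NA_real_, NA_real_)
              else stats::quantile(dur_draws, c(0.025, 0.975), na.rm = TRUE,
                                   names = FALSE)
    data.frame(year = cv$year, region = cv$region, tau = tau,
               start = st$day, start_lo = st$ci[1], start_hi = st$ci[2],
               end = en$day, end_lo = en$ci[1], end_hi = en$ci[2],
               duration = season_duration(st, en),
               duration_lo = dur_ci[1], duration_hi = dur_ci[2],
               start_defined = st$defined, end_censored = en$censored,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Threshold-sensitivity analysis of the season duration
#'
#' Recomputes the duration of every curve at each alternative threshold and
#' correlates the resulting duration vectors with the reference-threshold
#' vector (Pearson). High correlations across thresholds indicate that the
#' chosen threshold is not driving the results.
#'
#' @param curves List of `phenology_curve` objects (>= 3).
#' @param taus Alternative thresholds (default 1%--12% in 1% steps).
#' @param reference Reference threshold (default 5%).
#' @return Data frame `tau`, `r` (correlation with the reference durations),
#'   `n` (complete pairs). Thresholds where no duration is defined are
#'   omitted with a warning.
#' @export
threshold_sensitivity <- function(curves, taus = seq(0.01, 0.12, by = 0.01),
                                  reference = 0.05) {
  if (length(curves) < 3L)
    stopf("threshold sensitivity needs >= 3 curves (got %d)", length(curves))
  dur_at <- function(tau) vapply(curves, function(cv) {
    st <- extract_start_mean(cv, tau)
    if (is.na(st)) return(NA_real_)
    en <- first_drop_after_max(cv$doy, cv$mean, tau, st)
    en$day - st
  }, numeric(1))
  ref <- dur_at(reference)
  out <- lapply(taus, function(tau) {
    d <- dur_at(tau)
    ok <- !is.na(d) & !is.na(ref)
    if (sum(ok) < 3L) {
      warnf("threshold %.2f omitted: fewer than 3 defined durations", tau)
      return(NULL)
    }
    data.frame(tau = tau, r = stats::cor(d[ok], ref[ok]), n = sum(ok))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# point-estimate start only (posterior-mean curve), used in loops where the
# per-draw distribution is not needed
extract_start_mean <- function(curve, tau) {
  first_exceed(curve$doy, curve$mean, tau)
}
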