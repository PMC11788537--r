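# mixed-effect models linking phenology metrics to window climate and
# snowmelt covariates, plus the temperature trend regressions

#' Linear mixed-effect model for a phenology metric
#'
#' Gaussian LMM of a season metric (start, end, or duration, in days)
#' against critical-window climate summaries and snowmelt metrics, with
#' random intercepts for year and biogeographic region. Coefficients are
#' reported in two parameterizations computed from one fit: predictors are
#' centred at their analysis-sample means in both; the *standardized*
#' slopes refer to predictors additionally divided by their sample SD
#' (effect per SD, comparable across predictors), the *unstandardized*
#' slopes to the raw units (days/degC, days per precipitation day,
#' days/day). The identity `standardized = unstandardized x SD(x)` holds
#' exactly for every term; the interaction column is scaled by the product
#' of the two SDs. The response keeps its units (days) in both
#' parameterizations, so the intercept is the expected metric at average
#' covariate conditions.
#'
#' An optional temperature x precipitation interaction can be retained
#' always, never, or by the default reproducible rule (`"auto"`): keep it
#' when the 80% interval of its standardized coefficient excludes zero.
#'
#' Intervals come from the engine: `"sim"` (default) draws coefficient
#' vectors from the Gaussian approximation to the fixed-effect posterior
#' (flat priors; organised as 4 chains x 2000 iterations with the first
#' half discarded), `"reml"` uses Wald intervals.
#'
#' @param data Data frame with the response column, covariate columns, and
#'   `year` and `region` grouping columns.
#' @param response Name of the response column.
#' @param covariates Character vector of covariate column names.
#' @param interaction Optional `c(a, b)` pair of covariate names.
#' @param retain_interaction `"auto"`, `"always"`, or `"never"`.
#' @param engine `"sim"` or `"reml"`.
#' @param chains,iter Draw budget of the sim engine.
#' @param seed Seed for the draw stage.
#' @return Object of class `effects_fit`; see [coef.effects_fit()] for the
#'   coefficient table.
#' @export
fit_lmm <- function(data, response, covariates, interaction = NULL,
                    retain_interaction = c("auto", "always", "never"),
                    engine = c("sim", "reml"), chains = 4, iter = 2000,
                    seed = NULL) {
  engine <- match.arg(engine)
  retain_interaction <- match.arg(retain_interaction)
  need <- c(response, covariates, "year", "region")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stopf("data lacks column(s): %s", paste(miss, collapse = ", "))
  rows <- stats::complete.cases(data[, need])
  if (any(!rows)) {
    warnf("%d incomplete row(s) dropped from the %s model", sum(!rows),
          response)
    data <- data[rows, , drop = FALSE]
  }
  if (nrow(data) < 10L)
    stopf("at least 10 complete rows are required (got %d)", nrow(data))
  centers <- vapply(covariates, function(v) mean(data[[v]]), numeric(1))
  scales <- vapply(covariates, function(v) stats::sd(data[[v]]), numeric(1))
  if (any(scales == 0))
    stopf("covariate '%s' has zero variance", covariates[which(scales == 0)[1]])
  zdat <- data
  for (v in covariates) zdat[[v]] <- (data[[v]] - centers[v]) / scales[v]
  zdat$year <- factor(zdat$year)
  zdat$region <- factor(zdat$region)

  build <- function(with_int) {
    fixed <- paste(covariates, collapse = " + ")
    if (with_int && !is.null(interaction))
      fixed <- paste(fixed, sprintf("%s:%s", interaction[1], interaction[2]),
                     sep = " + ")
    stats::as.formula(sprintf("%s ~ %s + (1 | year) + (1 | region)",
                              response, fixed))
  }
  fit_one <- function(with_int) {
    suppressMessages(lme4::lmer(build(with_int), data = zdat, REML = TRUE,
                                control = lme4::lmerControl(
                                  check.conv.singular = "ignore")))
  }
  has_int <- !is.null(interaction)
  if (has_int && !all(interaction %in% covariates))
    stopf("interaction terms must be among the covariates")
  fit <- fit_one(has_int)
  if (has_int && retain_interaction == "never") {
    fit <- fit_one(FALSE); has_int <- FALSE
  } else if (has_int && retain_interaction == "auto") {
    b <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    iterm <- length(b)
    z80 <- stats::qnorm(0.9)
    lo <- b[iterm] - z80 * sqrt(V[iterm, iterm])
    hi <- b[iterm] + z80 * sqrt(V[iterm, iterm])
    if (lo < 0 && hi > 0) {
      fit <- fit_one(FALSE); has_int <- FALSE
    }
  }

  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  terms <- names(b)
  term_scale <- vapply(terms, function(tm) {
    if (tm == "(Intercept)") return(NA_real_)
    if (grepl(":", tm, fixed = TRUE)) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      return(prod(scales[parts]))
    }
    scales[[tm]]
  }, numeric(1))

  ndraws <- chains * iter / 2
  if (!is.null(seed)) set.seed(seed)
  draws <- if (engine == "sim") mgcv::rmvn(ndraws, b, V) else NULL
  if (engine == "sim") {
    qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975))
    lo <- qs[1, ]; hi <- qs[2, ]
  } else {
    z <- stats::qnorm(0.975)
    lo <- b - z * sqrt(diag(V)); hi <- b + z * sqrt(diag(V))
  }
  tab <- data.frame(term = terms,
                    std = unname(b), std_lo = unname(lo), std_hi = unname(hi),
                    unstd = unname(b) / term_scale,
                    unstd_lo = unname(lo) / term_scale,
                    unstd_hi = unname(hi) / term_scale,
                    stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  re_sd <- stats::setNames(vc$sdcor[match(c("year", "region"), vc$grp)],
                           c("year", "region"))
  ranges <- lapply(covariates, function(v) range(data[[v]]))
  names(ranges) <- covariates
  structure(list(response = response, covariates = covariates,
                 interaction = if (has_int) interaction else NULL,
                 table = tab, re_sd = re_sd,
                 sigma = stats::sigma(fit),
                 singular = lme4::isSingular(fit),
                 centers = centers, scales = scales,
                 term_scale = term_scale,
                 draws = draws, engine = engine, vcov = V,
                 coef_std = b, ranges = ranges, n = nrow(zdat),
                 fit = fit),
            class = "effects_fit")
}

#' @export
print.effects_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Mixed-effect model for %s (n = %d, engine %s%s)\n", x$response,
              x$n, x$engine,
              if (x$singular) ", singular random-effect fit" else ""))
  tab <- x$table
  num <- vapply(tab[-1], function(cl) is.numeric(cl), logical(1))
  tab[-1][num] <- lapply(tab[-1][num], function(cl) signif(cl, digits))
  print(tab, row.names = FALSE)
  cat(sprintf("Random-effect SDs (days): year %.2f, region %.2f; residual %.2f\n",
              x$re_sd["year"], x$re_sd["region"], x$sigma))
  invisible(x)
}

#' Coefficient table of an effects model
#'
#' @param object An [fit_lmm()] result.
#' @param ... Unused.
#' @return Data frame with one row per fixed-effect term: standardized
#'   estimate with 95% interval, and unstandardized estimate with 95%
#'   interval (NA for the intercept, which has no natural per-unit scale).
#' @export
coef.effects_fit <- function(object, ...) object$table

#' @export
summary.effects_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
confint.effects_fit <- function(object, parm = NULL, level = 0.95, ...) {
  a <- (1 - level) / 2
  if (object$engine == "sim") {
    qs <- apply(object$draws, 2, stats::quantile, probs = c(a, 1 - a))
    out <- t(qs)
  } else {
    z <- stats::qnorm(1 - a)
    se <- sqrt(diag(object$vcov))
    out <- cbind(object$coef_std - z * se, object$coef_std + z * se)
  }
  rownames(out) <- object$table$term
  colnames(out) <- paste0(100 * c(a, 1 - a), " %")
  if (!is.null(parm)) out <- out[parm, , drop = FALSE]
  out
}

# posterior draws of a standardized coefficient (sim engine) or a Gaussian
# stand-in from the Wald curvature (reml engine)
coef_draws <- function(fit, ndraws = 4000) {
  if (!is.null(fit$draws)) return(fit$draws)
  mgcv::rmvn(ndraws, fit$coef_std, fit$vcov)
}

#' Response change per unit change of one covariate
#'
#' Scales the unstandardized slope by `delta`; in models containing an
#' interaction, the slope refers to conditions where the interacting
#' covariate sits at its sample mean (the models centre predictors, so the
#' main-effect coefficient is exactly that conditional slope).
#'
#' @param fit An [fit_lmm()] result.
#' @param covariate Covariate name.
#' @param delta Change in raw covariate units.
#' @return List `estimate`, `lo`, `hi` (95%), in response units (days).
#' @export
effect_per_unit <- function(fit, covariate, delta = 1) {
  stopifnot(inherits(fit, "effects_fit"))
  i <- match(covariate, fit$table$term)
  if (is.na(i)) stopf("covariate '%s' is not a term of the model", covariate)
  dr <- coef_draws(fit)[, i] / fit$term_scale[i] * delta
  est <- fit$table$unstd[i] * delta
  qs <- stats::quantile(dr, c(0.025, 0.975), names = FALSE)
  list(estimate = est, lo = min(qs), hi = max(qs), delta = delta,
       covariate = covariate)
}

#' Predicted response difference between two covariate scenarios
#'
#' Difference of the linear predictions (random effects at zero) between
#' scenario A and scenario B, with a 95% interval from the joint
#' coefficient distribution. Scenarios outside the observed covariate range
#' trigger an extrapolation warning, not an error.
#'
#' @param fit An [fit_lmm()] result.
#' @param scenario_a,scenario_b Named numeric vectors giving every model
#'   covariate in raw units.
#' @return List `estimate`, `lo`, `hi` (days, A minus B).
#' @export
scenario_contrast <- function(fit, scenario_a, scenario_b) {
  stopifnot(inherits(fit, "effects_fit"))
  need <- fit$covariates
  for (sc in list(scenario_a, scenario_b)) {
    miss <- setdiff(need, names(sc))
    if (length(miss))
      stopf("scenario lacks covariate(s): %s", paste(miss, collapse = ", "))
  }
  for (v in need) {
    vals <- c(scenario_a[[v]], scenario_b[[v]])
    if (any(vals < fit$ranges[[v]][1] | vals > fit$ranges[[v]][2]))
      warnf("scenario value for '%s' lies outside the observed range [%.3g, %.3g]",
            v, fit$ranges[[v]][1], fit$ranges[[v]][2])
  }
  row_for <- function(sc) {
    z <- (unlist(sc[need]) - fit$centers[need]) / fit$scales[need]
    out <- numeric(nrow(fit$table))
    names(out) <- fit$table$term
    out["(Intercept)"] <- 1
    out[need] <- z
    if (!is.null(fit$interaction)) {
      tm <- sprintf("%s:%s", fit$interaction[1], fit$interaction[2])
      out[tm] <- z[fit$interaction[1]] * z[fit$interaction[2]]
    }
    out
  }
  d <- row_for(scenario_a) - row_for(scenario_b)
  est <- sum(fit$coef_std * d)
  dr <- as.vector(coef_draws(fit) %*% d)
  qs <- stats::quantile(dr, c(0.025, 0.975), names = FALSE)
  list(estimate = est, lo = qs[1], hi = qs[2])
}

#' Linear temperature trend across years
#'
#' Gaussian linear model of an annual mean-temperature series against year;
#' reports the slope (degC/year) with its 95% interval and the implied
#' total change over the study span, `slope x (last year - first year)`.
#'
#' @param year Integer vector of years.
#' @param temp Annual mean temperatures (degC).
#' @return Object of class `trend_fit`: `slope`, `slope_lo`, `slope_hi`,
#'   `total_change`, `total_lo`, `total_hi`, `span`, `n`, `fit`.
#' @export
fit_trend <- function(year, temp) {
  ok <- !is.na(year) & !is.na(temp)
  year <- year[ok]; temp <- temp[ok]
  if (length(year) < 3L) stopf("at least 3 years are required")
  if (stats::sd(year) == 0) stopf("all observations share the same year")
  fit <- stats::lm(temp ~ year)
  slope <- unname(stats::coef(fit)[2])
  ci <- stats::confint(fit, "year", level = 0.95)
  span <- diff(range(year))
  structure(list(slope = slope, slope_lo = ci[1], slope_hi = ci[2],
                 total_change = slope * span,
                 total_lo = ci[1] * span, total_hi = ci[2] * span,
                 span = span, n = length(year), fit = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Temperature trend over %d years: %.4f degC/yr (95%% CI %.4f to %.4f)\n",
              x$span + 1, x$slope, x$slope_lo, x$slope_hi))
  cat(sprintf("  total change over the span: %.2f degC (%.2f to %.2f)\n",
              x$total_change, x$total_lo, x$total_hi))
  invisible(x)
}

#' Mean temperature during the breeding season of one region-year
#'
#' Mean of daily mean temperature between the season start and end days --
#' the conditions the birds actually experienced while breeding.
#'
#' @param climate Climate data frame.
#' @param year,region Cell selector.
#' @param start,end Season limits (days of year); NA gives NA.
#' @return Mean temperature (degC), or NA when the season is undefined.
#' @export
breeding_season_mean_temp <- function(climate, year, region, start, end) {
  if (is.na(start) || is.na(end)) return(NA_real_)
  keep <- climate$year == year & climate$region == region &
    climate$day_of_year >= start & climate$day_of_year <= end
  if (!any(keep)) return(NA_real_)
  mean(climate$temp_mean[keep])
}
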