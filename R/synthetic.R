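#' Configuration of the synthetic study generator
#'
#' Describes a simulated multi-year, multi-region citizen-science study with
#' known ground truth. The defaults mirror the scale and effect structure of
#' an Alpine breeding-phenology study: 16 years (2006--2021) x 4
#' biogeographic regions, ~200 observations per region-year (~12,800 rows),
#' a minority likely-breeding state following a rise--plateau--fall seasonal
#' curve, and planted linear effects of window-summarized climate on the true
#' start and end of the breeding season.
#'
#' True start/end days are constructed per year x region as
#' \deqn{start = base + \beta_T (T_w - ref) + \beta_P (P_w - ref) + u_{year}
#'   + v_{region} + \epsilon}
#' where \eqn{T_w} is the mean temperature in the causal start window,
#' \eqn{P_w} the number of precipitation days (>= 1 mm) in the causal
#' precipitation window, and references are the deterministic seasonal
#' expectations (so only weather anomalies move phenology). The end day is
#' analogous with its own temperature window and slope.
#'
#' @param years Integer vector of study years.
#' @param regions Character vector of region names.
#' @param effort Observations per region-year.
#' @param effort_bulge Summer weighting of observation dates: 0 = uniform
#'   over the season; larger values concentrate effort around midsummer.
#' @param p_max Plateau probability of the likely-breeding curve.
#' @param tau Threshold at which the latent curve is anchored: the curve
#'   crosses `tau` exactly at the true start and end days.
#' @param rise_scale,fall_scale Logistic scales (days) of the curve's rise
#'   and fall.
#' @param base_start,base_end Baseline start/end days of year.
#' @param beta_T_start Planted effect (days/degC) of start-window mean
#'   temperature on the start day.
#' @param beta_P_start Planted effect (days per precipitation day) on the
#'   start day.
#' @param beta_T_end Planted effect (days/degC) of end-window mean
#'   temperature on the end day.
#' @param window_T_start,window_P_start,window_T_end Causal windows as
#'   `c(first, last)` days of year.
#' @param sd_year_start,sd_region_start Random-intercept SDs (days) for the
#'   start day.
#' @param sd_year_end,sd_region_end Random-intercept SDs (days) for the end
#'   day.
#' @param sd_resid Residual SD (days) of true start/end days.
#' @param temp_mean Annual-mean temperature (degC) of the simulated
#'   elevation band.
#' @param temp_ref Reference level used to centre window-temperature
#'   anomalies (defaults to `temp_mean`).
#' @param temp_amp Seasonal amplitude (degC) of the temperature sinusoid.
#' @param temp_peak_day Day of year of the temperature maximum.
#' @param temp_noise_sd Daily temperature noise SD (degC).
#' @param temp_trend Linear warming trend (degC/year).
#' @param year_anom_sd SD (degC) of yearly temperature anomalies shared
#'   across regions.
#' @param spell_sd_shared,spell_sd_region Marginal SDs (degC) of the
#'   week-scale weather-spell anomalies (stationary AR(1) over days):
#'   one spell series per year shared by all regions, plus one
#'   region-specific series. Spells are what give different candidate
#'   windows within a season genuinely different anomalies.
#' @param spell_corr_length E-folding correlation length (days) of the
#'   spell processes.
#' @param region_temp_offsets Named numeric, regional temperature offsets
#'   (degC).
#' @param precip_occ Daily precipitation occurrence probability.
#' @param precip_occ_ref Reference occurrence probability used to centre
#'   precipitation-day anomalies (defaults to `precip_occ`).
#' @param precip_shape,precip_scale Gamma parameters of wet-day amounts (mm).
#' @param snow_max Maximum snow-cover fraction.
#' @param snow_t50 Mean day of year at which cover first reaches 50%.
#' @param snow_span Mean 95%-to-5%-of-maximum melt span (days).
#' @param snow_t50_sd,snow_span_sd Between-year SDs of melt timing and span.
#' @param snow_temp_coupling Shift (days/degC) of melt timing per yearly
#'   temperature anomaly (negative: warm years melt earlier).
#' @param snow_region_offsets Named numeric, regional melt-timing offsets
#'   (days).
#' @param doy_range Day-of-year domain `c(first, last)` of the simulated
#'   season (Mar 1 -- Oct 31 by default).
#' @param map Breeding-code map used when assigning codes.
#' @return A list of class `synth_config`.
#' @seealso [generate_truth()], [simulate_study()]
#' @export
synth_config <- function(years = 2006:2021,
                         regions = default_regions(),
                         effort = 200,
                         effort_bulge = 0,
                         p_max = 0.35,
                         tau = 0.05,
                         rise_scale = 6,
                         fall_scale = 8,
                         base_start = 142,
                         base_end = 236,
                         beta_T_start = -6,
                         beta_P_start = 3.7,
                         beta_T_end = -1.8,
                         window_T_start = c(125, 161),
                         window_P_start = c(109, 119),
                         window_T_end = c(165, 181),
                         sd_year_start = 6,
                         sd_region_start = 8,
                         sd_year_end = 4,
                         sd_region_end = 2.5,
                         sd_resid = 3,
                         temp_mean = 2,
                         temp_ref = temp_mean,
                         temp_amp = 9,
                         temp_peak_day = 200,
                         temp_noise_sd = 2,
                         temp_trend = 0.0533,
                         year_anom_sd = 0.8,
                         spell_sd_shared = 1.2,
                         spell_sd_region = 0.8,
                         spell_corr_length = 12,
                         region_temp_offsets = c(northern = 0, eastern = -0.5,
                                                 southern = 1.5, western = 0.3),
                         precip_occ = 0.5,
                         precip_occ_ref = precip_occ,
                         precip_shape = 0.8,
                         precip_scale = 8,
                         snow_max = 0.95,
                         snow_t50 = 150,
                         snow_span = 45,
                         snow_t50_sd = 8,
                         snow_span_sd = 6,
                         snow_temp_coupling = -3,
                         snow_region_offsets = c(northern = 0, eastern = 4,
                                                 southern = -8, western = 2),
                         doy_range = c(60, 304),
                         map = code_map()) {
  cfg <- as.list(environment())
  if (length(cfg$regions) < 1L) stopf("at least one region is required")
  if (is.null(names(cfg$region_temp_offsets)))
    names(cfg$region_temp_offsets) <- rep_len(cfg$regions,
                                              length(cfg$region_temp_offsets))
  if (is.null(names(cfg$snow_region_offsets)))
    names(cfg$snow_region_offsets) <- rep_len(cfg$regions,
                                              length(cfg$snow_region_offsets))
  cfg$region_temp_offsets <-
    cfg$region_temp_offsets[match(cfg$regions, names(cfg$region_temp_offsets))]
  cfg$region_temp_offsets[is.na(cfg$region_temp_offsets)] <- 0
  names(cfg$region_temp_offsets) <- cfg$regions
  cfg$snow_region_offsets <-
    cfg$snow_region_offsets[match(cfg$regions, names(cfg$snow_region_offsets))]
  cfg$snow_region_offsets[is.na(cfg$snow_region_offsets)] <- 0
  names(cfg$snow_region_offsets) <- cfg$regions
  structure(cfg, class = "synth_config")
}

# deterministic seasonal temperature expectation, optionally with region
# offset and trend
seasonal_temp <- function(cfg, doy, year = NULL, region = NULL) {
  base <- cfg$temp_mean +
    cfg$temp_amp * cos(2 * pi * (doy - cfg$temp_peak_day) / 365)
  if (!is.null(region)) base <- base + cfg$region_temp_offsets[region]
  if (!is.null(year)) base <- base + cfg$temp_trend * (year - cfg$years[1])
  unname(base)
}

# reference curve used for centring planted anomalies: no offsets, no trend
reference_temp <- function(cfg, doy) {
  cfg$temp_ref + cfg$temp_amp * cos(2 * pi * (doy - cfg$temp_peak_day) / 365)
}

#' Generate the ground truth of a synthetic study
#'
#' Draws the yearly temperature anomalies, the snow-curve parameters and the
#' random components of the phenology construction, simulates the climate
#' (deterministically reproducible via the stored sub-seed), and computes the
#' true start and end day per year x region from the planted linear effect
#' structure.
#'
#' @param config A [synth_config()].
#' @param seed Master seed; all sub-stage seeds derive from it.
#' @return Object of class `synth_truth`: a list with `table` (one row per
#'   year x region: `year`, `region`, `true_start`, `true_end`, the causal
#'   window summaries, and the latent-curve parameters `m1`, `m2`),
#'   `config`, `seeds`, `year_anom`, and `snow` (per region-year melt-curve
#'   parameters).
#' @export
generate_truth <- function(config = synth_config(), seed = 1L) {
  cfg <- config
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$p_max > 0 && cfg$p_max <= cfg$tau)
    stopf("p_max (%.3f) must exceed the anchoring threshold tau (%.3f); the season would be undetectable by construction",
          cfg$p_max, cfg$tau)
  seeds <- list(truth = derive_seed(seed, 1L),
                climate = derive_seed(seed, 2L),
                obs = derive_seed(seed, 3L))
  ny <- length(cfg$years); nr <- length(cfg$regions)

  set.seed(seeds$truth)
  year_anom <- stats::rnorm(ny, 0, cfg$year_anom_sd)
  names(year_anom) <- as.character(cfg$years)
  u_year_start <- stats::rnorm(ny, 0, cfg$sd_year_start)
  u_year_end <- stats::rnorm(ny, 0, cfg$sd_year_end)
  v_region_start <- stats::rnorm(nr, 0, cfg$sd_region_start)
  v_region_end <- stats::rnorm(nr, 0, cfg$sd_region_end)
  eps_start <- matrix(stats::rnorm(ny * nr, 0, cfg$sd_resid), ny, nr)
  eps_end <- matrix(stats::rnorm(ny * nr, 0, cfg$sd_resid), ny, nr)
  snow_t50 <- outer(cfg$snow_temp_coupling * year_anom +
                      stats::rnorm(ny, 0, cfg$snow_t50_sd),
                    cfg$snow_region_offsets, "+") + cfg$snow_t50
  snow_span <- pmax(10, matrix(cfg$snow_span +
                                 stats::rnorm(ny * nr, 0, cfg$snow_span_sd),
                               ny, nr))
  snow <- data.frame(year = rep(cfg$years, nr),
                     region = rep(cfg$regions, each = ny),
                     t50 = as.vector(snow_t50),
                     span = as.vector(snow_span),
                     max = cfg$snow_max,
                     stringsAsFactors = FALSE)

  truth <- list(config = cfg, seeds = seeds, year_anom = year_anom,
                snow = snow)
  class(truth) <- "synth_truth"
  clim <- build_climate(truth, seeds$climate)

  win_mean <- function(win, value) {
    keep <- clim$day_of_year >= win[1] & clim$day_of_year <= win[2]
    tapply(value[keep], list(clim$year[keep], clim$region[keep]), mean)
  }
  t_start_w <- win_mean(cfg$window_T_start, clim$temp_mean)
  t_end_w <- win_mean(cfg$window_T_end, clim$temp_mean)
  keep <- clim$day_of_year >= cfg$window_P_start[1] &
    clim$day_of_year <= cfg$window_P_start[2]
  p_start_w <- tapply(clim$precip_sum[keep] >= 1,
                      list(clim$year[keep], clim$region[keep]), sum)
  # reorder tapply output (alphabetical) to the configured region order
  t_start_w <- t_start_w[as.character(cfg$years), cfg$regions, drop = FALSE]
  t_end_w <- t_end_w[as.character(cfg$years), cfg$regions, drop = FALSE]
  p_start_w <- p_start_w[as.character(cfg$years), cfg$regions, drop = FALSE]

  ref_T_start <- mean(reference_temp(cfg, seq(cfg$window_T_start[1],
                                              cfg$window_T_start[2])))
  ref_T_end <- mean(reference_temp(cfg, seq(cfg$window_T_end[1],
                                            cfg$window_T_end[2])))
  ref_P <- cfg$precip_occ_ref * (cfg$window_P_start[2] -
                                   cfg$window_P_start[1] + 1)

  start <- cfg$base_start +
    cfg$beta_T_start * (t_start_w - ref_T_start) +
    cfg$beta_P_start * (p_start_w - ref_P) +
    matrix(u_year_start, ny, nr) +
    matrix(v_region_start, ny, nr, byrow = TRUE) + eps_start
  end <- cfg$base_end +
    cfg$beta_T_end * (t_end_w - ref_T_end) +
    matrix(u_year_end, ny, nr) +
    matrix(v_region_end, ny, nr, byrow = TRUE) + eps_end
  start <- pmin(pmax(start, cfg$doy_range[1] + 1), cfg$doy_range[2] - 1)
  end <- pmin(pmax(end, cfg$doy_range[1] + 1), cfg$doy_range[2] - 1)
  if (any(start >= end))
    stopf("configuration produced true_start >= true_end for %d year x region cell(s)",
          sum(start >= end))

  tab <- data.frame(year = rep(cfg$years, nr),
                    region = rep(cfg$regions, each = ny),
                    true_start = as.vector(start),
                    true_end = as.vector(end),
                    temp_w_start = as.vector(t_start_w),
                    pdays_w_start = as.vector(p_start_w),
                    temp_w_end = as.vector(t_end_w),
                    stringsAsFactors = FALSE)
  anchors <- anchor_curve(tab$true_start, tab$true_end, cfg)
  tab$m1 <- anchors$m1
  tab$m2 <- anchors$m2
  truth$table <- tab
  truth
}

# Solve the double-logistic shifts so that p(d) = p_max * L1 * L2 crosses tau
# exactly at (start, end). Fixed-point iteration; converges in a handful of
# steps whenever tau < p_max and the season is longer than a few logistic
# scales.
anchor_curve <- function(start, end, cfg) {
  if (cfg$p_max <= 0)
    return(list(m1 = rep(NA_real_, length(start)),
                m2 = rep(NA_real_, length(start))))
  m1 <- start; m2 <- end
  for (i in 1:50) {
    q_a <- cfg$tau / (cfg$p_max * stats::plogis((m2 - start) / cfg$fall_scale))
    q_b <- cfg$tau / (cfg$p_max * stats::plogis((end - m1) / cfg$rise_scale))
    if (any(q_a >= 1 | q_b >= 1))
      stopf("latent curve cannot reach tau at the requested start/end; raise p_max or shorten the logistic scales")
    m1_new <- start - cfg$rise_scale * logit(q_a)
    m2_new <- end + cfg$fall_scale * logit(q_b)
    if (max(abs(m1_new - m1), abs(m2_new - m2)) < 1e-10) {
      m1 <- m1_new; m2 <- m2_new
      break
    }
    m1 <- m1_new; m2 <- m2_new
  }
  list(m1 = m1, m2 = m2)
}

#' Latent likely-breeding probability of a synthetic study
#'
#' Evaluates the planted rise--plateau--fall curve
#' `p(d) = p_max * plogis((d - m1)/rise) * plogis((m2 - d)/fall)` for one
#' year x region of a [generate_truth()] object. By construction
#' `p(true_start) = p(true_end) = tau`.
#'
#' @param truth A `synth_truth` object.
#' @param year,region Cell selector.
#' @param doy Numeric vector of days of year.
#' @return Probability vector.
#' @export
synth_prob <- function(truth, year, region, doy) {
  cfg <- truth$config
  row <- truth$table[truth$table$year == year & truth$table$region == region, ]
  if (nrow(row) != 1L) stopf("no truth row for year %s, region %s", year, region)
  if (cfg$p_max <= 0) return(rep(0, length(doy)))
  cfg$p_max * stats::plogis((doy - row$m1) / cfg$rise_scale) *
    stats::plogis((row$m2 - doy) / cfg$fall_scale)
}

# stationary AR(1) series with marginal SD `sd` and daily lag correlation
# exp(-1 / corr_length)
ar1_series <- function(n, sd, corr_length) {
  if (sd <= 0) return(rep(0, n))
  phi <- exp(-1 / corr_length)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
  for (t in 2:n) x[t] <- phi * x[t - 1] + innov[t - 1]
  x
}

# internal climate builder; truth carries all process parameters
build_climate <- function(truth, seed) {
  cfg <- truth$config
  set.seed(seed)
  doys <- seq(cfg$doy_range[1], cfg$doy_range[2])
  nd <- length(doys)
  # week-scale weather spells: one series per year shared by every region
  shared_spell <- lapply(cfg$years, function(yr)
    ar1_series(nd, cfg$spell_sd_shared, cfg$spell_corr_length))
  names(shared_spell) <- as.character(cfg$years)
  rows <- vector("list", length(cfg$regions) * length(cfg$years))
  k <- 0L
  for (rg in cfg$regions) {
    for (yr in cfg$years) {
      k <- k + 1L
      sn <- truth$snow[truth$snow$region == rg & truth$snow$year == yr, ]
      w <- sn$span / (logit(0.95) - logit(0.05))
      m <- if (sn$max > 0.5) sn$t50 - w * log(2 * sn$max - 1) else sn$t50
      temp <- seasonal_temp(cfg, doys, year = yr, region = rg) +
        truth$year_anom[as.character(yr)] +
        shared_spell[[as.character(yr)]] +
        ar1_series(nd, cfg$spell_sd_region, cfg$spell_corr_length) +
        stats::rnorm(nd, 0, cfg$temp_noise_sd)
      wet <- stats::rbinom(nd, 1L, cfg$precip_occ)
      amount <- stats::rgamma(nd, shape = cfg$precip_shape,
                              scale = cfg$precip_scale)
      snow <- sn$max / (1 + exp((doys - m) / w))
      rows[[k]] <- data.frame(region = rg,
                              date = date_from_doy(yr, doys),
                              year = yr,
                              day_of_year = doys,
                              temp_mean = round(temp, 3),
                              precip_sum = round(wet * amount, 3),
                              snow_cover_fraction = round(snow, 5),
                              stringsAsFactors = FALSE)
    }
  }
  clim <- do.call(rbind, rows)
  clim[order(clim$region, clim$date), , drop = FALSE]
}

#' Generate the daily climate table of a synthetic study
#'
#' Daily series Mar 1 -- Oct 31 per region x year: temperature is a seasonal
#' sinusoid plus region offset, warming trend, yearly anomaly, week-scale
#' AR(1) weather spells (regionally shared and region-specific), and
#' Gaussian daily noise; precipitation is Bernoulli occurrence times a
#' Gamma amount;
#' snow-cover fraction declines monotonically through the planted 50%-cover
#' day with the planted 95%-to-5% melt span. Fully deterministic given the
#' truth's stored sub-seed.
#'
#' @param truth A `synth_truth` object from [generate_truth()].
#' @param seed Seed; defaults to the sub-seed stored in `truth`, which
#'   reproduces the exact climate the truth was constructed from.
#' @return Climate data frame in the layout of [read_climate()].
#' @export
generate_climate <- function(truth, seed = truth$seeds$climate) {
  stopifnot(inherits(truth, "synth_truth"))
  build_climate(truth, seed)
}

#' Generate citizen-science observations of a synthetic study
#'
#' Draws effort-weighted observation dates per region-year over the season
#' domain, samples the latent likely-breeding state as Bernoulli(p(d)) from
#' the anchored curve, and assigns breeding codes consistent with the state
#' (likely-breeding rows receive courtship-or-higher codes). The recorded
#' `state` column is the classification a reader of the table would assign
#' via [classify_state()], so dates outside the May 1 -- Aug 31 season are
#' nonbreeding regardless of the latent draw.
#'
#' @param truth A `synth_truth` object.
#' @param climate Climate table (unused by the sampler; accepted so the
#'   call-site mirrors the data dependencies and can assert consistency).
#' @param seed Seed; defaults to the truth's observation sub-seed.
#' @return Observation data frame in the layout of [read_observations()].
#' @export
generate_observations <- function(truth, climate = NULL,
                                  seed = truth$seeds$obs) {
  stopifnot(inherits(truth, "synth_truth"))
  cfg <- truth$config
  if (all(cfg$effort <= 0))
    stopf("observation effort is zero everywhere; no observations can be generated")
  set.seed(seed)
  doys <- seq(cfg$doy_range[1], cfg$doy_range[2])
  wgt <- 1 + cfg$effort_bulge * exp(-((doys - 200) / 40)^2)
  lv <- cfg$map$levels
  cut_i <- match(cfg$map$cut, lv)
  hi_codes <- lv[cut_i:length(lv)]
  lo_codes <- lv[seq_len(cut_i - 1L)]
  out <- vector("list", nrow(truth$table))
  for (i in seq_len(nrow(truth$table))) {
    tr <- truth$table[i, ]
    n <- cfg$effort
    if (n <= 0) next
    d <- sort(sample(doys, n, replace = TRUE, prob = wgt))
    p <- synth_prob(truth, tr$year, tr$region, d)
    latent <- stats::rbinom(n, 1L, p) == 1L
    code <- character(n)
    code[latent] <- sample(hi_codes, sum(latent), replace = TRUE)
    absent <- !latent & stats::runif(n) < 0.7
    code[absent] <- NA_character_
    rest <- !latent & !absent
    code[rest] <- sample(lo_codes, sum(rest), replace = TRUE)
    date <- date_from_doy(tr$year, d)
    out[[i]] <- data.frame(date = date,
                           year = tr$year,
                           day_of_year = d,
                           region = tr$region,
                           breeding_code = code,
                           stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, out)
  obs$state <- classify_state(obs$breeding_code, obs$date, map = cfg$map)
  rownames(obs) <- NULL
  obs
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: truth, climate, and observations from one master
#' seed. `(config, seed)` fully determines every output.
#'
#' @param config A [synth_config()].
#' @param seed Master seed.
#' @return List with elements `truth`, `climate`, `observations`.
#' @examples
#' sim <- simulate_study(synth_config(years = 2006:2007,
#'                                    regions = c("northern", "southern"),
#'                                    effort = 50), seed = 1)
#' nrow(sim$observations)
#' @export
simulate_study <- function(config = synth_config(), seed = 1L) {
  truth <- generate_truth(config, seed)
  climate <- generate_climate(truth)
  observations <- generate_observations(truth, climate)
  list(truth = truth, climate = climate, observations = observations)
}
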