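# end-to-end orchestration: simulate/read -> phenology -> metrics -> snow ->
# window scan -> effects models -> trend, with a machine-readable manifest

#' Analysis run configuration
#'
#' Collects every analysis constant of the pipeline in one place, with the
#' standard values as defaults: May 1 -- Aug 31 breeding-evidence season, 5%
#' phenology threshold with a 1%--12% sensitivity ladder, 7-day minimum
#' window slid by 2 days, Apr 1 -- Jun 30 (start) and Apr 15 -- Aug 15 (end)
#' search ranges, 1 mm precipitation-day threshold, 50% absolute snowmelt
#' timing with 95%/5%-of-maximum duration thresholds, and the sampler
#' budgets. Nothing is hard-coded in the stage functions.
#'
#' @param observations,climate Paths to input CSVs, or `NULL` when
#'   `simulate` is `TRUE`.
#' @param output_dir Directory for stage outputs and the manifest.
#' @param simulate Generate the inputs with [simulate_study()]?
#' @param synth A [synth_config()] used when simulating.
#' @param regions,years Region set and study years (`NULL`: all present in
#'   the inputs).
#' @param tau Phenology threshold.
#' @param tau_sensitivity Thresholds of the sensitivity analysis.
#' @param window_range_start,window_range_end Day-of-year search ranges for
#'   the start and end responses.
#' @param window_min_len,window_step Window enumeration parameters.
#' @param precip_mm Precipitation-day threshold (mm).
#' @param snow_threshold,snow_hi,snow_lo Snowmelt thresholds.
#' @param n_knots Phenology basis dimension control.
#' @param gam_method,gam_ndraws,gam_chains,gam_iter,gam_thin Phenology
#'   sampler budget.
#' @param lmm_engine,lmm_chains,lmm_iter Effects-model budget.
#' @param trend_region Region whose phenology defines the breeding-season
#'   temperature series of the trend analysis.
#' @param seed Master seed; every stage seed derives from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(observations = NULL, climate = NULL,
                       output_dir = tempfile("snowphen_run_"),
                       simulate = is.null(observations),
                       synth = synth_config(),
                       regions = default_regions(),
                       years = NULL,
                       tau = 0.05,
                       tau_sensitivity = seq(0.01, 0.12, by = 0.01),
                       window_range_start = c(91, 181),
                       window_range_end = c(105, 227),
                       window_min_len = 7,
                       window_step = 2,
                       precip_mm = 1,
                       snow_threshold = 0.5,
                       snow_hi = 0.95,
                       snow_lo = 0.05,
                       n_knots = 12,
                       gam_method = "laplace",
                       gam_ndraws = 1000,
                       gam_chains = 4, gam_iter = 8000, gam_thin = 4,
                       lmm_engine = "sim",
                       lmm_chains = 4, lmm_iter = 2000,
                       trend_region = "eastern",
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$simulate) {
    cfg$regions <- cfg$synth$regions
    if (is.null(cfg$years)) cfg$years <- cfg$synth$years
  }
  structure(cfg, class = "run_config")
}

#' Validate a run configuration
#'
#' Checks every structural invariant and returns the violations as a
#' character vector (empty when the configuration is valid); it never
#' throws.
#'
#' @param config A [run_config()].
#' @return Character vector of human-readable violation messages.
#' @export
validate_config <- function(config) {
  v <- character()
  bad_range <- function(r) length(r) != 2L || any(is.na(r)) || r[2] <= r[1]
  if (!isTRUE(config$simulate)) {
    if (is.null(config$observations))
      v <- c(v, "observations path is missing and simulate is FALSE")
    if (is.null(config$climate))
      v <- c(v, "climate path is missing and simulate is FALSE")
  }
  if (is.null(config$years) || length(config$years) == 0L)
    v <- c(v, "no study years configured")
  if (!is.numeric(config$tau) || config$tau < 0 || config$tau >= 1)
    v <- c(v, sprintf("threshold tau = %s outside [0, 1)", config$tau))
  if (any(config$tau_sensitivity <= 0 | config$tau_sensitivity >= 1))
    v <- c(v, "sensitivity thresholds must lie in (0, 1)")
  if (bad_range(config$window_range_start))
    v <- c(v, "start-response window range end must be after its start")
  if (bad_range(config$window_range_end))
    v <- c(v, "end-response window range end must be after its start")
  if (config$window_min_len < 1)
    v <- c(v, "minimum window length must be >= 1 day")
  if (config$window_step < 1)
    v <- c(v, "window step must be >= 1 day")
  if (config$precip_mm < 0)
    v <- c(v, "precipitation-day threshold must be non-negative")
  if (config$snow_threshold <= 0 || config$snow_threshold >= 1)
    v <- c(v, "snow timing threshold must lie in (0, 1)")
  if (config$snow_lo >= config$snow_hi)
    v <- c(v, "snow duration thresholds need lo < hi")
  if (config$n_knots < 4) v <- c(v, "n_knots must be >= 4")
  if (!config$gam_method %in% c("laplace", "mcmc"))
    v <- c(v, sprintf("unknown gam method '%s'", config$gam_method))
  v
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the complete analysis pipeline
#'
#' Executes every stage in order -- simulate (optional), per-year phenology
#' GAMs, threshold metrics and sensitivity, snowmelt metrics, window scans
#' for both responses and both climate variables, critical-window
#' selection, the three effects models (start, end, duration), and the two
#' temperature-trend regressions -- writing each stage's table as CSV into
#' the output directory plus a JSON manifest with seeds, the configuration
#' hash, per-stage warnings, and the checksums of every output file. The
#' run is fully reproducible from `(config, seed)`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all stage results (`truth` when
#'   simulated, `metrics`, `snow`, `scans`, `selection`, `effects`,
#'   `trend`, `manifest`).
#' @export
run_all <- function(config = run_config()) {
  t_start <- Sys.time()
  problems <- validate_config(config)
  if (length(problems))
    stopf("invalid configuration:\n  - %s", paste(problems, collapse = "\n  - "))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- list()
  note <- function(stage, w) {
    warnings_log[[stage]] <<- c(warnings_log[[stage]], w)
    warnf("[%s] %s", stage, w)
  }
  catch_warn <- function(stage, expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log[[stage]] <<- c(warnings_log[[stage]],
                                  conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  run_stage <- function(stage, expr) {
    stage_log(stage, "starting")
    tryCatch(catch_warn(stage, expr), error = function(e) {
      stopf("pipeline stage '%s' failed: %s (earlier stage outputs remain in %s)",
            stage, conditionMessage(e), config$output_dir)
    })
  }
  out_files <- character()
  emit <- function(df, name) {
    path <- file.path(config$output_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    out_files <<- c(out_files, path)
    path
  }
  res <- list(config = config)

  # ---- inputs ----
  if (config$simulate) {
    sim <- run_stage("simulate", {
      s <- simulate_study(config$synth, seed = derive_seed(config$seed, 10L))
      write_observations(s$observations,
                         file.path(config$output_dir, "observations.csv"))
      write_climate(s$climate, file.path(config$output_dir, "climate.csv"))
      utils::write.csv(s$truth$table,
                       file.path(config$output_dir, "truth.csv"),
                       row.names = FALSE)
      s
    })
    out_files <- c(out_files,
                   file.path(config$output_dir,
                             c("observations.csv", "climate.csv",
                               "truth.csv")))
    obs <- sim$observations
    clim <- sim$climate
    res$truth <- sim$truth
  } else {
    obs <- run_stage("read", read_observations(config$observations,
                                               regions = config$regions,
                                               quiet = TRUE))
    clim <- run_stage("read", read_climate(config$climate,
                                           regions = config$regions))
  }
  years <- intersect(config$years, unique(obs$year))
  if (length(years) == 0L) stopf("no configured year present in the data")

  # ---- phenology ----
  basis <- cyclic_basis(n_knots = config$n_knots)
  phen <- run_stage("fit-phenology", {
    fit_phenology_all(obs, years = years, basis = basis,
                      regions = config$regions,
                      method = config$gam_method,
                      ndraws = config$gam_ndraws,
                      chains = config$gam_chains, iter = config$gam_iter,
                      thin = config$gam_thin,
                      seed = derive_seed(config$seed, 20L))
  })
  res$fits <- phen$fits
  res$curves <- phen$curves
  curve_summary <- do.call(rbind, lapply(phen$curves, function(cv) {
    qs <- apply(cv$draws, 2, stats::quantile, probs = c(0.025, 0.975))
    data.frame(year = cv$year, region = cv$region, doy = cv$doy,
               p_mean = cv$mean, p_lo = qs[1, ], p_hi = qs[2, ])
  }))
  emit(curve_summary, "phenology_curves.csv")

  # ---- metrics ----
  res$metrics <- run_stage("metrics", phenology_metrics(phen$curves,
                                                        tau = config$tau))
  emit(res$metrics, "phenology_metrics.csv")
  res$sensitivity <- run_stage("metrics",
                               threshold_sensitivity(phen$curves,
                                                     taus = config$tau_sensitivity,
                                                     reference = config$tau))
  emit(res$sensitivity, "threshold_sensitivity.csv")

  # ---- snow ----
  res$snow <- run_stage("snow-metrics",
                        snow_metrics(clim, threshold = config$snow_threshold,
                                     hi = config$snow_hi,
                                     lo = config$snow_lo))
  emit(res$snow, "snow_metrics.csv")

  # ---- window scans ----
  res$scans <- list()
  res$selection <- list()
  scan_spec <- list(
    start_temp = list(response = "start", variable = "mean_temperature",
                      range = config$window_range_start),
    start_precip = list(response = "start", variable = "precipitation_days",
                        range = config$window_range_start),
    end_temp = list(response = "end", variable = "mean_temperature",
                    range = config$window_range_end),
    end_precip = list(response = "end", variable = "precipitation_days",
                      range = config$window_range_end))
  for (nm in names(scan_spec)) {
    sp <- scan_spec[[nm]]
    res$scans[[nm]] <- run_stage("scan-windows", {
      wins <- enumerate_windows(sp$range, min_len = config$window_min_len,
                                step = config$window_step)
      correlation_scan(res$metrics, clim, wins, variable = sp$variable,
                       response = sp$response, precip_mm = config$precip_mm)
    })
    res$selection[[nm]] <- select_best_window(res$scans[[nm]])
    emit(scan_heatmap_table(res$scans[[nm]]), sprintf("scan_%s.csv", nm))
  }
  sel_tab <- do.call(rbind, lapply(names(res$selection), function(nm) {
    s <- res$selection[[nm]]
    data.frame(scan = nm, selected = s$selected,
               open = if (s$selected) s$open else NA,
               close = if (s$selected) s$close else NA,
               r = if (s$selected) s$r else NA)
  }))
  emit(sel_tab, "selected_windows.csv")

  # ---- effects models ----
  n_cells <- sum(!is.na(res$metrics$start))
  if (n_cells < 10L) {
    note("fit-effects",
         sprintf("skipped: %d year x region cells with defined phenology (>= 10 required)",
                 n_cells))
    res$effects <- NULL
  } else
  res$effects <- run_stage("fit-effects", {
    mk_cov <- function(sel, variable, fallback_range) {
      win <- if (sel$selected) c(sel$open, sel$close) else fallback_range
      window_summary(clim, win, variable, precip_mm = config$precip_mm)
    }
    tab <- res$metrics[, c("year", "region", "start", "end", "duration")]
    add <- function(tab, s, nm) {
      names(s)[names(s) == "value"] <- nm
      merge(tab, s, by = c("year", "region"), all.x = TRUE)
    }
    tab <- add(tab, mk_cov(res$selection$start_temp, "mean_temperature",
                           config$window_range_start), "temp_start_win")
    tab <- add(tab, mk_cov(res$selection$start_precip, "precipitation_days",
                           config$window_range_start), "pdays_start_win")
    tab <- add(tab, mk_cov(res$selection$end_temp, "mean_temperature",
                           config$window_range_end), "temp_end_win")
    tab <- merge(tab, res$snow[, c("year", "region", "melt_timing",
                                   "melt_duration")],
                 by = c("year", "region"), all.x = TRUE)
    seed_lmm <- derive_seed(config$seed, 30L)
    list(
      data = tab,
      start = fit_lmm(tab, "start",
                      c("temp_start_win", "pdays_start_win", "melt_timing"),
                      interaction = c("temp_start_win", "pdays_start_win"),
                      engine = config$lmm_engine,
                      chains = config$lmm_chains, iter = config$lmm_iter,
                      seed = seed_lmm),
      end = fit_lmm(tab, "end",
                    c("temp_end_win", "melt_timing", "melt_duration"),
                    engine = config$lmm_engine,
                    chains = config$lmm_chains, iter = config$lmm_iter,
                    seed = seed_lmm + 1L),
      duration = fit_lmm(tab, "duration",
                         c("temp_start_win", "pdays_start_win",
                           "temp_end_win"),
                         interaction = c("temp_start_win", "pdays_start_win"),
                         engine = config$lmm_engine,
                         chains = config$lmm_chains, iter = config$lmm_iter,
                         seed = seed_lmm + 2L))
  })
  if (!is.null(res$effects))
    for (nm in c("start", "end", "duration"))
      emit(res$effects[[nm]]$table, sprintf("effects_%s.csv", nm))

  # ---- temperature trends ----
  if (length(years) < 3L) {
    note("trend", sprintf("skipped: %d study year(s) (>= 3 required)",
                          length(years)))
    res$trend <- NULL
  } else
  res$trend <- run_stage("trend", {
    m <- res$metrics[res$metrics$region == config$trend_region, ]
    season_temp <- mapply(function(yr, s, e)
      breeding_season_mean_temp(clim, yr, config$trend_region, s, e),
      m$year, m$start, m$end)
    summer_temp <- vapply(years, function(yr) {
      keep <- clim$year == yr & clim$region == config$trend_region &
        clim$day_of_year >= 121 & clim$day_of_year <= 243
      mean(clim$temp_mean[keep])
    }, numeric(1))
    list(breeding_season = fit_trend(m$year, season_temp),
         may_aug = fit_trend(years, summer_temp),
         table = data.frame(year = years,
                            breeding_season_temp = season_temp[match(years, m$year)],
                            may_aug_temp = summer_temp))
  })
  if (!is.null(res$trend)) emit(res$trend$table, "trend_series.csv")

  # ---- manifest ----
  cfg_file <- file.path(config$output_dir, "config.yaml")
  cfg_plain <- config
  cfg_plain$synth <- unclass(cfg_plain$synth)
  cfg_plain$synth$map <- unclass(cfg_plain$synth$map)
  yaml::write_yaml(lapply(unclass(cfg_plain), function(x)
    if (is.function(x)) NULL else x), cfg_file)
  out_files <- c(out_files, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("snowphen")),
    r_version = as.character(getRversion()),
    created = format(t_start, "%Y-%m-%d %H:%M:%S"),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    stages = c("simulate"[config$simulate], "fit-phenology", "metrics",
               "snow-metrics", "scan-windows", "fit-effects", "trend"),
    warnings = warnings_log,
    files = lapply(stats::setNames(out_files, basename(out_files)),
                   function(f) list(path = f,
                                    md5 = unname(tools::md5sum(f)))))
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  res$manifest <- manifest
  stage_log("done", "all stages complete; outputs in %s", config$output_dir)
  invisible(res)
}
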