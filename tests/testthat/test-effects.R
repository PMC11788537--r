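# deterministic-ish LMM test data with known structure
effects_test_data <- function(seed = 1, n_year = 8, n_region = 4,
                              b_temp = -6, b_pdays = 3.7, sd_year = 3,
                              sd_region = 4, sd_eps = 2) {
  set.seed(seed)
  g <- expand.grid(year = 2000 + seq_len(n_year),
                   region = paste0("r", seq_len(n_region)))
  g$temp <- rnorm(nrow(g), 8, 1.5)
  g$pdays <- rpois(nrow(g), 6)
  g$melt <- rnorm(nrow(g), 150, 10)
  u <- rnorm(n_year, 0, sd_year)[match(g$year, unique(g$year))]
  v <- rnorm(n_region, 0, sd_region)[match(g$region, unique(g$region))]
  g$start <- 142 + b_temp * (g$temp - 8) + b_pdays * (g$pdays - 6) +
    u + v + rnorm(nrow(g), 0, sd_eps)
  g
}

test_that("standardized and unstandardized coefficients obey the SD identity", {
  dat <- effects_test_data()
  fit <- fit_lmm(dat, "start", c("temp", "pdays", "melt"),
                 interaction = c("temp", "pdays"),
                 retain_interaction = "always", seed = 4)
  tab <- coef(fit)
  for (i in seq_len(nrow(tab))) {
    tm <- tab$term[i]
    if (tm == "(Intercept)") {
      expect_true(is.na(tab$unstd[i]))
      next
    }
    sdx <- if (grepl(":", tm)) sd(dat$temp) * sd(dat$pdays)
           else sd(dat[[tm]])
    expect_equal(tab$std[i], tab$unstd[i] * sdx, tolerance = 1e-6)
    expect_lte(tab$std_lo[i], tab$std[i])
    expect_gte(tab$std_hi[i], tab$std[i])
  }
  # rescaling a predictor (x -> 2x, doubling its spread) leaves the
  # standardized slope unchanged and exactly halves the per-raw-unit slope
  dat2 <- dat
  dat2$temp <- dat$temp * 2
  fit2 <- fit_lmm(dat2, "start", c("temp", "pdays", "melt"),
                  retain_interaction = "never", engine = "reml")
  fit1 <- fit_lmm(dat, "start", c("temp", "pdays", "melt"),
                  retain_interaction = "never", engine = "reml")
  i <- match("temp", fit1$table$term)
  expect_equal(fit2$table$std[i], fit1$table$std[i], tolerance = 1e-6)
  expect_equal(fit2$table$unstd[i], fit1$table$unstd[i] / 2,
               tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with informative errors", {
  dat <- effects_test_data()
  dat$flat <- 5
  expect_error(fit_lmm(dat, "start", c("temp", "flat")), "flat")
  expect_error(fit_lmm(dat[1:6, ], "start", "temp"), "10")
  expect_error(fit_lmm(dat, "start", c("temp"), interaction = c("temp", "pdays")),
               "among the covariates")
  dat$temp[1:3] <- NA
  expect_warning(fit_lmm(dat, "start", c("temp", "pdays")), "dropped")
})

test_that("with zero random-effect variance the LMM reduces to OLS", {
  # no grouping structure in the signal: both variance estimates collapse
  # to the boundary, where the mixed model is ordinary least squares
  dat <- effects_test_data(seed = 2, sd_year = 0, sd_region = 0, sd_eps = 1)
  fit <- fit_lmm(dat, "start", c("temp", "pdays"), engine = "reml")
  expect_true(all(fit$re_sd == 0))
  expect_true(fit$singular)
  zt <- scale(dat$temp); zp <- scale(dat$pdays)
  ols <- lm(dat$start ~ zt + zp)
  expect_equal(unname(fit$coef_std),
               unname(coef(ols)), tolerance = 1e-6)
})

test_that("per-unit effects and scenario contrasts are linear algebra on the fit", {
  dat <- effects_test_data(seed = 5)
  fit <- fit_lmm(dat, "start", c("temp", "pdays", "melt"),
                 retain_interaction = "never", seed = 9)
  i <- match("temp", fit$table$term)
  slope <- fit$table$unstd[i]
  e1 <- effect_per_unit(fit, "temp", delta = 1)
  expect_equal(e1$estimate, slope, tolerance = 1e-12)
  e10 <- effect_per_unit(fit, "temp", delta = -10)
  expect_equal(e10$estimate, -10 * slope, tolerance = 1e-12)
  expect_lt(e1$lo, e1$estimate); expect_gt(e1$hi, e1$estimate)
  e0 <- effect_per_unit(fit, "temp", delta = 0)
  expect_equal(e0$estimate, 0)
  expect_error(effect_per_unit(fit, "humidity"), "humidity")

  # identical scenarios give exactly zero
  sc <- c(temp = 8, pdays = 6, melt = 150)
  z <- scenario_contrast(fit, sc, sc)
  expect_equal(z$estimate, 0)
  # additive model: contrast equals the sum of per-covariate effects
  sc_a <- c(temp = 6, pdays = 10, melt = 150)
  sc_b <- c(temp = 9, pdays = 4, melt = 155)
  ctr <- scenario_contrast(fit, sc_a, sc_b)
  manual <- sum(fit$table$unstd[-1] * (sc_a - sc_b)[fit$covariates])
  expect_equal(ctr$estimate, manual, tolerance = 1e-10)
  expect_lt(ctr$lo, ctr$estimate); expect_gt(ctr$hi, ctr$estimate)
  # extrapolation warns but does not error
  expect_warning(scenario_contrast(fit, c(temp = 50, pdays = 6, melt = 150),
                                   sc), "outside the observed range")
})

test_that("planted slopes are recovered with interval coverage", {
  hits <- 0L
  for (rep in 1:20) {
    dat <- effects_test_data(seed = 100 + rep, n_year = 16, n_region = 4)
    fit <- fit_lmm(dat, "start", c("temp", "pdays", "melt"),
                   engine = "reml")
    i <- match("temp", fit$table$term)
    hits <- hits + (fit$table$unstd_lo[i] <= -6 &&
                      -6 <= fit$table$unstd_hi[i])
  }
  expect_gte(hits, 16)
})

test_that("temperature trends report slope and span change", {
  yrs <- 2006:2021
  # noiseless fixtures trigger the perfect-fit note from summary.lm
  tr <- suppressWarnings(fit_trend(yrs, 5 + 0.1 * (yrs - 2006)))
  expect_equal(tr$slope, 0.1, tolerance = 1e-10)
  expect_equal(tr$total_change, 1.5, tolerance = 1e-10)
  flat <- suppressWarnings(fit_trend(yrs, rep(4, 16)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$total_change, 0)
  expect_error(fit_trend(rep(2010, 5), rnorm(5)), "same year")
  expect_error(fit_trend(2010:2011, c(1, 2)), "3 years")
  expect_output(print(tr), "degC/yr")
})

test_that("breeding-season mean temperature averages the season window", {
  clim <- data.frame(region = "eastern", year = 2015,
                     day_of_year = 60:304,
                     temp_mean = (60:304) / 10,
                     precip_sum = 0, snow_cover_fraction = 0,
                     date = as.Date("2015-01-01") + 59:303)
  expect_equal(breeding_season_mean_temp(clim, 2015, "eastern", 139, 231),
               18.5)
  const <- clim; const$temp_mean <- 5
  expect_equal(breeding_season_mean_temp(const, 2015, "eastern", 139, 231), 5)
  expect_true(is.na(breeding_season_mean_temp(clim, 2015, "eastern", NA, 231)))
  # a season shrunk symmetrically about the warm peak has a higher mean
  peaky <- clim
  peaky$temp_mean <- 10 * exp(-((peaky$day_of_year - 185) / 40)^2)
  wide <- breeding_season_mean_temp(peaky, 2015, "eastern", 139, 231)
  narrow <- breeding_season_mean_temp(peaky, 2015, "eastern", 165, 205)
  expect_gt(narrow, wide)
})
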