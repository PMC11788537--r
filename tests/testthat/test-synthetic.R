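test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- mini_synth_config()
  a <- simulate_study(cfg, seed = 7)
  b <- simulate_study(cfg, seed = 7)
  expect_identical(a$truth$table, b$truth$table)
  expect_identical(a$climate, b$climate)
  expect_identical(a$observations, b$observations)
  c <- simulate_study(cfg, seed = 8)
  expect_false(identical(a$observations, c$observations))
})

test_that("truth construction is the planted linear model", {
  # all betas and SDs zero -> identical start/end everywhere
  cfg0 <- mini_synth_config(beta_T_start = 0, beta_P_start = 0,
                            beta_T_end = 0, sd_year_start = 0,
                            sd_region_start = 0, sd_year_end = 0,
                            sd_region_end = 0, sd_resid = 0)
  tr0 <- generate_truth(cfg0, seed = 11)
  expect_equal(unique(tr0$table$true_start), cfg0$base_start)
  expect_equal(unique(tr0$table$true_end), cfg0$base_end)

  # a uniform +1 degC shift moves every start by beta_T_start days
  cfg1 <- mini_synth_config(beta_T_start = -6, beta_P_start = 0,
                            beta_T_end = 0, sd_year_start = 0,
                            sd_region_start = 0, sd_year_end = 0,
                            sd_region_end = 0, sd_resid = 0,
                            temp_noise_sd = 0, temp_trend = 0,
                            year_anom_sd = 0)
  cfg2 <- mini_synth_config(beta_T_start = -6, beta_P_start = 0,
                            beta_T_end = 0, sd_year_start = 0,
                            sd_region_start = 0, sd_year_end = 0,
                            sd_region_end = 0, sd_resid = 0,
                            temp_noise_sd = 0, temp_trend = 0,
                            year_anom_sd = 0,
                            temp_mean = 3, temp_ref = 2)
  t1 <- generate_truth(cfg1, seed = 5)$table
  t2 <- generate_truth(cfg2, seed = 5)$table
  expect_equal(t2$true_start, t1$true_start - 6, tolerance = 1e-10)
  expect_equal(t2$true_end, t1$true_end, tolerance = 1e-10)

  # study scale: 16 years x 4 regions -> 64 truth rows
  tr <- generate_truth(synth_config(), seed = 1)
  expect_identical(nrow(tr$table), 64L)
  expect_true(all(tr$table$true_start < tr$table$true_end))
  expect_true(all(tr$table$true_start >= 60 & tr$table$true_end <= 304))
})

test_that("undetectable configurations are rejected", {
  expect_error(generate_truth(mini_synth_config(p_max = 0.04, tau = 0.05)),
               "undetectable")
})

test_that("the latent curve is anchored at tau exactly at the true start and end", {
  sim <- mini_study()
  tr <- sim$truth$table
  cfg <- sim$truth$config
  for (i in c(1, 4, nrow(tr))) {
    p_start <- synth_prob(sim$truth, tr$year[i], tr$region[i], tr$true_start[i])
    p_end <- synth_prob(sim$truth, tr$year[i], tr$region[i], tr$true_end[i])
    expect_equal(p_start, cfg$tau, tolerance = 1e-8)
    expect_equal(p_end, cfg$tau, tolerance = 1e-8)
  }
  # plateau approaches p_max mid-season
  mid <- (tr$true_start[1] + tr$true_end[1]) / 2
  expect_gt(synth_prob(sim$truth, tr$year[1], tr$region[1], mid),
            0.9 * cfg$p_max)
})

test_that("generated climate honours the planted snow curve and precipitation", {
  cfg <- mini_synth_config(snow_t50 = 150, snow_t50_sd = 0,
                           snow_temp_coupling = 0,
                           snow_region_offsets = c(northern = 0, southern = 0),
                           snow_span_sd = 0)
  sim <- simulate_study(cfg, seed = 13)
  one <- sim$climate[sim$climate$year == 2014 &
                       sim$climate$region == "northern", ]
  one <- one[order(one$day_of_year), ]
  # planted 50%-crossing day: first day at or below 0.5 absolute cover
  first_le <- one$day_of_year[which(one$snow_cover_fraction <= 0.5)[1]]
  expect_equal(first_le, 150)

  # no precipitation at occurrence probability zero
  dry <- simulate_study(mini_synth_config(precip_occ = 0, beta_P_start = 0),
                        seed = 3)
  expect_true(all(dry$climate$precip_sum == 0))

  # climate table satisfies the reader's invariants
  expect_silent(snowphen:::validate_climate(sim$climate))
})

test_that("observation tables have the configured size and coherent states", {
  sim <- mini_study()
  obs <- sim$observations
  cfg <- sim$truth$config
  expect_equal(nrow(obs),
               length(cfg$years) * length(cfg$regions) * cfg$effort)
  # states equal what the classifier assigns to the emitted codes/dates
  expect_identical(obs$state, classify_state(obs$breeding_code, obs$date,
                                             map = cfg$map))
  # p_max = 0 -> no likely-breeding observations
  none <- simulate_study(mini_synth_config(p_max = 0), seed = 2)
  expect_identical(sum(none$observations$state == "likely_breeding"), 0L)
  expect_error(generate_observations(
    generate_truth(mini_synth_config(effort = 0), seed = 1)),
    "effort")
})

test_that("empirical state frequency converges to the latent curve at high effort", {
  cfg <- synth_config(years = 2015, regions = "northern",
                      effort = 10000,
                      region_temp_offsets = c(northern = 0),
                      snow_region_offsets = c(northern = 0))
  sim <- simulate_study(cfg, seed = 21)
  obs <- sim$observations
  # mid-season bins, away from the May 1 season-window truncation
  for (bin_mid in c(160, 185, 210)) {
    rows <- abs(obs$day_of_year - bin_mid) <= 3
    n <- sum(rows)
    phat <- mean(obs$state[rows] == "likely_breeding")
    p_true <- mean(synth_prob(sim$truth, 2015, "northern",
                              (bin_mid - 3):(bin_mid + 3)))
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(phat - p_true), 3 * se + 1e-12)
  }
})

test_that("window summaries of generated climate reproduce planted anomalies", {
  # spell processes off: this checks the sinusoid + year-anomaly backbone
  cfg <- mini_synth_config(temp_trend = 0, temp_noise_sd = 1,
                           spell_sd_shared = 0, spell_sd_region = 0)
  tr <- generate_truth(cfg, seed = 17)
  clim <- generate_climate(tr)
  win <- cfg$window_T_start
  len <- win[2] - win[1] + 1
  for (yr in cfg$years) {
    keep <- clim$year == yr & clim$region == "northern" &
      clim$day_of_year >= win[1] & clim$day_of_year <= win[2]
    observed <- mean(clim$temp_mean[keep])
    expected <- mean(snowphen:::seasonal_temp(cfg, win[1]:win[2],
                                              year = yr,
                                              region = "northern")) +
      tr$year_anom[as.character(yr)]
    se <- cfg$temp_noise_sd / sqrt(len)
    expect_lt(abs(observed - expected), 4 * se)
  }
})
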