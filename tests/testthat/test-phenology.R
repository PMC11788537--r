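# a minimal hand-made fit object for curve-algebra tests
fake_fit <- function(coefs, ndraws = 3, basis = cyclic_basis(),
                     regions = c("northern", "southern")) {
  des <- phenology_design(basis, 100, "northern", regions)
  p <- ncol(des$X) + 1L
  stopifnot(length(coefs) == p)
  structure(list(year = 2015, coefficients = coefs,
                 Vp = diag(p) * 0, sp = c(1, 1, 1),
                 draws = matrix(rep(coefs, each = ndraws), nrow = ndraws),
                 basis = basis, Z = des$Z, regions = regions,
                 idx_global = des$idx_global, idx_region = des$idx_region,
                 method = "laplace", converged = TRUE, degenerate = FALSE,
                 rhat = NA_real_, nobs = 1L, n_likely = 0L,
                 data = data.frame(day_of_year = 100, region = "northern",
                                   y = 0L),
                 fitted_p = 0.5),
            class = "phenology_fit")
}

test_that("all-zero coefficients give a flat curve at one half", {
  b <- cyclic_basis()
  des <- phenology_design(b, 100, "northern", c("northern", "southern"))
  fit <- fake_fit(rep(0, ncol(des$X) + 1L), basis = b)
  cv <- expected_proportion_curve(fit, "northern")
  expect_equal(unique(as.vector(cv$draws)), 0.5)
  expect_equal(cv$mean, rep(0.5, length(cv$doy)))
  # curves are probabilities on the complete daily grid
  expect_equal(cv$doy, 60:304)
  expect_error(expected_proportion_curve(fit, "alpine"), "alpine")
})

test_that("degenerate all-nonbreeding data yield a near-zero curve", {
  set.seed(31)
  n <- 500
  d <- sample(60:304, n, replace = TRUE)
  obs <- data.frame(
    date = as.Date(d - 1, origin = "2015-01-01"),
    year = 2015,
    day_of_year = d,
    region = sample(c("northern", "southern"), n, replace = TRUE),
    breeding_code = NA_character_, state = "nonbreeding",
    stringsAsFactors = FALSE)
  fit <- fit_phenology_gam(obs, year = 2015,
                           regions = c("northern", "southern"), seed = 1)
  expect_true(fit$degenerate)
  cv <- expected_proportion_curve(fit, "northern", force = TRUE)
  expect_lt(max(cv$mean), 0.05)
})

test_that("the fitted curve recovers a planted season", {
  cfg <- synth_config(years = 2012, regions = default_regions(),
                      effort = 400)
  sim <- simulate_study(cfg, seed = 61)
  fit <- fit_phenology_gam(sim$observations, year = 2012, seed = 8)
  expect_true(fit$converged)
  expect_gte(nrow(fit$draws), 1000)
  # per-cell crossings carry ~5 days of sampling noise even at this effort;
  # the informative check is the mean error across regions
  err_s <- err_e <- numeric(0)
  for (rg in default_regions()) {
    tr <- sim$truth$table[sim$truth$table$region == rg, ]
    cv <- expected_proportion_curve(fit, rg)
    st <- extract_start(cv, 0.05)
    en <- extract_end(cv, 0.05, start = st)
    err_s <- c(err_s, st$day - tr$true_start)
    err_e <- c(err_e, en$day - tr$true_end)
  }
  expect_lt(mean(abs(err_s)), 6)
  expect_lt(mean(abs(err_e)), 8)
})

test_that("a region without observations inherits the global curve", {
  sim <- mini_study()
  obs <- sim$observations[sim$observations$year == 2015, ]
  obs <- obs[obs$region != "southern", ]
  fit <- fit_phenology_gam(obs, year = 2015,
                           regions = c("northern", "southern"), seed = 3)
  cv_n <- expected_proportion_curve(fit, "northern")
  cv_s <- expected_proportion_curve(fit, "southern")
  # the empty region's deviation smoother is shrunk to ~0, so its curve
  # follows the (global + northern-deviation-free) shape; compare the
  # southern curve to the global component alone
  Xg <- cbind(1, basis_matrix(fit$basis, cv_s$doy) %*% fit$Z)
  eta_global <- as.vector(Xg %*%
                            fit$coefficients[c(1, 1 + fit$idx_global)])
  expect_lt(max(abs(plogis(eta_global) - cv_s$mean)), 0.02)
  expect_gt(max(abs(plogis(eta_global) - cv_n$mean)), 0.0)
})

test_that("an infinite penalty flattens the curve to the mean frequency", {
  sim <- mini_study()
  obs <- sim$observations[sim$observations$year == 2016 &
                            sim$observations$region == "northern", ]
  fit <- fit_phenology_gam(obs, year = 2016, regions = "northern",
                           sp = c(1e9, 1e9, 1e9), seed = 2)
  cv <- expected_proportion_curve(fit, "northern")
  freq <- mean(obs$state == "likely_breeding")
  expect_lt(diff(range(cv$mean)), 1e-3)
  expect_equal(mean(cv$mean), freq, tolerance = 0.01)
})

test_that("the penalized fit matches a direct optimizer of the same objective", {
  sim <- mini_study()
  obs <- sim$observations[sim$observations$year == 2015, ]
  sp_fixed <- c(2, 2, 2)
  fit <- fit_phenology_gam(obs, year = 2015,
                           regions = c("northern", "southern"),
                           sp = sp_fixed, seed = 1)
  des <- phenology_design(fit$basis, obs$day_of_year, obs$region,
                          c("northern", "southern"))
  X <- cbind(1, des$X)
  y <- as.integer(obs$state == "likely_breeding")
  objective <- function(beta) {
    eta <- as.vector(X %*% beta)
    dev <- -2 * sum(y * eta - log1p(exp(eta)))
    pen <- 0
    for (i in seq_along(des$penalties)) {
      b <- beta[-1]
      pen <- pen + sp_fixed[i] * sum(b * (des$penalties[[i]] %*% b))
    }
    dev + pen
  }
  opt <- optim(fit$coefficients, objective, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  # independent Newton-free optimizer lands on the same coefficients
  expect_lt(max(abs(opt$par - fit$coefficients)), 1e-4)
  expect_lte(objective(fit$coefficients), opt$value + 1e-6)
})

test_that("the MCMC reference engine agrees with the Laplace approximation", {
  sim <- mini_study()
  obs <- sim$observations[sim$observations$year == 2015, ]
  fit_l <- fit_phenology_gam(obs, year = 2015,
                             regions = c("northern", "southern"), seed = 5)
  fit_m <- fit_phenology_gam(obs, year = 2015,
                             regions = c("northern", "southern"),
                             method = "mcmc", chains = 4, iter = 4000,
                             thin = 4, seed = 5)
  expect_true(all(fit_m$rhat < 1.05, na.rm = TRUE))
  expect_gte(nrow(fit_m$draws), 1000)
  cv_l <- expected_proportion_curve(fit_l, "northern")
  cv_m <- expected_proportion_curve(fit_m, "northern", force = TRUE)
  # posterior-mean curves from the two engines agree to a few percent
  expect_lt(max(abs(cv_l$mean - cv_m$mean)), 0.05)
})

test_that("posterior intervals for the curve cover the threshold at the true start", {
  # over many year x region cells, the 95% interval of p(true_start) should
  # contain tau (= the latent curve value there) most of the time
  sim <- mini_study()
  tau <- sim$truth$config$tau
  fits <- fit_phenology_all(sim$observations,
                            regions = c("northern", "southern"), seed = 44)
  covered <- 0L; total <- 0L
  for (cv in fits$curves) {
    tr <- sim$truth$table[sim$truth$table$year == cv$year &
                            sim$truth$table$region == cv$region, ]
    i <- which.min(abs(cv$doy - tr$true_start))
    qs <- quantile(cv$draws[, i], c(0.025, 0.975))
    covered <- covered + (qs[1] <= tau && tau <= qs[2])
    total <- total + 1L
  }
  expect_gte(covered / total, 0.7)
})

test_that("fit methods expose the usual modelling surface", {
  fit <- mini_fit()
  expect_output(print(fit), "Hierarchical phenology GAM")
  s <- summary(fit)
  expect_output(print(s), "curve peaks")
  expect_length(coef(fit), ncol(fit$draws))
  p <- predict(fit)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(predict(fit, type = "link"), qlogis(p), tolerance = 1e-10)
  r <- residuals(fit)
  expect_length(r, fit$nobs)
  expect_equal(sign(r), sign(residuals(fit, type = "response")))
  sm <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(dim(sm), c(fit$nobs, 2L))
  expect_true(all(unlist(sm) %in% 0:1))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
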