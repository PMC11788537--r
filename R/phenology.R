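#' Design matrices of the hierarchical phenology GAM
#'
#' Builds the model matrix and penalty list of the hierarchical curve model:
#' a global cyclic day-of-year smoother shared by all regions (sum-to-zero
#' constrained, leaving the intercept free) plus one deviation smoother per
#' region sharing the same cyclic basis. Region smoothers carry two
#' penalties with smoothing parameters common to all regions: the cyclic
#' roughness penalty on their shape, and a separate level penalty on the
#' per-region constant (the roughness penalty's null space), which acts as
#' a random region intercept. Regions with little data are shrunk towards
#' the global shape and level.
#'
#' @param basis A [cyclic_basis()].
#' @param doy Numeric vector of days of year (one per observation).
#' @param region Character/factor vector of region memberships.
#' @param regions Character vector of modelled regions.
#' @return List with `X` (model matrix without intercept), `penalties`
#'   (list of three full-size penalty matrices: global roughness, regional
#'   roughness, regional level), `Z` (the global sum-to-zero contrast), and
#'   the column index sets `idx_global`, `idx_region` (a list by region).
#' @export
phenology_design <- function(basis, doy, region, regions = default_regions()) {
  stopifnot(inherits(basis, "cyclic_basis"))
  region <- as.character(region)
  unknown <- setdiff(unique(region), regions)
  if (length(unknown))
    stopf("observations contain unmodelled region(s): %s",
          paste(unknown, collapse = ", "))
  k <- basis$dim
  nr <- length(regions)
  X0 <- basis_matrix(basis, doy)
  Z <- qr.Q(qr(matrix(1, k, 1)), complete = TRUE)[, -1, drop = FALSE]
  Xg <- X0 %*% Z
  Sg <- crossprod(Z, basis$S %*% Z)
  n <- length(doy)
  Xr <- matrix(0, n, nr * k)
  for (j in seq_len(nr)) {
    rows <- region == regions[j]
    if (any(rows))
      Xr[rows, (j - 1L) * k + seq_len(k)] <- X0[rows, , drop = FALSE]
  }
  X <- cbind(Xg, Xr)
  p <- ncol(X)
  pad <- function(M, at) {
    out <- matrix(0, p, p)
    out[at, at] <- M
    out
  }
  ig <- seq_len(k - 1L)
  ir <- (k - 1L) + seq_len(nr * k)
  Scc <- matrix(0, nr * k, nr * k)
  Slev <- matrix(0, nr * k, nr * k)
  ones <- matrix(1 / k^2, k, k)   # penalizes (mean of the block)^2 only
  for (j in seq_len(nr)) {
    at <- (j - 1L) * k + seq_len(k)
    Scc[at, at] <- basis$S
    Slev[at, at] <- ones
  }
  penalties <- list(global = pad(Sg, ig),
                    region = pad(Scc, ir),
                    level = pad(Slev, ir))
  idx_region <- lapply(seq_len(nr), function(j) (k - 1L) + (j - 1L) * k + seq_len(k))
  names(idx_region) <- regions
  list(X = X, penalties = penalties, Z = Z, idx_global = ig,
       idx_region = idx_region)
}

#' Fit the hierarchical phenology GAM for one year
#'
#' Binomial (Bernoulli) model of the likely-breeding state against day of
#' year: `logit p = beta0 + f_global(doy) + f_region(doy)`, with cyclic
#' cubic regression spline smoothers (see [phenology_design()]). Smoothing
#' parameters are estimated by REML through the `mgcv` penalized-likelihood
#' machinery operating on the package's own design and penalty matrices.
#'
#' Two posterior-draw engines are available. `method = "laplace"` (default)
#' draws coefficients from the Gaussian approximation to the posterior at
#' the penalized-likelihood optimum -- fast, deterministic given `seed`, and
#' adequate at the sample sizes of a citizen-science season. `method =
#' "mcmc"` is the reference sampler: independence Metropolis--Hastings on
#' the exact penalized-likelihood posterior (smoothing parameters fixed at
#' their REML estimates) with 4 chains of 8000 iterations thinned by 4;
#' split-chain potential-scale-reduction diagnostics are attached and the
#' fit is flagged non-converged if any exceeds `rhat_limit` (1.01).
#'
#' @param observations Observation data frame (see [read_observations()]);
#'   rows of other years are dropped if `year` is given.
#' @param year Study year to fit; defaults to the single year present.
#' @param basis A [cyclic_basis()].
#' @param regions Modelled region set.
#' @param method `"laplace"` or `"mcmc"`.
#' @param ndraws Posterior draws kept in laplace mode (>= 1000 recommended).
#' @param chains,iter,thin MCMC budget (defaults 4 x 8000, thinning 4).
#' @param rhat_limit Convergence bound for the Gelman--Rubin statistic.
#' @param sp Optional fixed smoothing parameters (length 3) bypassing REML.
#' @param sp_cap Upper bounds on the three smoothing parameters. REML
#'   empirical-Bayes estimates of the regional deviation penalties can
#'   diverge when the between-region information is weak (there are only a
#'   handful of regions), collapsing the hierarchy to complete pooling and
#'   erasing real regional phenology differences. The default caps the
#'   deviation roughness and level penalties at weakly informative values
#'   -- the same role weakly informative priors on the smoother scales play
#'   in a fully Bayesian fit -- while leaving the global smoother
#'   unbounded. Set to `c(Inf, Inf, Inf)` for plain REML.
#' @param seed Seed for the draw stage.
#' @return Object of class `phenology_fit`.
#' @export
fit_phenology_gam <- function(observations, year = NULL,
                              basis = cyclic_basis(),
                              regions = default_regions(),
                              method = c("laplace", "mcmc"),
                              ndraws = 1000,
                              chains = 4, iter = 8000, thin = 4,
                              rhat_limit = 1.01,
                              sp = NULL, sp_cap = c(Inf, 1e4, 1),
                              seed = NULL) {
  method <- match.arg(method)
  obs <- observations
  if (is.null(year)) {
    yrs <- unique(obs$year)
    if (length(yrs) != 1L)
      stopf("`observations` span %d years; give `year` explicitly", length(yrs))
    year <- yrs
  }
  obs <- obs[obs$year == year, , drop = FALSE]
  if (nrow(obs) == 0L) stopf("no observations for year %s", year)
  y <- as.integer(obs$state == "likely_breeding")
  degenerate <- length(unique(y)) < 2L
  des <- phenology_design(basis, obs$day_of_year, obs$region, regions)
  XP <- des$X
  pp <- des$penalties
  if (!is.null(sp)) pp$sp <- sp   # fix smoothing parameters, bypassing REML
  gam_fit <- function(pp) suppressWarnings(mgcv::gam(
    y ~ XP,
    paraPen = list(XP = pp),
    family = stats::binomial(),
    method = "REML"
  ))
  fit <- gam_fit(pp)
  if (is.null(sp) && any(fit$sp > sp_cap)) {
    pp$sp <- pmin(fit$sp, sp_cap)
    fit <- gam_fit(pp)
  }
  mu <- stats::coef(fit)
  Vp <- fit$Vp
  sp_hat <- if (length(fit$sp)) fit$sp else unname(pp$sp)
  if (!is.null(seed)) set.seed(seed)
  Xfull <- cbind(1, XP)
  if (method == "laplace") {
    draws <- mgcv::rmvn(max(ndraws, 2L), mu, Vp)
    rhat <- rep(NA_real_, length(mu))
    converged <- isTRUE(fit$converged)
  } else {
    penalties <- des$penalties
    log_post <- function(beta) {
      eta <- as.vector(Xfull %*% beta)
      ll <- sum(y * eta - log1p(exp(eta)))
      quad <- 0
      for (i in seq_along(penalties)) {
        b <- beta[-1]
        quad <- quad + sp_hat[i] * sum(b * (penalties[[i]] %*% b))
      }
      ll - 0.5 * quad
    }
    Vprop <- Vp * 1.4
    keep_per <- floor(iter / thin)
    kept <- array(NA_real_, c(keep_per, chains, length(mu)))
    for (ch in seq_len(chains)) {
      prop <- mgcv::rmvn(iter, mu, Vprop)
      lq <- mgcv::dmvn(t(prop), mu, Vprop)
      cur <- mu
      lp_cur <- log_post(cur)
      lq_cur <- mgcv::dmvn(matrix(cur), mu, Vprop)
      u <- log(stats::runif(iter))
      ki <- 0L
      for (it in seq_len(iter)) {
        cand <- prop[it, ]
        lp_cand <- log_post(cand)
        if (u[it] < (lp_cand - lq[it]) - (lp_cur - lq_cur)) {
          cur <- cand; lp_cur <- lp_cand; lq_cur <- lq[it]
        }
        if (it %% thin == 0L) {
          ki <- ki + 1L
          kept[ki, ch, ] <- cur
        }
      }
    }
    rhat <- apply(kept, 3, function(m) split_rhat(m))
    converged <- all(rhat < rhat_limit, na.rm = TRUE)
    if (!converged)
      warnf("phenology fit for year %s did not converge (max Rhat = %.3f)",
            year, max(rhat, na.rm = TRUE))
    draws <- matrix(aperm(kept, c(1, 2, 3)), nrow = keep_per * chains)
  }
  structure(list(
    year = year,
    coefficients = mu,
    Vp = Vp,
    sp = sp_hat,
    draws = draws,
    basis = basis,
    Z = des$Z,
    regions = regions,
    idx_global = des$idx_global,
    idx_region = des$idx_region,
    method = method,
    converged = converged,
    degenerate = degenerate,
    rhat = rhat,
    rhat_limit = rhat_limit,
    nobs = nrow(obs),
    n_likely = sum(y),
    data = data.frame(day_of_year = obs$day_of_year, region = obs$region,
                      y = y, stringsAsFactors = FALSE),
    fitted_p = as.vector(stats::plogis(Xfull %*% mu))
  ), class = "phenology_fit")
}

# full design row(s) for (doy, region) on the coefficient vector of a fit
curve_design <- function(fit, doy, region) {
  X0 <- basis_matrix(fit$basis, doy)
  Xg <- X0 %*% fit$Z
  p <- length(fit$coefficients)
  X <- matrix(0, length(doy), p)
  X[, 1] <- 1
  X[, 1 + fit$idx_global] <- Xg
  X[, 1 + fit$idx_region[[region]]] <- X0
  X
}

#' Posterior phenology curve for one region
#'
#' Evaluates the expected proportion of likely-breeding observations
#' `p(d) = inverse-logit(f_global(d) + f_region(d))` on a daily grid, per
#' posterior draw.
#'
#' @param fit A [fit_phenology_gam()] object.
#' @param region Region name (must be among the fit's regions).
#' @param grid Day-of-year grid (default: every day of the basis domain).
#' @param force Evaluate even if the fit is flagged non-converged.
#' @return Object of class `phenology_curve`: list with `year`, `region`,
#'   `doy`, `mean` (posterior-mean curve), and `draws`
#'   (draws x grid matrix, all values in [0, 1]).
#' @export
expected_proportion_curve <- function(fit, region,
                                      grid = NULL, force = FALSE) {
  stopifnot(inherits(fit, "phenology_fit"))
  if (!region %in% fit$regions)
    stopf("region '%s' is not part of the fit (regions: %s)", region,
          paste(fit$regions, collapse = ", "))
  if (!fit$converged && !force)
    warnf("phenology fit for year %s is flagged non-converged; curves may be unreliable",
          fit$year)
  if (is.null(grid))
    grid <- seq(fit$basis$domain[1], fit$basis$domain[2], by = 1)
  X <- curve_design(fit, grid, region)
  eta <- fit$draws %*% t(X)
  p <- stats::plogis(eta)
  structure(list(year = fit$year, region = region, doy = grid,
                 mean = as.vector(stats::plogis(X %*% fit$coefficients)),
                 draws = p),
            class = "phenology_curve")
}

#' Fit phenology GAMs for every year and extract all regional curves
#'
#' @param observations Multi-year observation table.
#' @param years Years to fit (default: all present).
#' @param ... Passed to [fit_phenology_gam()].
#' @return List with `fits` (by year) and `curves` (flat list of
#'   `phenology_curve`, one per year x region).
#' @export
fit_phenology_all <- function(observations, years = NULL, ...) {
  if (is.null(years)) years <- sort(unique(observations$year))
  fits <- lapply(years, function(yr)
    fit_phenology_gam(observations, year = yr, ...))
  names(fits) <- as.character(years)
  curves <- list()
  for (f in fits)
    for (rg in f$regions)
      curves[[length(curves) + 1L]] <- expected_proportion_curve(f, rg)
  list(fits = fits, curves = curves)
}

#' @export
print.phenology_fit <- function(x, ...) {
  cat(sprintf("Hierarchical phenology GAM, year %s\n", x$year))
  cat(sprintf("  %d observations (%d likely breeding) in %d regions\n",
              x$nobs, x$n_likely, length(x$regions)))
  cat(sprintf("  engine: %s, %d posterior draws; converged: %s%s\n",
              x$method, nrow(x$draws), x$converged,
              if (x$degenerate) " (degenerate: single state)" else ""))
  invisible(x)
}

#' @export
summary.phenology_fit <- function(object, ...) {
  out <- list(year = object$year, nobs = object$nobs,
              n_likely = object$n_likely, method = object$method,
              converged = object$converged, degenerate = object$degenerate,
              sp = object$sp,
              max_rhat = if (all(is.na(object$rhat))) NA_real_
                         else max(object$rhat, na.rm = TRUE),
              peak = vapply(object$regions, function(rg) {
                cv <- expected_proportion_curve(object, rg, force = TRUE)
                max(cv$mean)
              }, numeric(1)))
  class(out) <- "summary.phenology_fit"
  out
}

#' @export
print.summary.phenology_fit <- function(x, ...) {
  cat(sprintf("Phenology GAM %s: n = %d (%d likely breeding), engine %s\n",
              x$year, x$nobs, x$n_likely, x$method))
  cat(sprintf("  smoothing parameters: %s\n",
              paste(signif(x$sp, 3), collapse = ", ")))
  if (!is.na(x$max_rhat))
    cat(sprintf("  max split-Rhat: %.4f (converged: %s)\n", x$max_rhat,
                x$converged))
  cat("  posterior-mean curve peaks:\n")
  for (rg in names(x$peak))
    cat(sprintf("    %-10s %.3f\n", rg, x$peak[rg]))
  invisible(x)
}

#' @export
coef.phenology_fit <- function(object, ...) object$coefficients

#' @export
predict.phenology_fit <- function(object, newdata = NULL,
                                  type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata))
    newdata <- object$data[, c("day_of_year", "region")]
  eta <- numeric(nrow(newdata))
  for (rg in unique(newdata$region)) {
    rows <- newdata$region == rg
    X <- curve_design(object, newdata$day_of_year[rows], rg)
    eta[rows] <- X %*% object$coefficients
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
residuals.phenology_fit <- function(object, type = c("deviance", "response"),
                                    ...) {
  type <- match.arg(type)
  y <- object$data$y
  p <- object$fitted_p
  if (type == "response") return(y - p)
  d2 <- -2 * (y * log(p) + (1 - y) * log1p(-p))
  sign(y - p) * sqrt(pmax(d2, 0))
}

#' @export
simulate.phenology_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fitted_p
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.phenology_fit <- function(x, regions = x$regions, level = 0.95, ...) {
  cols <- grDevices::hcl.colors(length(regions), "Dark 3")
  grid <- seq(x$basis$domain[1], x$basis$domain[2], by = 1)
  curves <- lapply(regions, function(rg)
    expected_proportion_curve(x, rg, grid = grid, force = TRUE))
  ymax <- max(vapply(curves, function(cv) max(cv$mean), numeric(1)), 0.1)
  graphics::plot(NA, xlim = range(grid), ylim = c(0, ymax * 1.3),
                 xlab = "day of year",
                 ylab = "expected proportion likely breeding",
                 main = sprintf("Breeding phenology, %s", x$year), ...)
  a <- (1 - level) / 2
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    qs <- apply(cv$draws, 2, stats::quantile, probs = c(a, 1 - a))
    graphics::polygon(c(cv$doy, rev(cv$doy)), c(qs[1, ], rev(qs[2, ])),
                      col = grDevices::adjustcolor(cols[i], 0.2), border = NA)
    graphics::lines(cv$doy, cv$mean, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = regions, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' @export
print.phenology_curve <- function(x, ...) {
  cat(sprintf("Phenology curve %s / %s: %d days, %d posterior draws, peak mean %.3f\n",
              x$year, x$region, length(x$doy), nrow(x$draws), max(x$mean)))
  invisible(x)
}
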