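# Shared fixtures, built in code. `mini_study()` is a small, seeded
# multi-year scenario reused across tests; memoised so the suite pays for it
# once.

mini_synth_config <- function(...) {
  defaults <- list(years = 2014:2017,
                   regions = c("northern", "southern"),
                   effort = 150,
                   region_temp_offsets = c(northern = 0, southern = 1.5),
                   snow_region_offsets = c(northern = 0, southern = -8))
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

.mini_cache <- new.env(parent = emptyenv())

mini_study <- function() {
  if (is.null(.mini_cache$sim))
    .mini_cache$sim <- simulate_study(mini_synth_config(), seed = 42)
  .mini_cache$sim
}

mini_fit <- function() {
  if (is.null(.mini_cache$fit)) {
    sim <- mini_study()
    .mini_cache$fit <- fit_phenology_gam(sim$observations, year = 2015,
                                         seed = 99)
  }
  .mini_cache$fit
}

# hand-made phenology curve from a closed-form p(d), with optional fake draws
curve_from_function <- function(f, n_draws = 5, doy = 60:304,
                                year = 2015, region = "northern") {
  p <- f(doy)
  structure(list(year = year, region = region, doy = doy, mean = p,
                 draws = matrix(rep(p, each = n_draws), nrow = n_draws)),
            class = "phenology_curve")
}

# random smooth unimodal curves for property tests
random_bump_curve <- function(seed) {
  set.seed(seed)
  peak <- runif(1, 140, 230)
  height <- runif(1, 0.08, 0.6)
  width <- runif(1, 10, 40)
  curve_from_function(function(d) height * exp(-((d - peak) / width)^2))
}
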