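# snowphen

Breeding-season phenology of an alpine songbird from citizen-science
breeding evidence, and how temperature, precipitation, and snow shape it.

High-elevation birds such as the white-winged snowfinch breed inside a
short window between snowmelt and midsummer vegetation growth. Citizen
scientists report observations year-round, a minority of which carry
ordinal breeding-evidence codes (courtship, nest building, feeding
nestlings, ...). `snowphen` turns such records into estimates of the
**start, end, and duration of the breeding season** per year and
biogeographic region, and then asks which climate windows drive them. It
is aimed at ecologists analysing opportunistic breeding-evidence data over
multiple years and regions.

## The model

Observations are classified into a binary state: *likely breeding*
(courtship-level code or higher inside May 1–Aug 31) vs *nonbreeding*.
Per year, the state is modelled with a hierarchical binomial GAM

  logit p(d, r) = β₀ + f(d) + f_r(d),

where d is day of year, f a global cyclic cubic regression spline shared
by all regions and f_r shrunken per-region deviation smoothers (cyclic, so
the curve closes at the March/October domain ends where no breeding
occurs). The breeding season **starts** on the first day the expected
proportion of likely-breeding observations exceeds a threshold τ (5%
default), **ends** on the first day after the seasonal peak it drops below
τ, and the **duration** is their difference; a 1%–12% threshold ladder
quantifies sensitivity to τ. Snowmelt **timing** is the first day after
peak cover with ≤ 50% absolute snow-cover fraction; snowmelt **duration**
the days between 95% and 5% of the seasonal maximum. A sliding-window scan
(windows ≥ 7 days on a 2-day grid; Apr 1–Jun 30 for the start, Apr 15–Aug
15 for the end) correlates window mean temperature and precipitation days
(≥ 1 mm) with the metrics, keeps windows whose Pearson r ± 1.96·SE
excludes zero (SE = √((1−r²)/(n−2))), and selects the certain window with
the largest |r|. Linear mixed models with year and region random
intercepts then quantify effects in standardized (per SD) and
unstandardized (days/°C, days per precipitation day, days/day) form, and
linear trend models track breeding-season temperature across years.

A seeded synthetic-data generator (`simulate_study()`) reproduces the
study design — 16 years × 4 regions × 200 observations per region-year,
realistic alpine climate with week-scale weather spells, and planted
linear climate effects on the true season limits — so every stage has a
parameter-recovery test surface.

## Worked example

```r
library(snowphen)

cfg <- synth_config(years = 2010:2015)      # 6-year, 4-region synthetic study
sim <- simulate_study(cfg, seed = 42)

fit <- fit_phenology_gam(sim$observations, year = 2012, seed = 1)
print(fit)
#> Hierarchical phenology GAM, year 2012
#>   800 observations (105 likely breeding) in 4 regions
#>   engine: laplace, 1000 posterior draws; converged: TRUE

cv <- expected_proportion_curve(fit, "eastern")
st <- extract_start(cv, tau = 0.05)
en <- extract_end(cv, tau = 0.05, start = st)
print(st); print(en)
#> Season start at threshold 0.05: day 124 (95% CrI 92-135)
#> Season end at threshold 0.05: day 233 (95% CrI 222.975-255)
season_duration(st, en)
#> [1] 109
```

The start day (124 ≈ May 4) is the first day the expected proportion of
likely-breeding observations among eastern-region reports exceeds 5%, with
its 95% credible interval from 1000 posterior draws of the curve; the
109-day duration is the span to the day that proportion falls back below
5% after the peak.

The whole pipeline over all years, plus the climate scan:

```r
res <- fit_phenology_all(sim$observations, seed = 7)
metrics <- phenology_metrics(res$curves, tau = 0.05)
head(metrics[, c("year", "region", "start", "end", "duration")], 4)
#>   year   region start end duration
#> 1 2010 northern   139 225       86
#> 2 2010  eastern   142 231       89
#> 3 2010 southern   127 231      104
#> 4 2010  western   134 224       90

wins <- enumerate_windows(c(91, 181), min_len = 7, step = 2)
scan <- correlation_scan(metrics, sim$climate, wins,
                         "mean_temperature", "start")
select_best_window(scan)
#> Critical window for start ~ mean_temperature: days 123-147 (length 25),
#>   r = -0.783 (se 0.133, n = 24)

head(snow_metrics(sim$climate)[, c("year", "region", "melt_timing",
                                   "melt_duration")], 3)
#>   year  region melt_timing melt_duration
#> 1 2010 eastern         158            44
#> 2 2011 eastern         158            47
#> 3 2012 eastern         149            45
```

The selected window (days 123–147, mid-May to late May) is the period
whose mean temperature correlates most strongly — negatively, r = −0.78:
warm springs, earlier breeding — with the estimated start days across the
24 year × region cells, among all certainty-filtered candidate windows.
`fit_lmm()` then turns the selected windows and snowmelt metrics into
effect sizes, and `run_all()` executes every stage from one `run_config()`
with CSV outputs and a JSON manifest.

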