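# snowmelt timing and duration from daily snow-cover-fraction series

#' Snowmelt timing of one region-year
#'
#' The melt timing is the first day, at or after the day of seasonal maximum
#' cover, on which the snow-cover fraction is at 50% absolute coverage or
#' below (`<= 0.5`; set `strict = TRUE` for `< 0.5`). Undefined (NA with
#' flag) when the series never exceeds 50% cover.
#'
#' @param doy Day-of-year vector (gapless daily series).
#' @param cover Snow-cover fractions in [0, 1], same length.
#' @param threshold Absolute cover threshold (default 0.5).
#' @param strict Use a strict `<` comparison instead of `<=`.
#' @return List `day` (NA if undefined), `defined`, `max_day`, `max_cover`.
#' @export
snowmelt_timing <- function(doy, cover, threshold = 0.5, strict = FALSE) {
  stopifnot(length(doy) == length(cover), !is.unsorted(doy))
  imax <- which.max(cover)
  mx <- cover[imax]
  if (mx <= threshold)
    return(list(day = NA_real_, defined = FALSE, max_day = doy[imax],
                max_cover = mx))
  after <- imax:length(cover)
  hit <- if (strict) cover[after] < threshold else cover[after] <= threshold
  i <- first_which(hit)
  list(day = if (is.na(i)) NA_real_ else doy[after[i]],
       defined = !is.na(i), max_day = doy[imax], max_cover = mx)
}

#' Snowmelt duration of one region-year
#'
#' Days between the series dropping below 95% and below 5% of its seasonal
#' maximum cover (both measured after the day of maximum cover). Thresholds
#' are relative to the maximum because full cover is not reached in every
#' region and year. If cover never falls below 5% of the maximum the
#' duration is censored at the domain end and flagged.
#'
#' @inheritParams snowmelt_timing
#' @param hi,lo Relative thresholds (defaults 0.95 and 0.05 of the maximum).
#' @return List `duration` (days, >= 0), `day_hi`, `day_lo`, `censored`,
#'   `max_cover`.
#' @export
snowmelt_duration <- function(doy, cover, hi = 0.95, lo = 0.05,
                              strict = TRUE) {
  stopifnot(length(doy) == length(cover), !is.unsorted(doy))
  imax <- which.max(cover)
  mx <- cover[imax]
  if (mx <= 0)
    return(list(duration = NA_real_, day_hi = NA_real_, day_lo = NA_real_,
                censored = FALSE, max_cover = mx))
  after <- imax:length(cover)
  cmp <- function(x, thr) if (strict) x < thr else x <= thr
  i_hi <- first_which(cmp(cover[after], hi * mx))
  i_lo <- first_which(cmp(cover[after], lo * mx))
  censored <- is.na(i_lo)
  day_hi <- if (is.na(i_hi)) doy[length(doy)] else doy[after[i_hi]]
  day_lo <- if (censored) doy[length(doy)] else doy[after[i_lo]]
  list(duration = day_lo - day_hi, day_hi = day_hi, day_lo = day_lo,
       censored = censored || is.na(i_hi), max_cover = mx)
}

#' Snowmelt metrics for every region-year of a climate table
#'
#' @param climate Climate data frame (see [read_climate()]).
#' @param threshold Absolute timing threshold (default 0.5).
#' @param hi,lo Relative duration thresholds.
#' @return Data frame: `year`, `region`, `melt_timing`, `melt_duration`,
#'   `max_cover`, `timing_defined`, `duration_censored`.
#' @export
snow_metrics <- function(climate, threshold = 0.5, hi = 0.95, lo = 0.05) {
  cells <- unique(climate[, c("year", "region")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- climate[climate$year == cells$year[i] &
                     climate$region == cells$region[i], ]
    sub <- sub[order(sub$day_of_year), ]
    tm <- snowmelt_timing(sub$day_of_year, sub$snow_cover_fraction, threshold)
    du <- snowmelt_duration(sub$day_of_year, sub$snow_cover_fraction, hi, lo)
    data.frame(year = cells$year[i], region = cells$region[i],
               melt_timing = tm$day, melt_duration = du$duration,
               max_cover = tm$max_cover,
               timing_defined = tm$defined,
               duration_censored = du$censored,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$region, out$year), ]
  rownames(out) <- NULL
  out
}
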