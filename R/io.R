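#' Read citizen-science observations from CSV
#'
#' Expects a header row with columns `date`, `region`, `breeding_code`
#' (RFC 4180, UTF-8). Dates are ISO-8601. The binary breeding state is
#' assigned on read via [classify_state()], and summary counts (total,
#' likely breeding, nonbreeding) are reported with `message()`.
#'
#' @param path CSV file path.
#' @param map A [code_map()] used for state assignment.
#' @param regions Allowed region identifiers.
#' @param season Season window passed to [classify_state()].
#' @param quiet Suppress the summary message.
#' @return A data frame with columns `date`, `year`, `day_of_year`,
#'   `region`, `breeding_code`, `state`.
#' @export
read_observations <- function(path, map = code_map(),
                              regions = default_regions(),
                              season = default_season(), quiet = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("date", "region", "breeding_code")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stopf("observations file %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) {
    if (!quiet) message("read 0 observations (0 likely breeding, 0 nonbreeding)")
    return(data.frame(date = as.Date(character()), year = integer(),
                      day_of_year = integer(), region = character(),
                      breeding_code = character(), state = character(),
                      stringsAsFactors = FALSE))
  }
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates) | is.na(raw$date) | raw$date == "")
  if (length(bad))
    stopf("malformed date '%s' in %s at row %d", raw$date[bad[1]], path, bad[1])
  bad_region <- which(!raw$region %in% regions)
  if (length(bad_region))
    stopf("unknown region '%s' in %s at row %d", raw$region[bad_region[1]],
          path, bad_region[1])
  code <- raw$breeding_code
  code[code %in% c("", "NA", "absent")] <- NA_character_
  obs <- data.frame(
    date = dates,
    year = as.integer(format(dates, "%Y")),
    day_of_year = day_of_year(dates),
    region = raw$region,
    breeding_code = code,
    state = classify_state(code, dates, map = map, season = season),
    stringsAsFactors = FALSE
  )
  if (!quiet) {
    n_lb <- sum(obs$state == "likely_breeding")
    message(sprintf("read %d observations (%d likely breeding, %d nonbreeding)",
                    nrow(obs), n_lb, nrow(obs) - n_lb))
  }
  obs
}

#' Write observations to CSV
#'
#' Writes the three input columns (`date`, `region`, `breeding_code`) so that
#' [read_observations()] of the result reproduces the table (round trip).
#'
#' @param obs Observation data frame as from [read_observations()] or
#'   [generate_observations()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  out <- data.frame(date = format(as.Date(obs$date), "%Y-%m-%d"),
                    region = obs$region,
                    breeding_code = ifelse(is.na(obs$breeding_code), "",
                                           obs$breeding_code),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily climate table from CSV
#'
#' Expects columns `region`, `date`, `temp_mean` (degC), `precip_sum`
#' (mm/day, >= 0), `snow_cover_fraction` (in [0, 1]). Per region and year the
#' dates between the first and last entry must form a gapless daily series;
#' a gap raises an error naming the region and the first missing date.
#'
#' @param path CSV file path.
#' @param regions Allowed region identifiers, or `NULL` to accept any.
#' @return Data frame with columns `region`, `date`, `year`, `day_of_year`,
#'   `temp_mean`, `precip_sum`, `snow_cover_fraction`.
#' @export
read_climate <- function(path, regions = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "date", "temp_mean", "precip_sum", "snow_cover_fraction")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stopf("climate file %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad))
    stopf("malformed date '%s' in %s at row %d", raw$date[bad[1]], path, bad[1])
  if (!is.null(regions)) {
    bad_region <- which(!raw$region %in% regions)
    if (length(bad_region))
      stopf("unknown region '%s' in %s at row %d", raw$region[bad_region[1]],
            path, bad_region[1])
  }
  clim <- data.frame(region = raw$region, date = dates,
                     year = as.integer(format(dates, "%Y")),
                     day_of_year = day_of_year(dates),
                     temp_mean = as.numeric(raw$temp_mean),
                     precip_sum = as.numeric(raw$precip_sum),
                     snow_cover_fraction = as.numeric(raw$snow_cover_fraction),
                     stringsAsFactors = FALSE)
  validate_climate(clim, source = path)
  clim[order(clim$region, clim$date), , drop = FALSE]
}

# shared invariant checks for climate tables (also applied to generated ones)
validate_climate <- function(clim, source = "climate table") {
  if (any(clim$precip_sum < 0, na.rm = TRUE))
    stopf("%s: precip_sum must be >= 0", source)
  out_of_range <- clim$snow_cover_fraction < 0 | clim$snow_cover_fraction > 1
  if (any(out_of_range, na.rm = TRUE))
    stopf("%s: snow_cover_fraction %.3g outside [0, 1]", source,
          clim$snow_cover_fraction[first_which(out_of_range)])
  for (rg in unique(clim$region)) {
    for (yr in unique(clim$year[clim$region == rg])) {
      d <- sort(clim$date[clim$region == rg & clim$year == yr])
      if (anyDuplicated(d))
        stopf("%s: duplicated date %s for region %s", source,
              d[anyDuplicated(d)], rg)
      full <- seq(d[1], d[length(d)], by = "day")
      missing <- setdiff(as.character(full), as.character(d))
      if (length(missing))
        stopf("%s: daily series for region %s has a gap at %s", source, rg,
              missing[1])
    }
  }
  invisible(clim)
}

#' Write a climate table to CSV
#'
#' Inverse of [read_climate()] (round trip on the five input columns).
#'
#' @param clim Climate data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_climate <- function(clim, path) {
  out <- data.frame(region = clim$region,
                    date = format(as.Date(clim$date), "%Y-%m-%d"),
                    temp_mean = clim$temp_mean,
                    precip_sum = clim$precip_sum,
                    snow_cover_fraction = clim$snow_cover_fraction,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
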