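# sliding-window climate sensitivity scan

#' Enumerate candidate climate windows
#'
#' All windows whose opening and closing days lie on a step-day grid
#' anchored at the start of the search range, with length at least
#' `min_len`, fully inside the range. The default 2-day slide and 7-day
#' minimum length give the pixel grid of a window-scan heatmap.
#'
#' @param range Day-of-year interval `c(first, last)` to search.
#' @param min_len Minimum window length in days (default 7).
#' @param step Grid step in days for both endpoints (default 2).
#' @return Data frame `open`, `close`, `length`; empty if the range is
#'   shorter than `min_len`.
#' @export
enumerate_windows <- function(range, min_len = 7, step = 2) {
  stopifnot(length(range) == 2L, range[2] >= range[1])
  grid <- seq(range[1], range[2], by = step)
  out <- expand.grid(open = grid, close = grid)
  out <- out[out$close - out$open + 1 >= min_len, , drop = FALSE]
  out$length <- out$close - out$open + 1
  out <- out[order(out$open, out$close), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize climate inside one window per year x region
#'
#' `mean_temperature` is the mean of daily mean temperature in the window;
#' `precipitation_days` counts the days with at least `precip_mm` (1 mm)
#' of precipitation. Year x region cells with missing days in the window
#' are dropped with a warning.
#'
#' @param climate Climate data frame.
#' @param window `c(open, close)` days of year (or a one-row data frame
#'   with `open`/`close` columns).
#' @param variable `"mean_temperature"` or `"precipitation_days"`.
#' @param precip_mm Precipitation-day threshold in mm (default 1).
#' @return Data frame `year`, `region`, `value`.
#' @export
window_summary <- function(climate, window,
                           variable = c("mean_temperature",
                                        "precipitation_days"),
                           precip_mm = 1) {
  variable <- match.arg(variable)
  if (is.data.frame(window)) window <- c(window$open[1], window$close[1])
  len <- window[2] - window[1] + 1
  keep <- climate$day_of_year >= window[1] & climate$day_of_year <= window[2]
  sub <- climate[keep, , drop = FALSE]
  key <- interaction(sub$year, sub$region, drop = TRUE)
  n <- tapply(sub$day_of_year, key, length)
  x <- if (variable == "mean_temperature")
    tapply(sub$temp_mean, key, mean)
  else
    tapply(sub$precip_sum >= precip_mm, key, sum)
  ids <- do.call(rbind, strsplit(names(x), ".", fixed = TRUE))
  out <- data.frame(year = as.integer(ids[, 1]), region = ids[, 2],
                    value = as.vector(x), stringsAsFactors = FALSE)
  complete <- n == len
  if (any(!complete)) {
    warnf("%d year x region cell(s) dropped from window [%g, %g]: incomplete daily series",
          sum(!complete), window[1], window[2])
    out <- out[complete, , drop = FALSE]
  }
  out <- out[order(out$region, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Pearson correlation and its large-sample standard error, from scratch.
# Returns c(r, se, n); NA r for zero-variance inputs.
pearson_with_se <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(c(r = NA_real_, se = NA_real_, n = n))
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) return(c(r = NA_real_, se = NA_real_, n = n))
  r <- sum(xc * yc) / (sx * sy)
  r <- max(-1, min(1, r))
  se <- sqrt((1 - r^2) / (n - 2))
  c(r = r, se = se, n = n)
}

#' Sliding-window correlation scan
#'
#' For every candidate window, summarizes the climate variable per
#' year x region ([window_summary()]) and computes the Pearson correlation
#' with the phenology response over the pooled year x region points,
#' together with its standard error `sqrt((1 - r^2) / (n - 2))`. A window is
#' flagged `certain` when the symmetric 95% interval `r +/- 1.96 se`
#' excludes zero; when many windows are scanned, some high correlations
#' arise by chance, and the certainty filter is what guards the subsequent
#' selection. Windows with fewer than 3 complete pairs or zero-variance
#' summaries are omitted with a warning.
#'
#' @param metrics Phenology metrics table ([phenology_metrics()] or any
#'   data frame with `year`, `region`, and the response column).
#' @param climate Climate data frame.
#' @param windows Window table from [enumerate_windows()].
#' @param variable Climate summary variable (see [window_summary()]).
#' @param response Name of the response column in `metrics` (`"start"` or
#'   `"end"`, or `"duration"`).
#' @param precip_mm Precipitation-day threshold (mm).
#' @param z_crit Certainty multiplier (default 1.96 for a 95% interval).
#' @return Data frame of class `window_scan`: `open`, `close`, `length`,
#'   `r`, `se`, `n`, `certain`, plus attributes `variable` and `response`.
#' @export
correlation_scan <- function(metrics, climate, windows,
                             variable = c("mean_temperature",
                                          "precipitation_days"),
                             response = "start",
                             precip_mm = 1, z_crit = 1.96) {
  variable <- match.arg(variable)
  if (!response %in% names(metrics))
    stopf("response column '%s' not found in metrics", response)
  resp <- metrics[!is.na(metrics[[response]]), c("year", "region", response)]
  if (nrow(resp) < 3L)
    stopf("correlation scan needs >= 3 year x region phenology values")
  # cumulative sums per region-year over the day grid make each window an
  # O(1) lookup
  doys <- sort(unique(climate$day_of_year))
  cells <- unique(climate[, c("year", "region")])
  cells <- merge(cells, resp, by = c("year", "region"))
  nc <- nrow(cells)
  if (nc < 3L)
    stopf("fewer than 3 year x region cells shared between climate and metrics")
  cum_t <- cum_p <- matrix(NA_real_, nc, length(doys) + 1L)
  present <- matrix(FALSE, nc, length(doys))
  for (i in seq_len(nc)) {
    sub <- climate[climate$year == cells$year[i] &
                     climate$region == cells$region[i], ]
    idx <- match(sub$day_of_year, doys)
    tv <- pv <- rep(NA_real_, length(doys))
    tv[idx] <- sub$temp_mean
    pv[idx] <- as.numeric(sub$precip_sum >= precip_mm)
    present[i, idx] <- TRUE
    cum_t[i, ] <- c(0, cumsum(ifelse(is.na(tv), 0, tv)))
    cum_p[i, ] <- c(0, cumsum(ifelse(is.na(pv), 0, pv)))
  }
  cum_n <- cbind(0, t(apply(present, 1, cumsum)))
  y <- cells[[response]]
  nw <- nrow(windows)
  r_v <- se_v <- rep(NA_real_, nw)
  n_v <- integer(nw)
  for (w in seq_len(nw)) {
    i1 <- match(windows$open[w], doys)
    i2 <- match(windows$close[w], doys)
    if (is.na(i1) || is.na(i2)) next
    len <- windows$close[w] - windows$open[w] + 1
    ndays <- cum_n[, i2 + 1L] - cum_n[, i1]
    complete <- ndays == len
    x <- if (variable == "mean_temperature")
      (cum_t[, i2 + 1L] - cum_t[, i1]) / ndays
    else
      cum_p[, i2 + 1L] - cum_p[, i1]
    x[!complete] <- NA
    st <- pearson_with_se(x, y)
    r_v[w] <- st[["r"]]; se_v[w] <- st[["se"]]; n_v[w] <- st[["n"]]
  }
  keep_w <- !is.na(r_v)
  if (any(!keep_w))
    warnf("%d window(s) omitted from the scan (insufficient or degenerate data)",
          sum(!keep_w))
  out <- data.frame(open = windows$open[keep_w], close = windows$close[keep_w],
                    length = windows$close[keep_w] - windows$open[keep_w] + 1,
                    r = r_v[keep_w], se = se_v[keep_w], n = n_v[keep_w],
                    certain = abs(r_v[keep_w]) > z_crit * se_v[keep_w])
  rownames(out) <- NULL
  attr(out, "variable") <- variable
  attr(out, "response") <- response
  attr(out, "z_crit") <- z_crit
  class(out) <- c("window_scan", "data.frame")
  out
}

#' Select the critical window from a scan
#'
#' Among the windows whose correlation is certain (95% interval excluding
#' zero), picks the one with the highest absolute correlation coefficient;
#' ties are broken by shorter window, then earlier opening day. When no
#' window is certain, nothing is selected and the result is flagged.
#'
#' @param scan A [correlation_scan()] result.
#' @return List of class `window_selection`: `selected` (logical), and if
#'   selected `open`, `close`, `length`, `r`, `se`, `n`.
#' @export
select_best_window <- function(scan) {
  stopifnot(inherits(scan, "window_scan"))
  cand <- scan[scan$certain, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(structure(list(selected = FALSE, variable = attr(scan, "variable"),
                          response = attr(scan, "response")),
                     class = "window_selection"))
  ord <- order(-abs(cand$r), cand$length, cand$open)
  best <- cand[ord[1L], ]
  structure(list(selected = TRUE, open = best$open, close = best$close,
                 length = best$length, r = best$r, se = best$se, n = best$n,
                 variable = attr(scan, "variable"),
                 response = attr(scan, "response")),
            class = "window_selection")
}

#' @export
print.window_selection <- function(x, ...) {
  if (!x$selected) {
    cat(sprintf("No certain window for %s ~ %s\n", x$response, x$variable))
  } else {
    cat(sprintf("Critical window for %s ~ %s: days %g-%g (length %g), r = %.3f (se %.3f, n = %d)\n",
                x$response, x$variable, x$open, x$close, x$length, x$r,
                x$se, x$n))
  }
  invisible(x)
}

#' Long-format heatmap table of a window scan
#'
#' One row per scanned window with its opening day, closing day,
#' correlation and certainty flag -- the layout from which a window-scan
#' heatmap is drawn (uncertain cells are the grey-shaded pixels).
#'
#' @param scan A [correlation_scan()] result.
#' @return Data frame `open`, `close`, `r`, `certain`.
#' @export
scan_heatmap_table <- function(scan) {
  stopifnot(inherits(scan, "window_scan"))
  out <- data.frame(open = scan$open, close = scan$close, r = scan$r,
                    certain = scan$certain)
  rownames(out) <- NULL
  out
}
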