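#' Breeding-code catalogues
#'
#' Citizen-science portals attach ordinal breeding-evidence codes (atlas
#' codes) to bird observations: possible breeding (a bird seen or singing in
#' suitable habitat), probable breeding (pair, territory, courtship, nest
#' building), and confirmed breeding (occupied nest, adults carrying food,
#' feeding nestlings, fledglings). `code_map()` describes such a ladder
#' together with the cut point from which an observation counts as evidence
#' of likely breeding; the default cut is at courtship behaviour.
#'
#' National code schemes differ, so the catalogue is fully configurable: any
#' ordered character vector of labels plus a cut-point label defines a valid
#' map.
#'
#' @param levels Character vector of code labels, ordered from weakest to
#'   strongest breeding evidence.
#' @param cut Label from `levels`; this code and every higher one classify an
#'   in-season observation as likely breeding.
#' @return An object of class `code_map` with elements `levels` and `cut`.
#' @examples
#' m <- code_map()
#' m$cut
#' @export
code_map <- function(levels = c("seen", "singing", "pair_in_habitat",
                                "territory", "courtship", "nest_building",
                                "distraction_display", "occupied_nest",
                                "carrying_food", "feeding_nestlings",
                                "fledglings"),
                     cut = "courtship") {
  if (!is.character(levels) || length(levels) < 2L || anyDuplicated(levels))
    stopf("`levels` must be >= 2 distinct code labels")
  if (!cut %in% levels)
    stopf("cut point '%s' is not among the code levels", cut)
  structure(list(levels = levels, cut = cut), class = "code_map")
}

#' @export
print.code_map <- function(x, ...) {
  cut_i <- match(x$cut, x$levels)
  marked <- x$levels
  marked[cut_i] <- paste0("[", marked[cut_i], "]")
  cat("Breeding-code map (", length(x$levels), " levels, cut at '",
      x$cut, "'):\n  ", paste(marked, collapse = " < "), "\n", sep = "")
  invisible(x)
}

#' Default analysis season window
#'
#' Month-day limits of the breeding season inside which breeding codes are
#' taken at face value; observations outside are treated as nonbreeding
#' regardless of code (no breeding activity is expected there).
#'
#' @return Character vector `c(start, end)` in `"mm-dd"` form, May 1 to
#'   Aug 31 by default.
#' @export
default_season <- function() c("05-01", "08-31")

#' Default biogeographic region set
#'
#' The four Alpine sub-regions used as the spatial grouping unit.
#' @return Character vector of region identifiers.
#' @export
default_regions <- function() c("northern", "eastern", "southern", "western")

#' Classify observations into likely-breeding vs nonbreeding
#'
#' An observation is `"likely_breeding"` iff its breeding code is at or above
#' the map's cut point (courtship or higher by default) AND its date falls
#' inside the season window; every other observation -- lower codes, absent
#' codes, or any date outside the window -- is `"nonbreeding"`.
#'
#' @param code Character vector of code labels; `NA` means no code reported.
#' @param date `Date` vector (recycled against `code`).
#' @param map A [code_map()].
#' @param season Month-day season window as from [default_season()].
#' @return Character vector with values `"likely_breeding"` /
#'   `"nonbreeding"`.
#' @examples
#' classify_state("courtship", as.Date("2015-06-10"))
#' classify_state("feeding_nestlings", as.Date("2015-04-20"))
#' @export
classify_state <- function(code, date, map = code_map(),
                           season = default_season()) {
  stopifnot(inherits(map, "code_map"))
  date <- as.Date(date)
  n <- max(length(code), length(date))
  code <- rep_len(code, n)
  date <- rep_len(date, n)
  known <- is.na(code) | code %in% map$levels
  if (!all(known))
    stopf("unknown breeding code label(s): %s",
          paste(unique(code[!known]), collapse = ", "))
  rank <- match(code, map$levels)           # NA for absent codes
  cut_rank <- match(map$cut, map$levels)
  yr <- format(date, "%Y")
  season_start <- as.Date(paste0(yr, "-", season[1]))
  season_end <- as.Date(paste0(yr, "-", season[2]))
  in_season <- !is.na(date) & date >= season_start & date <= season_end
  likely <- !is.na(rank) & rank >= cut_rank & in_season
  ifelse(likely, "likely_breeding", "nonbreeding")
}
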