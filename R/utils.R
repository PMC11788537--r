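# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
inv_logit <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
logit <- function(p) log(p / (1 - p))

# Derive a stage seed from a master seed; keeps results < 2^31 so they are
# valid R integers.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 7919 + offset * 104729) %% 2147483629L + 1)
}

# day-of-year in the observation's own calendar year (leap years keep the
# natural numbering, so Mar 1 is day 60 or 61)
day_of_year <- function(date) {
  as.POSIXlt(date)$yday + 1L
}

date_from_doy <- function(year, doy) {
  as.Date(doy - 1L, origin = as.Date(sprintf("%d-01-01", year)))
}

# Split-chain potential scale reduction factor for one parameter.
# `draws` is an iterations x chains matrix.
split_rhat <- function(draws) {
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half) + B / (half * W))
}

# first index in x (scanning left to right) satisfying a logical vector,
# NA if none
first_which <- function(l) {
  w <- which(l)
  if (length(w) == 0L) NA_integer_ else w[1L]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
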