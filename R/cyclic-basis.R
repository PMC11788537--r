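#' Cyclic cubic regression spline basis
#'
#' Builds a cyclic cubic regression spline basis over a day-of-year domain.
#' The spline is parameterized by its values at the knots: with `n_knots`
#' equally spaced knots whose last knot is identified with the first
#' (periodicity), the free basis dimension is `n_knots - 1`. Periodicity
#' makes the function and its first two derivatives match at the domain
#' endpoints, which pins the fitted phenology curve to a common level at the
#' season boundaries (March and October), where no breeding activity is
#' modelled.
#'
#' The roughness penalty is the integrated squared second derivative,
#' `S = D' B^{-1} D` in the standard cyclic-spline matrices `B` (second
#' derivative continuity) and `D` (value-to-second-derivative map); it is
#' symmetric positive semidefinite with the constant function in its null
#' space.
#'
#' @param domain Numeric `c(min, max)` day interval (default days 60--304,
#'   Mar 1 -- Oct 31).
#' @param n_knots Number of knots including the duplicated endpoint
#'   (>= 4); basis dimension is `n_knots - 1`.
#' @return Object of class `cyclic_basis` with elements `knots`, `S`
#'   (penalty, `(n_knots-1) x (n_knots-1)`), `F` (map from knot values to
#'   knot second derivatives), `domain`, and `dim`.
#' @examples
#' b <- cyclic_basis(c(60, 304), 12)
#' b$dim
#' @export
cyclic_basis <- function(domain = c(60, 304), n_knots = 12) {
  if (length(domain) != 2L || diff(domain) <= 0)
    stopf("`domain` must be an increasing interval")
  if (n_knots < 4L) stopf("n_knots must be >= 4 (got %d)", n_knots)
  knots <- seq(domain[1], domain[2], length.out = n_knots)
  k <- n_knots - 1L                       # free coefficients
  h <- diff(knots)                        # length k
  hl <- h[c(k, seq_len(k - 1L))]          # h_{i-1}, cyclic
  B <- D <- matrix(0, k, k)
  for (i in seq_len(k)) {
    im <- if (i == 1L) k else i - 1L
    ip <- if (i == k) 1L else i + 1L
    B[i, i] <- (hl[i] + h[i]) / 3
    B[i, im] <- B[im, i] <- hl[i] / 6
    D[i, i] <- -(1 / hl[i] + 1 / h[i])
    D[i, im] <- 1 / hl[i]
    D[i, ip] <- D[i, ip] + 1 / h[i]
  }
  Fm <- solve(B, D)
  S <- crossprod(D, Fm)
  S <- (S + t(S)) / 2
  structure(list(knots = knots, h = h, F = Fm, S = S,
                 domain = domain, dim = k),
            class = "cyclic_basis")
}

#' @export
print.cyclic_basis <- function(x, ...) {
  cat(sprintf("Cyclic cubic regression spline basis: %d knots over [%g, %g], dimension %d\n",
              length(x$knots), x$domain[1], x$domain[2], x$dim))
  invisible(x)
}

#' Evaluate a cyclic spline basis
#'
#' Returns the design matrix mapping the `n_knots - 1` knot-value
#' coefficients to function values at `x`. Points are wrapped into the
#' domain by periodicity.
#'
#' @param basis A [cyclic_basis()].
#' @param x Numeric vector of evaluation points.
#' @return Matrix `length(x) x basis$dim`; `X %*% beta` evaluates the spline
#'   with knot values `beta`.
#' @export
basis_matrix <- function(basis, x) {
  stopifnot(inherits(basis, "cyclic_basis"))
  kn <- basis$knots
  k <- basis$dim
  period <- basis$domain[2] - basis$domain[1]
  x <- basis$domain[1] + (x - basis$domain[1]) %% period
  i <- findInterval(x, kn, rightmost.closed = TRUE)
  i[i > k] <- k
  h <- basis$h[i]
  xl <- kn[i]; xr <- kn[i + 1L]
  am <- (xr - x) / h
  ap <- (x - xl) / h
  cm <- ((xr - x)^3 / h - h * (xr - x)) / 6
  cp <- ((x - xl)^3 / h - h * (x - xl)) / 6
  ip <- ifelse(i == k, 1L, i + 1L)        # wrap last knot onto the first
  X <- matrix(0, length(x), k)
  idx <- seq_along(x)
  X[cbind(idx, i)] <- X[cbind(idx, i)] + am
  X[cbind(idx, ip)] <- X[cbind(idx, ip)] + ap
  X <- X + cm * basis$F[i, , drop = FALSE] + cp * basis$F[ip, , drop = FALSE]
  X
}
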