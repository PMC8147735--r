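#' Concentration curve points
#'
#' Computes the concentration curve of a non-negative health indicator:
#' respondents are ordered poorest first by their fractional rank and the
#' curve traces cumulative normalized weight (`p`) against cumulative
#' weighted share of the indicator (`L`), starting at (0, 0) and ending
#' at (1, 1).  Twice the signed area between the 45-degree line and the
#' curve is the concentration index (see [ci_from_curve_area()]).
#'
#' @param x a `"concindex"` fit, or a numeric indicator vector `h`.
#' @param r fractional ranks (only for the default method).
#' @param w positive weights (only for the default method; default equal).
#' @param ... unused.
#' @return a `data.frame` with columns `p` and `L`, one row per
#'   respondent plus the (0, 0) origin.
#' @export
concentration_curve <- function(x, ...) UseMethod("concentration_curve")

#' @rdname concentration_curve
#' @export
concentration_curve.concindex <- function(x, ...) {
  concentration_curve.default(x$sample$h, x$sample$r, x$sample$w)
}

#' @rdname concentration_curve
#' @export
concentration_curve.default <- function(x, r, w = NULL, ...) {
  h <- as.numeric(x)
  n <- length(h)
  if (n == 0L) stop("empty input")
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(r) == n, length(w) == n)
  if (anyNA(h) || anyNA(r) || anyNA(w)) stop("missing values are not allowed")
  if (any(h < 0)) stop("concentration curve is undefined for negative indicator values")
  if (any(w <= 0)) stop("all weights must be strictly positive")
  total_h <- sum(w * h)
  if (total_h <= 0) stop("indicator total must be positive for share interpretation")
  o <- order(r)
  p <- cumsum(w[o]) / sum(w)
  L <- cumsum(w[o] * h[o]) / total_h
  data.frame(p = c(0, p), L = c(0, L))
}

#' Concentration index from the curve area
#'
#' Recovers the concentration index as twice the area between the
#' 45-degree equality line and the concentration curve (positive when
#' the curve lies below the diagonal, i.e. pro-rich), integrating the
#' piecewise-linear curve by the trapezoid rule.  This is an independent
#' geometric route to the same quantity as [ci_direct()]; the two agree
#' up to O(1/n) discretization error.
#'
#' @param points a `data.frame` with columns `p` and `L` as returned by
#'   [concentration_curve()]; `p` must be non-decreasing from 0 to 1.
#' @return twice the signed area, a single number.
#' @export
ci_from_curve_area <- function(points) {
  stopifnot(is.data.frame(points), all(c("p", "L") %in% names(points)))
  p <- points$p
  L <- points$L
  if (length(p) < 2L) stop("need at least two curve points")
  if (is.unsorted(p)) stop("curve points must be sorted by cumulative population share")
  d <- p - L
  2 * sum(diff(p) * (d[-1L] + d[-length(d)]) / 2)
}
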