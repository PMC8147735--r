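#' Concentration index by the weighted covariance formula
#'
#' The standard concentration index of a health variable `h` against a
#' socioeconomic ordering is \eqn{CI = 2\,cov_w(h, r)/\mu}, where `r` is
#' the weighted fractional rank (poorest to richest), the covariance is
#' taken with weights normalized to sum 1, and \eqn{\mu} is the weighted
#' mean of `h`.  Equivalently \eqn{(2/\mu)\sum \tilde w_i h_i r_i - 1}
#' since the weighted mean of `r` is 1/2.  Positive values indicate a
#' pro-rich distribution.
#'
#' @param h numeric vector of indicator values.
#' @param r fractional ranks from [fractional_rank()].
#' @param w positive weights (default equal).
#' @return the concentration index, a single number.
#' @seealso [ci_regression()] for the same point estimate with a standard
#'   error, [concindex()] for the full fit.
#' @export
ci_direct <- function(h, r, w = NULL) {
  n <- length(h)
  if (n < 2L) stop("at least two observations are required (rank has zero variance)")
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(r) == n, length(w) == n)
  if (anyNA(h) || anyNA(r) || anyNA(w)) stop("missing values are not allowed")
  if (any(w <= 0)) stop("all weights must be strictly positive")
  wt <- w / sum(w)
  mu <- sum(wt * h)
  if (mu == 0) stop("undefined index: weighted mean of the indicator is zero")
  rbar <- sum(wt * r)
  2 * sum(wt * (h - mu) * (r - rbar)) / mu
}

#' Concentration index by the convenient weighted regression
#'
#' Estimates the concentration index as the slope of the weighted
#' least-squares regression of \eqn{y_i = 2\sigma_r^2 h_i / \mu} on the
#' fractional rank \eqn{r_i} with weights `w`, where \eqn{\sigma_r^2} is
#' the weighted variance of the ranks.  The slope is algebraically
#' identical to [ci_direct()]; the conventional WLS slope standard error
#' provides inference.
#'
#' @inheritParams ci_direct
#' @return list with elements `value` (slope), `se` (WLS standard error;
#'   `NA` when n < 3), `mu`, and `n`.
#' @export
ci_regression <- function(h, r, w = NULL) {
  n <- length(h)
  if (n < 2L) stop("at least two observations are required (rank has zero variance)")
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(r) == n, length(w) == n)
  if (anyNA(h) || anyNA(r) || anyNA(w)) stop("missing values are not allowed")
  if (any(w <= 0)) stop("all weights must be strictly positive")
  wt <- w / sum(w)
  mu <- sum(wt * h)
  if (mu == 0) stop("undefined index: weighted mean of the indicator is zero")
  rbar <- sum(wt * r)
  s2r <- sum(wt * (r - rbar)^2)
  if (s2r == 0) stop("zero-variance ranks: ranking variable is degenerate")
  y <- 2 * s2r * h / mu
  ybar <- sum(wt * y)
  sxx <- sum(w * (r - rbar)^2)
  slope <- sum(w * (r - rbar) * (y - ybar)) / sxx
  if (n >= 3L) {
    resid <- (y - ybar) - slope * (r - rbar)
    sigma2 <- sum(w * resid^2) / (n - 2)
    se <- sqrt(sigma2 / sxx)
  } else {
    se <- NA_real_
  }
  list(value = slope, se = se, mu = mu, n = n)
}

#' Wagstaff normalization of a concentration index
#'
#' For a bounded health variable with theoretical bounds (a, b) the
#' attainable range of the standard concentration index shrinks as the
#' mean approaches a bound.  The Wagstaff correction restores the full
#' \[-1, 1\] range: the indicator is rescaled to \[0, 1\]
#' (\eqn{s = (h-a)/(b-a)}) and the index of `s` is divided by
#' \eqn{1 - \mu_s}.  In closed form,
#' \deqn{CI_W = CI \cdot \mu (b-a) / ((\mu-a)(b-\mu)),}
#' which for a binary indicator (a, b) = (0, 1) reduces to
#' \eqn{CI / (1-\mu)}.
#'
#' @param ci standard concentration index.
#' @param mu weighted mean of the indicator (strictly between the bounds).
#' @param bounds length-2 numeric, the theoretical minimum and maximum of
#'   the indicator (defaults to binary `c(0, 1)`).
#' @return the normalized concentration index.
#' @examples
#' wagstaff_normalize(0.5, 0.5)             # 1 (perfect binary concentration)
#' wagstaff_normalize(0.1, 2, c(0, 4))      # 0.2 (a 0-4 composite score)
#' @export
wagstaff_normalize <- function(ci, mu, bounds = c(0, 1)) {
  ci * wagstaff_factor(mu, bounds)
}

# multiplier taking the standard CI to the Wagstaff-normalized CI
wagstaff_factor <- function(mu, bounds) {
  if (length(bounds) != 2L || anyNA(bounds) || bounds[1] >= bounds[2]) {
    stop("`bounds` must be two numbers (a, b) with a < b")
  }
  a <- bounds[1]; b <- bounds[2]
  if (mu < a || mu > b) stop("mean lies outside the stated bounds")
  if (mu == a || mu == b) {
    stop("degenerate indicator: mean equals a theoretical bound, ",
         "Wagstaff normalization is undefined")
  }
  mu * (b - a) / ((mu - a) * (b - mu))
}

#' Fit a concentration index
#'
#' The main fitting function: ranks respondents on a socioeconomic
#' variable, estimates the concentration index of a health indicator by
#' the convenient weighted regression, optionally applies the Wagstaff
#' normalization for bounded indicators (the standard error is carried
#' through by the delta method with the mean held fixed), and classifies
#' the estimate by sign (pro-rich / pro-poor), statistical significance
#' (two-sided z-test), and practical relevance (|CI| at or above a
#' threshold, 0.2 by default).
#'
#' @param x for the default method, a numeric vector of indicator values
#'   `h`; alternatively a one-sided call via the formula method.
#' @param ranker socioeconomic ranking variable (e.g. wealth index), same
#'   length as `x`.  Ignored when `rank` is supplied.
#' @param weights positive sampling weights (default equal).
#' @param rank optional precomputed fractional ranks in (0, 1); when
#'   supplied, `ranker` is not used.
#' @param bounds theoretical (min, max) of the indicator.  Defaults to
#'   `c(0, 1)` when all values lie in \{0, 1\}; otherwise required if
#'   `normalize = TRUE`.
#' @param normalize apply the Wagstaff normalization? Default `TRUE`.
#' @param alpha two-sided significance level for the z-test (default 0.05).
#' @param relevance threshold on |CI| for a "relevant degree" of
#'   inequality (default 0.2).
#' @param na.action `"omit"` (drop incomplete cases, the default) or
#'   `"fail"`.
#' @param label optional character label carried into printed output.
#' @param ... passed between methods.
#' @return an object of class `"concindex"`: a list with components
#'   `value`, `se`, `ci95` (value +/- 1.96 se), `mu`, `n`, `bounds`,
#'   `normalized`, `raw` (unnormalized value and se), `pro_rich`,
#'   `significant`, `relevant`, `alpha`, `relevance`, `label`, and the
#'   aligned analysis vectors in `sample` (`h`, `r`, `w`).
#' @examples
#' fit <- concindex(c(0, 0, 1, 1), ranker = 1:4)
#' fit            # Wagstaff CI = 1: perfectly pro-rich binary toy
#' coef(fit)
#' summary(fit)
#' @export
concindex <- function(x, ...) UseMethod("concindex")

#' @rdname concindex
#' @export
concindex.default <- function(x, ranker = NULL, weights = NULL, rank = NULL,
                              bounds = NULL, normalize = TRUE, alpha = 0.05,
                              relevance = 0.2, na.action = c("omit", "fail"),
                              label = NULL, ...) {
  na.action <- match.arg(na.action)
  h <- as.numeric(x)
  n0 <- length(h)
  if (is.null(rank) && is.null(ranker)) {
    stop("supply either `ranker` (a ranking variable) or `rank` (precomputed ranks)")
  }
  rv <- if (is.null(rank)) as.numeric(ranker) else as.numeric(rank)
  if (length(rv) != n0) stop("indicator and ranking vectors must have equal length")
  w <- if (is.null(weights)) rep(1, n0) else as.numeric(weights)
  if (length(w) != n0) stop("`weights` must match the indicator length")
  keep <- !(is.na(h) | is.na(rv) | is.na(w))
  if (na.action == "fail" && !all(keep)) stop("missing values in the analysis variables")
  h <- h[keep]; rv <- rv[keep]; w <- w[keep]
  if (length(h) < 2L) stop("fewer than two complete cases")
  r <- if (is.null(rank)) fractional_rank(rv, w) else rv
  if (any(r <= 0) || any(r >= 1)) stop("ranks must lie strictly inside (0, 1)")

  fit <- ci_regression(h, r, w)
  value <- fit$value
  se <- fit$se
  mu <- fit$mu
  if (is.null(bounds)) {
    if (all(h %in% c(0, 1))) {
      bounds <- c(0, 1)
    } else if (normalize) {
      stop("`bounds` is required to Wagstaff-normalize a non-binary indicator")
    } else {
      bounds <- range(h)
    }
  }
  # a constant indicator carries no inequality: the index is exactly 0
  # (normalized or not, even when the mean sits on a bound) and the
  # regression provides no inference, so no significance is claimed
  constant_h <- min(h) == max(h)
  raw <- list(value = value, se = se)
  if (constant_h) {
    value <- 0
    se <- NA_real_
    raw <- list(value = 0, se = NA_real_)
  } else if (normalize) {
    f <- wagstaff_factor(mu, bounds)
    value <- value * f
    se <- se * f
  }
  zcrit <- stats::qnorm(1 - alpha / 2)
  out <- list(
    value = value,
    se = se,
    ci95 = c(value - 1.96 * se, value + 1.96 * se),
    mu = mu,
    n = fit$n,
    bounds = bounds,
    normalized = normalize,
    raw = raw,
    pro_rich = value > 0,
    significant = if (constant_h) FALSE
                  else if (is.na(se)) NA
                  else abs(value / se) > zcrit,
    relevant = abs(value) >= relevance,
    alpha = alpha,
    relevance = relevance,
    label = label,
    sample = list(h = h, r = r, w = w),
    n_dropped = n0 - fit$n
  )
  class(out) <- "concindex"
  out
}

#' @rdname concindex
#' @param formula a two-sided formula `indicator ~ ranker`.
#' @param data a `data.frame` in which to evaluate `formula` and `weights`.
#' @export
concindex.formula <- function(formula, data, weights = NULL, ...) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  if (ncol(mf) != 2L) stop("formula must have the form indicator ~ ranker")
  w <- eval(substitute(weights), data, parent.frame())
  concindex.default(mf[[1L]], ranker = mf[[2L]], weights = w,
                    label = deparse(formula), ...)
}

#' @export
print.concindex <- function(x, digits = 3, ...) {
  kind <- if (x$normalized) "Wagstaff-normalized concentration index"
          else "Concentration index"
  cat(kind, if (!is.null(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  cat(sprintf("  CI = %.*f  (se %.*f, 95%% CI %.*f to %.*f)\n",
              digits, x$value, digits, x$se,
              digits, x$ci95[1], digits, x$ci95[2]))
  cat(sprintf("  mean = %.*f on bounds [%g, %g], n = %d\n",
              digits, x$mu, x$bounds[1], x$bounds[2], x$n))
  cat(sprintf("  %s, %s at alpha = %g, %s (|CI| %s %g)\n",
              if (isTRUE(x$pro_rich)) "pro-rich" else "pro-poor",
              if (isTRUE(x$significant)) "significant" else "not significant",
              x$alpha,
              if (x$relevant) "relevant" else "not relevant",
              if (x$relevant) ">=" else "<", x$relevance))
  invisible(x)
}

#' @export
coef.concindex <- function(object, ...) c(CI = object$value)

#' @export
confint.concindex <- function(object, parm = "CI", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- matrix(c(object$value - z * object$se, object$value + z * object$se),
                nrow = 1,
                dimnames = list("CI", sprintf("%.1f %%", c((1 - level) / 2,
                                                           1 - (1 - level) / 2) * 100)))
  out
}

#' @export
summary.concindex <- function(object, ...) {
  out <- data.frame(
    label = if (is.null(object$label)) NA_character_ else object$label,
    n = object$n,
    mu = object$mu,
    value = object$value,
    se = object$se,
    ci_low = object$ci95[1],
    ci_high = object$ci95[2],
    normalized = object$normalized,
    pro_rich = object$pro_rich,
    significant = object$significant,
    relevant = object$relevant,
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary.concindex", "data.frame")
  out
}

#' @export
print.summary.concindex <- function(x, digits = 4, ...) {
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Plot a fitted concentration index as a concentration curve
#'
#' Draws the concentration curve (cumulative indicator share against
#' cumulative population share, poorest first) with the 45-degree
#' equality line.  A curve below the diagonal corresponds to a pro-rich
#' distribution (positive index).
#'
#' @param x a `"concindex"` fit.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.concindex <- function(x, ...) {
  pts <- concentration_curve(x)
  plot(pts$p, pts$L, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "cumulative population share (poorest first)",
       ylab = "cumulative indicator share",
       main = if (is.null(x$label)) "Concentration curve" else x$label, ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(pts)
}
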