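#' Weighted fractional rank
#'
#' Computes the weighted fractional rank of each observation in a
#' socioeconomic ordering variable: after sorting ascending, observation
#' \eqn{i} receives \eqn{r_i = (W_{<i} + w_i/2) / W}, where \eqn{W_{<i}}
#' is the total weight of strictly smaller values and \eqn{W} the total
#' weight.  Tied values share one block rank,
#' \eqn{(W_{<block} + W_{block}/2)/W}, which makes the rank (and every
#' downstream concentration index) invariant to the input order of tied
#' observations.  Ranks lie strictly inside (0, 1) and their weighted
#' mean is exactly 1/2.
#'
#' @param x numeric vector, the ranking variable (e.g. a wealth index).
#' @param w positive sampling weights, recycled to `rep(1, length(x))`
#'   when `NULL`.
#' @return numeric vector of ranks in (0, 1), in the original order of `x`.
#' @examples
#' fractional_rank(c(10, 20, 30), c(1, 1, 2)) # 0.125 0.375 0.750
#' fractional_rank(c(5, 5, 10))               # ties share a block rank
#' @export
fractional_rank <- function(x, w = NULL) {
  n <- length(x)
  if (n == 0L) stop("empty input: cannot rank zero observations")
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n) stop("`x` and `w` must have equal length")
  if (anyNA(x) || anyNA(w)) stop("missing values are not allowed in `x` or `w`")
  if (any(w <= 0)) stop("all weights must be strictly positive")
  o <- order(x)
  xs <- x[o]
  ws <- w[o]
  W <- sum(ws)
  cw <- cumsum(ws)
  block <- cumsum(c(TRUE, xs[-1L] != xs[-n]))
  w_block <- stats::ave(ws, block, FUN = sum)
  cw_block_end <- stats::ave(cw, block, FUN = max)
  r_sorted <- (cw_block_end - w_block / 2) / W
  r <- numeric(n)
  r[o] <- r_sorted
  r
}

#' Normalize a wealth index within countries
#'
#' Rescales a survey-specific wealth index to a common within-country
#' scale so that values can afterwards be placed on a cross-country scale
#' (see [scale_wealth_gdp()]).  The default is min-max rescaling to
#' \[0, 1\]; a z-score alternative is available.  A degenerate country in
#' which all households share one wealth value is mapped to 0.5 (min-max)
#' or 0 (z-score) with a warning.
#'
#' @param wealth numeric vector of household wealth-index values.
#' @param country character vector of country codes, same length.
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return numeric vector of normalized wealth, same order as input.
#' @export
normalize_wealth <- function(wealth, country, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  if (length(wealth) != length(country)) {
    stop("`wealth` and `country` must have equal length")
  }
  if (anyNA(wealth)) stop("missing wealth values are not allowed here")
  out <- numeric(length(wealth))
  for (cc in unique(country)) {
    idx <- which(country == cc)
    x <- wealth[idx]
    rng <- range(x)
    if (rng[1] == rng[2]) {
      warning(sprintf("constant wealth index in country '%s'; assigning %s",
                      cc, if (method == "minmax") "0.5" else "0"))
      out[idx] <- if (method == "minmax") 0.5 else 0
    } else if (method == "minmax") {
      out[idx] <- (x - rng[1]) / (rng[2] - rng[1])
    } else {
      out[idx] <- (x - mean(x)) / stats::sd(x)
    }
  }
  out
}

#' Scale normalized wealth by per-capita GDP (PPP)
#'
#' Places within-country normalized wealth on a single cross-country
#' scale by multiplying each respondent's normalized wealth by her
#' country's per-capita GDP at purchasing-power parity.  The product is
#' used only as a ranking variable for the inter-country concentration
#' index, so only the ordering it induces matters.
#'
#' @param norm_wealth numeric vector in \[0, 1\] from [normalize_wealth()].
#' @param country character vector of country codes.
#' @param meta country metadata `data.frame` with columns `country_code`
#'   and `pc_gdp_ppp` (see [read_country_meta()]).
#' @return numeric vector `norm_wealth * pc_gdp_ppp[country]`.
#' @export
scale_wealth_gdp <- function(norm_wealth, country, meta) {
  stopifnot(is.data.frame(meta), all(c("country_code", "pc_gdp_ppp") %in% names(meta)))
  m <- match(country, meta$country_code)
  if (anyNA(m)) {
    stop("no metadata for country: ",
         paste(unique(country[is.na(m)]), collapse = ", "))
  }
  gdp <- meta$pc_gdp_ppp[m]
  if (anyNA(gdp) || any(gdp <= 0)) {
    bad <- unique(country[is.na(gdp) | gdp <= 0])
    stop("missing or non-positive pc_gdp_ppp for country: ",
         paste(bad, collapse = ", "))
  }
  norm_wealth * gdp
}

#' Normalize survey weights for intra- or inter-country analysis
#'
#' In `"intra"` mode weights are rescaled to mean 1 within each
#' country-survey (country x program x year), so each survey's weight sum
#' equals its respondent count; the concentration index is invariant to
#' this rescaling, but reported effective sample sizes become comparable.
#' In `"inter"` mode weights are first rescaled to sum 1 within each
#' country and then multiplied by the country's share of the regional
#' female 15-24 population, so each country's total analysis weight
#' equals its population share and the grand total is 1.
#'
#' @param w positive sampling weights.
#' @param country character vector of country codes.
#' @param survey optional survey label (e.g. `paste(program, year)`) used
#'   to define country-survey cells in `"intra"` mode; ignored in
#'   `"inter"` mode.
#' @param mode `"intra"` or `"inter"`.
#' @param meta country metadata with `country_code` and `pop_share`
#'   (required in `"inter"` mode; shares over the countries present must
#'   sum to 1 within 1e-9).
#' @return numeric vector of rescaled weights.
#' @export
normalize_survey_weights <- function(w, country, survey = NULL,
                                     mode = c("intra", "inter"), meta = NULL) {
  mode <- match.arg(mode)
  if (any(is.na(w)) || any(w <= 0)) stop("all weights must be positive and non-missing")
  if (length(w) != length(country)) stop("`w` and `country` must have equal length")
  if (mode == "intra") {
    cell <- if (is.null(survey)) country else paste(country, survey, sep = "\r")
    return(w / stats::ave(w, cell, FUN = mean))
  }
  if (is.null(meta) || !all(c("country_code", "pop_share") %in% names(meta))) {
    stop("inter-country weight normalization requires `meta` with pop_share")
  }
  m <- match(country, meta$country_code)
  if (anyNA(m)) {
    stop("no metadata for country: ",
         paste(unique(country[is.na(m)]), collapse = ", "))
  }
  share <- meta$pop_share[m]
  if (anyNA(share)) {
    stop("missing pop_share for country: ",
         paste(unique(country[is.na(share)]), collapse = ", "))
  }
  present <- meta$pop_share[meta$country_code %in% unique(country)]
  if (abs(sum(present) - 1) > 1e-9) {
    stop(sprintf("pop_share over the analysis countries sums to %.12f, not 1",
                 sum(present)))
  }
  w / stats::ave(w, country, FUN = sum) * share
}
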