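#' Define a synthetic country survey scenario
#'
#' A scenario fixes everything needed to draw one country's respondent
#' table with a known-truth socioeconomic gradient.  Each binary
#' indicator follows the linear-in-rank probability model
#' \eqn{P(h = 1 | r) = a + b r}, where `r` is the respondent's true
#' fractional position in the country's wealth distribution; under this
#' model the population standard concentration index is exactly
#' \eqn{b / (6\mu)} with \eqn{\mu = a + b/2} (see [true_ci_linear()]),
#' which gives an analytic surface against which the estimator is
#' validated.  The four knowledge items are drawn the same way and summed
#' into the 0-4 composite.
#'
#' @param country country code.
#' @param n number of respondents (>= 2).
#' @param pc_gdp_ppp per-capita GDP (PPP), positive.
#' @param pop_share share of the regional female 15-24 population.
#' @param heard,tested,condom length-2 numeric `c(a, b)` gradients for the
#'   binary indicators, or `NULL` when the indicator is absent from the
#'   country's survey.
#' @param knowledge 4 x 2 matrix of per-item `(a, b)` gradients.
#' @param wealth_law `"lognormal"` or `"uniform"` household wealth
#'   distribution.
#' @param wealth_sigma log-sd of the lognormal wealth law (default 0.8).
#' @param weight_law `"equal"` or `"gamma"` sampling weights.
#' @param weight_shape shape of the mean-1 gamma weight law (default 4).
#' @param missing named MCAR missingness rates in \[0, 1) for `heard`,
#'   `knowledge`, `tested`, `condom`.
#' @param program,year survey labels.
#' @return an object of class `"country_scenario"` (a validated list).
#' @export
country_scenario <- function(country, n, pc_gdp_ppp, pop_share,
                             heard = c(0.9, 0.05),
                             knowledge = matrix(rep(c(0.6, 0.2), each = 4), ncol = 2),
                             tested = c(0.3, 0.1),
                             condom = c(0.25, 0.1),
                             wealth_law = c("lognormal", "uniform"),
                             wealth_sigma = 0.8,
                             weight_law = c("equal", "gamma"),
                             weight_shape = 4,
                             missing = c(heard = 0, knowledge = 0,
                                         tested = 0.05, condom = 0.42),
                             program = "MICS", year = "2015") {
  wealth_law <- match.arg(wealth_law)
  weight_law <- match.arg(weight_law)
  if (n < 2) stop("scenario requires n >= 2")
  if (pc_gdp_ppp <= 0) stop("pc_gdp_ppp must be positive")
  check_ab <- function(ab, what) {
    if (is.null(ab)) return(invisible(NULL))
    a <- ab[[1]]; b <- ab[[2]]
    if (!(a > 0 && a < 1 && a + b > 0 && a + b < 1)) {
      stop(sprintf("invalid gradient for %s: need 0 < a < 1 and 0 < a + b < 1 (a=%g, b=%g)",
                   what, a, b))
    }
  }
  check_ab(heard, "heard")
  check_ab(tested, "tested")
  check_ab(condom, "condom")
  knowledge <- as.matrix(knowledge)
  if (!all(dim(knowledge) == c(4, 2))) stop("`knowledge` must be a 4 x 2 (a, b) matrix")
  for (j in 1:4) check_ab(knowledge[j, ], paste0("knowledge item ", j))
  miss <- c(heard = 0, knowledge = 0, tested = 0, condom = 0)
  miss[names(missing)] <- missing
  if (any(miss < 0 | miss >= 1)) stop("missing rates must lie in [0, 1)")
  structure(list(country = country, n = as.integer(n),
                 pc_gdp_ppp = pc_gdp_ppp, pop_share = pop_share,
                 heard = heard, knowledge = knowledge,
                 tested = tested, condom = condom,
                 wealth_law = wealth_law, wealth_sigma = wealth_sigma,
                 weight_law = weight_law, weight_shape = weight_shape,
                 missing = miss, program = program, year = year),
            class = "country_scenario")
}

#' @export
print.country_scenario <- function(x, ...) {
  cat(sprintf("Country scenario '%s' (%s %s): n = %d, GDP-PPP = %g, pop share = %.4f\n",
              x$country, x$program, x$year, x$n, x$pc_gdp_ppp, x$pop_share))
  invisible(x)
}

#' Population concentration index under the linear-in-rank model
#'
#' For a binary indicator with \eqn{P(h=1|r) = a + b r} on \eqn{r \in
#' (0,1)}, the standard concentration index is
#' \eqn{(2/\mu)\int_0^1 r(a+br)\,dr - 1 = b/(6\mu)} with
#' \eqn{\mu = a + b/2}; the Wagstaff-normalized value divides by
#' \eqn{1 - \mu}.
#'
#' @param a intercept, `0 < a < 1`.
#' @param b slope (may be negative), with `0 < a + b < 1`.
#' @param normalized return the Wagstaff-normalized truth? Default `FALSE`.
#' @return the population concentration index.
#' @export
true_ci_linear <- function(a, b, normalized = FALSE) {
  mu <- a + b / 2
  if (mu <= 0 || mu >= 1) stop("mean a + b/2 must lie strictly inside (0, 1)")
  ci <- b / (6 * mu)
  if (normalized) ci / (1 - mu) else ci
}

#' Population concentration index of the 0-4 knowledge score
#'
#' The composite score is the sum of four linear-in-rank items, so
#' \eqn{cov(S, r) = \sum_j b_j / 12} and the standard index is
#' \eqn{\sum_j b_j / (6 \mu_S)} with \eqn{\mu_S = \sum_j (a_j + b_j/2)}.
#' Wagstaff normalization uses the theoretical bounds (0, 4), i.e. a
#' factor \eqn{4/(4 - \mu_S)}.
#'
#' @param items 4 x 2 matrix of per-item `(a, b)`.
#' @param normalized return the Wagstaff-normalized truth?
#' @return the population concentration index of the composite.
#' @export
true_ci_score <- function(items, normalized = FALSE) {
  items <- as.matrix(items)
  mu <- sum(items[, 1] + items[, 2] / 2)
  if (mu <= 0 || mu >= 4) stop("score mean must lie strictly inside (0, 4)")
  ci <- sum(items[, 2]) / (6 * mu)
  if (normalized) ci * 4 / (4 - mu) else ci
}

#' Draw one synthetic country survey
#'
#' Draws household wealth from the scenario's wealth law, computes each
#' respondent's true fractional position `r` in that law (its CDF), draws
#' sampling weights independently of wealth and outcomes, draws every
#' indicator Bernoulli(a + b r), sums the four knowledge items, draws
#' ages uniformly on 15-24, and applies missingness completely at random.
#' Reproducible: the same seed yields identical records.
#'
#' @param scenario a [country_scenario()].
#' @param seed integer seed.
#' @return a canonical respondent `data.frame` (see [read_survey_table()]).
#' @export
simulate_survey <- function(scenario, seed) {
  stopifnot(inherits(scenario, "country_scenario"))
  set.seed(seed)
  n <- scenario$n
  if (scenario$wealth_law == "lognormal") {
    wealth <- stats::rlnorm(n, meanlog = 0, sdlog = scenario$wealth_sigma)
    r <- stats::plnorm(wealth, meanlog = 0, sdlog = scenario$wealth_sigma)
  } else {
    wealth <- stats::runif(n)
    r <- wealth
  }
  w <- if (scenario$weight_law == "equal") {
    rep(1, n)
  } else {
    stats::rgamma(n, shape = scenario$weight_shape,
                  rate = scenario$weight_shape)
  }
  draw <- function(ab) {
    if (is.null(ab)) return(rep(NA_real_, n))
    stats::rbinom(n, 1L, ab[[1]] + ab[[2]] * r)
  }
  mcar <- function(x, rate) {
    if (rate > 0) x[stats::runif(n) < rate] <- NA_real_
    x
  }
  out <- data.frame(
    country = scenario$country, program = scenario$program,
    year = scenario$year, weight = w, wealth = wealth,
    age = sample(15:24, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  out$heard <- mcar(draw(scenario$heard), scenario$missing[["heard"]])
  for (j in 1:4) {
    out[[.knowledge_items[j]]] <- mcar(draw(scenario$knowledge[j, ]),
                                       scenario$missing[["knowledge"]])
  }
  out$tested <- mcar(draw(scenario$tested), scenario$missing[["tested"]])
  out$condom <- mcar(draw(scenario$condom), scenario$missing[["condom"]])
  out
}

#' Draw a multi-country synthetic region
#'
#' Draws every scenario's survey with a country seed derived
#' deterministically from the master seed, concatenates the records, and
#' assembles the matching country-metadata table together with the
#' analytic ground-truth concentration indices implied by each scenario.
#'
#' @param scenarios list of [country_scenario()] objects with distinct
#'   country codes and pop_shares summing to 1 (within 1e-9).
#' @param seed master integer seed.
#' @return a list: `records` (pooled canonical table), `meta`
#'   (`country_code`, `pc_gdp_ppp`, `pop_share`), and `truth` (a
#'   `data.frame` of per-country analytic standard and Wagstaff indices
#'   per indicator).
#' @export
simulate_region <- function(scenarios, seed) {
  codes <- vapply(scenarios, function(s) s$country, character(1))
  if (anyDuplicated(codes)) {
    stop("duplicate country codes: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  }
  shares <- vapply(scenarios, function(s) s$pop_share, numeric(1))
  if (abs(sum(shares) - 1) > 1e-9) {
    stop(sprintf("pop_shares sum to %.12f, not 1", sum(shares)))
  }
  set.seed(seed)
  country_seeds <- sample.int(.Machine$integer.max - 1L, length(scenarios))
  records <- do.call(rbind, Map(simulate_survey, scenarios, country_seeds))
  rownames(records) <- NULL
  meta <- data.frame(
    country_code = codes,
    pc_gdp_ppp = vapply(scenarios, function(s) s$pc_gdp_ppp, numeric(1)),
    pop_share = shares,
    stringsAsFactors = FALSE
  )
  truth_one <- function(s) {
    tci <- function(ab, norm) if (is.null(ab)) NA_real_ else true_ci_linear(ab[1], ab[2], norm)
    data.frame(
      country = s$country,
      heard = tci(s$heard, FALSE), heard_w = tci(s$heard, TRUE),
      knowledge = true_ci_score(s$knowledge, FALSE),
      knowledge_w = true_ci_score(s$knowledge, TRUE),
      tested = tci(s$tested, FALSE), tested_w = tci(s$tested, TRUE),
      condom = tci(s$condom, FALSE), condom_w = tci(s$condom, TRUE),
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, lapply(scenarios, truth_one))
  rownames(truth) <- NULL
  list(records = records, meta = meta, truth = truth)
}

# Default study region: 20 Latin-American/Caribbean-style countries.
# Indicator means and within-country Wagstaff gradients encode the
# reference multi-country survey setting the package emulates;
# per-capita GDP-PPP and female-15-24 population sizes (thousands) are
# plausible World-Bank-era values for the survey years.  Survey sizes
# are the reference totals, rescaled by lac_scenarios().
lac_reference_table <- function() {
  tab <- utils::read.csv(text = "
country,program,year,n_obs,gdp,pop,heard_pct,know_mean,test_pct,condom_pct,ci_heard,ci_know,ci_test,ci_condom
Argentina,MICS,2011,8158,19500,3300,97.20,3.35,26.64,NA,0.447,0.205,0,NA
Barbados,MICS,2012,388,15000,18,99.82,3.67,36.55,56.66,0,0,-0.135,0
Belize,MICS,2015/16,1771,8200,37,90.89,3.04,35.96,33.51,0.509,0.303,0.072,0.295
Bolivia,DHS,2008,6335,5000,1070,85.43,2.59,NA,NA,0.667,0.425,NA,NA
Colombia,DHS,2015,15139,13500,4000,97.21,3.07,30.72,30.28,0.656,0.155,-0.162,0.244
CostaRica,MICS,2011,1720,13900,390,98.93,3.27,23.08,33.81,0.586,0.327,-0.160,0.136
Cuba,MICS,2010/11,2740,12500,680,99.77,3.52,48.80,54.24,0,0.050,0.156,0.063
DominicanRep,MICS,2013,11691,12500,950,98.99,3.31,37.78,26.55,0.587,0.220,-0.160,0.230
ElSalvador,MICS,2014,5102,7500,620,98.66,3.01,29.19,21.66,0.450,0.217,0,0.201
Guatemala,DHS,2014/15,10598,7700,1750,88.78,1.77,24.13,10.87,0.627,0.249,0.134,0.444
Guyana,DHS,2014,3666,7200,75,97.33,2.58,47.45,32.15,0.447,0.120,0,0.165
Haiti,DHS,2012,6272,1700,1120,99.64,2.26,36.05,36.52,0.448,0.083,0.139,0.330
Honduras,DHS,2011/12,9347,4300,910,96.65,3.07,38.47,13.61,0.650,0.279,-0.046,0.317
Mexico,MICS,2015,4071,17200,10900,96.14,3.01,21.49,32.15,0.558,0.186,0.140,0.262
Panama,MICS,2013,3286,21800,320,96.45,3.04,29.50,25.76,0.822,0.325,0.058,0.223
Paraguay,MICS,2016,2641,8900,630,94.25,2.81,28.18,45.84,0.480,0.255,0,0.292
Peru,DHS,2010,7766,9900,2750,96.06,2.03,78.59,19.34,0.757,0.145,0.381,0.383
SaintLucia,MICS,2012,402,10800,15,98.89,3.58,41.13,52.01,0,0.181,0,0
Suriname,MICS,2018,2256,16200,50,93.59,3.15,25.56,24.23,0.452,0.245,-0.222,0
Uruguay,MICS,2012/13,760,19800,255,98.46,3.40,26.40,57.53,0.614,0.199,-0.285,0.279
", stringsAsFactors = FALSE, strip.white = TRUE)
  tab
}

# (mu, target Wagstaff CI) -> feasible (a, b) for the linear binary model:
# b = 6 mu (1-mu) CIw, clamped so that both a and a+b stay inside (0, 1)
# with a 2% margin.  The steepest reference gradients exceed what a
# linear probability model can represent and are truncated at the bound.
linear_gradient <- function(mu, ciw) {
  b <- 6 * mu * (1 - mu) * ciw
  cap <- 1.96 * min(mu, 1 - mu)
  b <- max(min(b, cap), -cap)
  c(a = mu - b / 2, b = b)
}

#' Default multi-country scenario set
#'
#' Builds the package's reference study region: 20 countries whose
#' indicator prevalences, within-country inequality gradients, relative
#' survey sizes, per-capita GDP-PPP and population shares emulate a
#' Latin-American/Caribbean multi-survey analysis of HIV knowledge and
#' behavior among women 15-24.  Gradients use the linear-in-rank model of
#' [country_scenario()], so every country carries an analytic
#' ground-truth concentration index.
#'
#' @param n_total total number of respondents across countries (default
#'   20000); per-country sizes are proportional to the reference survey
#'   sizes with a floor of 150.
#' @param weight_law sampling-weight law passed to every scenario
#'   (default `"gamma"`, unequal weights).
#' @return a list of [country_scenario()] objects (pop_shares sum to 1).
#' @export
lac_scenarios <- function(n_total = 20000, weight_law = "gamma") {
  tab <- lac_reference_table()
  tab$pop_share <- tab$pop / sum(tab$pop)
  n_i <- pmax(150L, as.integer(round(n_total * tab$n_obs / sum(tab$n_obs))))
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    grad <- function(pct, ciw) {
      if (is.na(pct)) return(NULL)
      linear_gradient(pct / 100, if (is.na(ciw)) 0 else ciw)
    }
    # four exchangeable knowledge items reproducing the composite mean
    # and its Wagstaff index: CI_std = CIw (4 - mu)/4, total slope
    # B = 6 mu CI_std, split evenly across items and clamped per item
    mu_s <- row$know_mean
    ciw_s <- if (is.na(row$ci_know)) 0 else row$ci_know
    B <- 6 * mu_s * ciw_s * (4 - mu_s) / 4
    mu_j <- mu_s / 4
    bj <- B / 4
    capj <- 1.96 * min(mu_j, 1 - mu_j)
    bj <- max(min(bj, capj), -capj)
    know <- matrix(rep(c(mu_j - bj / 2, bj), each = 4), ncol = 2)
    country_scenario(
      country = row$country, n = n_i[i],
      pc_gdp_ppp = row$gdp, pop_share = tab$pop_share[i],
      heard = grad(row$heard_pct, row$ci_heard),
      knowledge = know,
      tested = grad(row$test_pct, row$ci_test),
      condom = grad(row$condom_pct, row$ci_condom),
      wealth_law = "lognormal", weight_law = weight_law,
      program = row$program, year = row$year
    )
  })
}
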