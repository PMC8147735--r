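# Pipeline tables: weighted descriptives per country-survey, the
# country x indicator inequality matrix, and the pooled regional summary.

# analysis indicators and their theoretical bounds
default_bounds <- function() {
  list(heard = c(0, 1), knowledge = c(0, 4), tested = c(0, 1), condom = c(0, 1))
}

# attach the derived 0-4 composite as an analysis column
with_knowledge <- function(records) {
  records$knowledge <- knowledge_score(records)
  records
}

# weighted mean with naive linearization se: se^2 = sum(wt^2 (x - m)^2)
weighted_mean_se <- function(x, w) {
  wt <- w / sum(w)
  m <- sum(wt * x)
  list(mean = m, se = sqrt(sum(wt^2 * (x - m)^2)), n = length(x))
}

# direct standardization to a reference single-year age distribution:
# mean = sum_a W_a m_a over ages observed in this survey (W renormalized),
# se by the corresponding weighted combination of age-specific se's
age_standardized_mean <- function(x, w, age, std_age) {
  ages <- intersect(names(std_age), as.character(unique(age)))
  Wa <- std_age[ages] / sum(std_age[ages])
  parts <- lapply(ages, function(a) weighted_mean_se(x[age == as.integer(a)],
                                                     w[age == as.integer(a)]))
  m <- sum(Wa * vapply(parts, `[[`, numeric(1), "mean"))
  v <- sum(Wa^2 * vapply(parts, `[[`, numeric(1), "se")^2)
  list(mean = m, se = sqrt(v), n = length(x))
}

#' Weighted descriptive table by country-survey
#'
#' Computes, per country-survey (country x program x year), the weighted
#' mean of age and of each analysis indicator with a 95% normal-theory
#' interval (mean +/- 1.96 se, where se is the weighted-mean standard
#' error on that indicator's complete cases).  Binary indicators are
#' reported as percentages; the 0-4 knowledge composite on its own scale.
#' Intervals use a naive normal approximation, so percentage bounds can
#' exceed \[0, 100\] near the boundary.  Weights are rescaled to mean 1
#' within each country-survey before use.
#'
#' @param records canonical respondent `data.frame`.
#' @param age_standardize directly standardize indicator means to the
#'   pooled single-year age distribution of the full sample (off by
#'   default).  This removes differences between surveys that are due
#'   only to their age composition; age-specific cells missing from a
#'   survey are dropped and the standard weights renormalized.
#' @return a long `data.frame`: `country`, `program`, `year`, `indicator`,
#'   `n`, `mean`, `ci_low`, `ci_high` (NA rows where an indicator is
#'   entirely absent from a survey).
#' @export
descriptive_table <- function(records, age_standardize = FALSE) {
  records <- with_knowledge(records)
  records$weight <- normalize_survey_weights(
    records$weight, records$country,
    survey = paste(records$program, records$year), mode = "intra")
  vars <- c(age = 1, heard = 100, knowledge = 1, tested = 100, condom = 100)
  # pooled single-year age distribution used as the standard population
  std_age <- if (age_standardize) {
    tapply(records$weight, records$age, sum) / sum(records$weight)
  } else {
    NULL
  }
  cells <- unique(records[, c("country", "program", "year")])
  cells <- cells[order(cells$country, cells$program, cells$year), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- records[records$country == cells$country[i] &
                     records$program == cells$program[i] &
                     records$year == cells$year[i], , drop = FALSE]
    for (v in names(vars)) {
      ok <- !is.na(sub[[v]])
      if (!any(ok)) {
        rows[[length(rows) + 1L]] <- data.frame(
          cells[i, , drop = FALSE], indicator = v, n = 0L,
          mean = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      est <- if (is.null(std_age) || v == "age") {
        weighted_mean_se(sub[[v]][ok] * vars[[v]], sub$weight[ok])
      } else {
        age_standardized_mean(sub[[v]][ok] * vars[[v]], sub$weight[ok],
                              sub$age[ok], std_age)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cells[i, , drop = FALSE], indicator = v, n = est$n,
        mean = est$mean, ci_low = est$mean - 1.96 * est$se,
        ci_high = est$mean + 1.96 * est$se, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Intra-country inequality table
#'
#' Estimates, for every country and indicator, the Wagstaff-normalized
#' concentration index ranking respondents on the country's own wealth
#' index (no cross-country scaling), with intra-mode weights.  Each cell
#' is computed on the indicator's complete cases (per-indicator listwise
#' deletion).  Surveys pooled upstream (e.g. a country's MICS and DHS)
#' are analyzed together.  Cells whose indicator is absent from the
#' country's survey are `NA`.
#'
#' @param records canonical respondent `data.frame`.
#' @param meta country metadata (`country_code`, `pc_gdp_ppp`,
#'   `pop_share`); every country in `records` must appear.
#' @param indicators which indicators to tabulate (default the four
#'   analysis indicators: `heard`, `knowledge`, `tested`, `condom`).
#' @param bounds named list of theoretical (min, max) per indicator.
#' @param normalize Wagstaff-normalize (default `TRUE`).
#' @param alpha,relevance passed to [concindex()].
#' @return a long `data.frame` of class `"inequality_table"`: one row per
#'   country x indicator with `n`, `mu`, `value`, `se`, `ci_low`,
#'   `ci_high`, `significant`, `relevant`, `pro_rich`, `available`.
#' @export
intra_country_table <- function(records, meta,
                                indicators = c("heard", "knowledge", "tested", "condom"),
                                bounds = default_bounds(),
                                normalize = TRUE, alpha = 0.05, relevance = 0.2) {
  unknown <- setdiff(unique(records$country), meta$country_code)
  if (length(unknown)) {
    stop("country absent from metadata: ", paste(unknown, collapse = ", "))
  }
  records <- with_knowledge(records)
  records$aw <- normalize_survey_weights(
    records$weight, records$country,
    survey = paste(records$program, records$year), mode = "intra")
  rows <- list()
  for (cc in sort(unique(records$country))) {
    sub <- records[records$country == cc, , drop = FALSE]
    for (ind in indicators) {
      rows[[length(rows) + 1L]] <- ci_cell(
        sub, ind, ranker = sub$wealth, weights = sub$aw,
        bounds = bounds[[ind]], normalize = normalize,
        alpha = alpha, relevance = relevance, group = cc)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("inequality_table", "data.frame")
  out
}

# one table cell: estimate on the indicator's complete cases, or an NA
# cell when the indicator is structurally absent
ci_cell <- function(sub, ind, ranker, weights, bounds, normalize,
                    alpha, relevance, group) {
  na_cell <- data.frame(
    group = group, indicator = ind, n = 0L, mu = NA_real_, value = NA_real_,
    se = NA_real_, ci_low = NA_real_, ci_high = NA_real_, significant = NA,
    relevant = NA, pro_rich = NA, available = FALSE, stringsAsFactors = FALSE)
  ok <- !is.na(sub[[ind]])
  if (!any(ok)) return(na_cell)
  if (sum(ok) < 2L) stop(sprintf(
    "fewer than two complete cases for %s / %s", group, ind))
  fit <- concindex(sub[[ind]][ok], ranker = ranker[ok], weights = weights[ok],
                   bounds = bounds, normalize = normalize, alpha = alpha,
                   relevance = relevance, label = paste(group, ind))
  data.frame(
    group = group, indicator = ind, n = fit$n, mu = fit$mu, value = fit$value,
    se = fit$se, ci_low = fit$ci95[1], ci_high = fit$ci95[2],
    significant = fit$significant, relevant = fit$relevant,
    pro_rich = fit$pro_rich, available = TRUE, stringsAsFactors = FALSE)
}

#' Inter-country (regional) inequality summary
#'
#' Pools all countries, ranks respondents on within-country min-max
#' normalized wealth scaled by per-capita GDP-PPP, and rescales weights
#' so each country's total equals its share of the regional female 15-24
#' population.  One Wagstaff-normalized concentration index is estimated
#' per indicator on its complete cases; when an indicator is absent from
#' some countries' surveys, population shares are renormalized over the
#' countries contributing data.
#'
#' @inheritParams intra_country_table
#' @param wealth_normalization `"minmax"` (default) or `"zscore"` for the
#'   within-country wealth rescaling that precedes GDP scaling.
#' @return an `"inequality_table"` `data.frame`, one row per indicator,
#'   with `group` set to `"REGION"`.
#' @export
inter_country_summary <- function(records, meta,
                                  indicators = c("heard", "knowledge", "tested", "condom"),
                                  bounds = default_bounds(),
                                  normalize = TRUE, alpha = 0.05, relevance = 0.2,
                                  wealth_normalization = "minmax") {
  unknown <- setdiff(unique(records$country), meta$country_code)
  if (length(unknown)) {
    stop("country absent from metadata: ", paste(unknown, collapse = ", "))
  }
  records <- with_knowledge(records)
  nw <- normalize_wealth(records$wealth, records$country,
                         method = wealth_normalization)
  records$scaled_wealth <- scale_wealth_gdp(nw, records$country, meta)
  rows <- list()
  for (ind in indicators) {
    ok <- !is.na(records[[ind]])
    if (!any(ok)) {
      rows[[length(rows) + 1L]] <- ci_cell(
        records, ind, ranker = records$scaled_wealth,
        weights = records$weight, bounds = bounds[[ind]],
        normalize = normalize, alpha = alpha, relevance = relevance,
        group = "REGION")
      next
    }
    sub <- records[ok, , drop = FALSE]
    m <- meta[meta$country_code %in% unique(sub$country), , drop = FALSE]
    m$pop_share <- m$pop_share / sum(m$pop_share)
    sub$aw <- normalize_survey_weights(sub$weight, sub$country,
                                       mode = "inter", meta = m)
    rows[[length(rows) + 1L]] <- ci_cell(
      sub, ind, ranker = sub$scaled_wealth, weights = sub$aw,
      bounds = bounds[[ind]], normalize = normalize, alpha = alpha,
      relevance = relevance, group = "REGION")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("inequality_table", "data.frame")
  out
}

#' Render an inequality table in the publication style
#'
#' Turns the long per-cell output of [intra_country_table()] (optionally
#' stacked with [inter_country_summary()]) into a wide country x
#' indicator character matrix: estimates to three decimals, `NS` where
#' not statistically significant, `NA` where the indicator is absent.
#'
#' @param x an `"inequality_table"`.
#' @param digits decimals for rendered estimates (default 3).
#' @return a character `data.frame`, one row per group.
#' @export
format_inequality_table <- function(x, digits = 3) {
  stopifnot(inherits(x, "inequality_table") || is.data.frame(x))
  render <- function(row) {
    if (!row$available) return("NA")
    if (!isTRUE(row$significant)) return("NS")
    sprintf("%.*f", digits, row$value)
  }
  groups <- unique(x$group)
  inds <- unique(x$indicator)
  out <- data.frame(group = groups, stringsAsFactors = FALSE)
  for (ind in inds) {
    out[[ind]] <- vapply(groups, function(g) {
      row <- x[x$group == g & x$indicator == ind, , drop = FALSE]
      if (nrow(row) == 0L) "NA" else render(row[1L, ])
    }, character(1))
  }
  out
}
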