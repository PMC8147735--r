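# Canonical respondent schema used throughout the package.
# Required: country, program, year, weight, wealth, age.
# Indicators (tri-state; NA = missing / not asked):
#   heard     - ever heard of HIV/AIDS (1/0)
#   k_condom, k_partner, k_mosquito, k_food - the four knowledge items
#               (1 = correct, 0 = incorrect or "don't know")
#   tested    - ever tested for HIV (1/0)
#   condom    - condom use at last intercourse (1/0)
.required_cols <- c("country", "program", "year", "weight", "wealth", "age")
.knowledge_items <- c("k_condom", "k_partner", "k_mosquito", "k_food")
.indicator_cols <- c("heard", .knowledge_items, "tested", "condom")

# tolerant parser for yes/no style fields -> 1/0/NA
parse_binary <- function(x, dont_know = "missing") {
  if (is.numeric(x)) return(ifelse(x %in% c(0, 1), x, NA_real_))
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA_real_, length(v))
  out[v %in% c("1", "yes", "y", "true", "correct")] <- 1
  out[v %in% c("0", "no", "n", "false", "incorrect")] <- 0
  dk <- v %in% c("dk", "don't know", "dont know", "dont_know", "unsure")
  out[dk] <- if (dont_know == "incorrect") 0 else NA_real_
  out
}

#' Read a respondent-level survey table
#'
#' Reads a comma-delimited respondent table (header row, UTF-8, `NA` or
#' empty cell = missing) into the canonical schema, applying an optional
#' column mapping.  Rows failing hard validation — non-positive or
#' missing weight, unparseable wealth — are dropped and counted in a
#' validation report attached as `attr(x, "validation")`.  Binary fields
#' accept yes/no, 1/0, true/false and correct/incorrect spellings;
#' "don't know" on a knowledge item is coded according to `dont_know`
#' (incorrect by default: it is not correct knowledge).
#'
#' @param path path to the CSV file.
#' @param column_map named list or character vector mapping canonical
#'   column names (`country`, `program`, `year`, `weight`, `wealth`,
#'   `age`, `heard`, `k_condom`, `k_partner`, `k_mosquito`, `k_food`,
#'   `tested`, `condom`) to the file's column names; identity by default.
#' @param dont_know how to code "don't know" on knowledge items:
#'   `"incorrect"` (default) or `"missing"`.
#' @return a `data.frame` in the canonical schema with a `"validation"`
#'   attribute (list: `n_rows`, `n_kept`, `n_dropped`, `dropped` reason
#'   counts, `missing_by_indicator`).
#' @export
read_survey_table <- function(path, column_map = NULL,
                              dont_know = c("incorrect", "missing")) {
  dont_know <- match.arg(dont_know)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""), encoding = "UTF-8")
  if (nrow(raw) == 0L) stop("empty input: no data rows in ", path)
  cmap <- stats::setNames(c(.required_cols, .indicator_cols),
                          c(.required_cols, .indicator_cols))
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    unknown <- setdiff(names(column_map), names(cmap))
    if (length(unknown)) stop("column_map has unknown canonical names: ",
                              paste(unknown, collapse = ", "))
    cmap[names(column_map)] <- column_map
  }
  missing_req <- .required_cols[!(cmap[.required_cols] %in% names(raw))]
  if (length(missing_req)) {
    stop("missing required column(s): ", paste(missing_req, collapse = ", "))
  }
  out <- data.frame(
    country = as.character(raw[[cmap["country"]]]),
    program = as.character(raw[[cmap["program"]]]),
    year = as.character(raw[[cmap["year"]]]),
    weight = suppressWarnings(as.numeric(raw[[cmap["weight"]]])),
    wealth = suppressWarnings(as.numeric(raw[[cmap["wealth"]]])),
    age = suppressWarnings(as.integer(raw[[cmap["age"]]])),
    stringsAsFactors = FALSE
  )
  for (ind in .indicator_cols) {
    src <- cmap[ind]
    out[[ind]] <- if (src %in% names(raw)) {
      parse_binary(raw[[src]],
                   dont_know = if (ind %in% .knowledge_items) dont_know else "missing")
    } else {
      NA_real_
    }
  }
  bad_weight <- is.na(out$weight) | out$weight <= 0
  bad_wealth <- is.na(out$wealth)
  keep <- !(bad_weight | bad_wealth)
  report <- list(
    n_rows = nrow(out),
    n_kept = sum(keep),
    n_dropped = sum(!keep),
    dropped = c(nonpositive_or_missing_weight = sum(bad_weight),
                missing_wealth = sum(bad_wealth & !bad_weight)),
    missing_by_indicator = vapply(out[keep, .indicator_cols, drop = FALSE],
                                  function(x) sum(is.na(x)), integer(1))
  )
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "validation") <- report
  out
}

#' Write records back to the canonical delimited format
#'
#' Inverse of [read_survey_table()]: field values round-trip exactly.
#'
#' @param records canonical respondent `data.frame`.
#' @param path output CSV path.
#' @export
write_survey_table <- function(records, path) {
  utils::write.csv(records[, c(.required_cols, .indicator_cols)], path,
                   row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a country-metadata table
#'
#' Reads per-country metadata: `country_code`, `pc_gdp_ppp` (per-capita
#' GDP at purchasing-power parity, international dollars) and `pop_share`
#' (the country's share of the regional female 15-24 population, summing
#' to 1 over the analysis set).
#'
#' @param path CSV path.
#' @param check_shares error if pop_shares do not sum to 1 within 1e-9
#'   (default `TRUE`).
#' @return a `data.frame` with the three columns above.
#' @export
read_country_meta <- function(path, check_shares = TRUE) {
  if (!file.exists(path)) stop("metadata file does not exist: ", path)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("country_code", "pc_gdp_ppp", "pop_share")
  missing_req <- setdiff(need, names(meta))
  if (length(missing_req)) {
    stop("metadata is missing column(s): ", paste(missing_req, collapse = ", "))
  }
  if (any(is.na(meta$pc_gdp_ppp)) || any(meta$pc_gdp_ppp <= 0)) {
    stop("pc_gdp_ppp must be positive for every country")
  }
  if (check_shares && abs(sum(meta$pop_share) - 1) > 1e-9) {
    stop(sprintf("pop_share sums to %.12f, not 1", sum(meta$pop_share)))
  }
  meta
}

#' Keep respondents eligible for the analysis (females 15-24)
#'
#' @param records canonical respondent `data.frame`.
#' @param min_age,max_age inclusive eligibility bounds (defaults 15, 24).
#' @return the eligible subset; the number excluded is reported via
#'   `message()`, and an empty result triggers a warning.
#' @export
filter_eligible <- function(records, min_age = 15, max_age = 24) {
  keep <- !is.na(records$age) & records$age >= min_age & records$age <= max_age
  excluded <- sum(!keep)
  if (excluded > 0) {
    message(sprintf("filter_eligible: excluded %d record(s) outside ages %d-%d",
                    excluded, min_age, max_age))
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no eligible respondents remain")
  out
}

#' Composite HIV-knowledge score (0-4)
#'
#' Counts correct answers on the four transmission-knowledge items
#' (condom use prevents, single partner prevents, mosquito bites do not
#' transmit, sharing food does not transmit).  Respondents who never
#' heard of HIV/AIDS score 0 (they are retained on the scale, the items
#' having been skipped); respondents with missing awareness are missing;
#' an item that is structurally missing while the respondent is aware
#' makes the composite missing.
#'
#' @param records canonical respondent `data.frame`.
#' @param never_heard score for respondents who never heard of HIV:
#'   `"zero"` (default) or `"missing"`.
#' @return integer-valued numeric vector in 0..4 with `NA`s.
#' @export
knowledge_score <- function(records, never_heard = c("zero", "missing")) {
  never_heard <- match.arg(never_heard)
  items <- as.matrix(records[, .knowledge_items, drop = FALSE])
  score <- rowSums(items)  # NA-propagating: any missing item -> NA
  if (never_heard == "zero") {
    score[!is.na(records$heard) & records$heard == 0] <- 0
  } else {
    score[!is.na(records$heard) & records$heard == 0] <- NA_real_
  }
  score[is.na(records$heard)] <- NA_real_
  score
}

#' Pool respondent tables from several surveys
#'
#' Concatenates record sets (e.g. a country's MICS and DHS surveys),
#' retaining program and year labels so per-survey descriptives remain
#' computable.  Sampling weights are deliberately left on their original
#' scales here; analysis-weight construction happens in
#' [normalize_survey_weights()].
#'
#' @param ... canonical respondent `data.frame`s (or a single list of them).
#' @param expect_country optional country code; if supplied, an error is
#'   raised when any set contains a different country (single-country
#'   pooling guard).
#' @return one concatenated `data.frame`.
#' @export
pool_surveys <- function(..., expect_country = NULL) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !is.data.frame(sets[[1L]])) {
    sets <- sets[[1L]]
  }
  if (!length(sets)) stop("no record sets supplied")
  for (s in sets) {
    if (!is.data.frame(s) || !all(.required_cols %in% names(s))) {
      stop("all sets must be canonical respondent tables sharing the schema")
    }
    if (nrow(s) == 0L) warning("pooling an empty record set")
  }
  out <- do.call(rbind, c(sets, list(make.row.names = FALSE)))
  if (!is.null(expect_country)) {
    other <- setdiff(unique(out$country), expect_country)
    if (length(other)) {
      stop("single-country pool requested for '", expect_country,
           "' but found: ", paste(other, collapse = ", "))
    }
  }
  out
}
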