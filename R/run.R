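# Configured end-to-end run: read or simulate respondents, filter
# eligibility, and write the descriptive table, the intra-country
# inequality matrix, the regional summary, a validation report and a run
# log to an output directory.

.config_keys <- c("seed", "inputs", "simulate", "eligibility", "indicators",
                  "bounds", "ci", "ranking", "output")

# fill defaults and reject unknown keys
validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  bad <- setdiff(names(cfg), .config_keys)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(cfg$inputs) && is.null(cfg$simulate)) {
    stop("config must provide either `inputs` (records + meta paths) or `simulate`")
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$eligibility <- utils::modifyList(list(min_age = 15, max_age = 24),
                                       cfg$eligibility %||% list())
  cfg$indicators <- cfg$indicators %||% c("heard", "knowledge", "tested", "condom")
  b <- default_bounds()
  for (nm in names(cfg$bounds %||% list())) b[[nm]] <- as.numeric(cfg$bounds[[nm]])
  cfg$bounds <- b
  cfg$ci <- utils::modifyList(list(normalize = "wagstaff", alpha = 0.05,
                                   relevance = 0.2), cfg$ci %||% list())
  if (!cfg$ci$normalize %in% c("wagstaff", "none")) {
    stop("ci.normalize must be 'wagstaff' or 'none'")
  }
  cfg$ranking <- utils::modifyList(list(normalization = "minmax"),
                                   cfg$ranking %||% list())
  if (!cfg$ranking$normalization %in% c("minmax", "zscore")) {
    stop("ranking.normalization must be 'minmax' or 'zscore'")
  }
  cfg$output <- utils::modifyList(list(dir = "concindex-output"),
                                  cfg$output %||% list())
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full inequality analysis from a config file
#'
#' Reads a YAML configuration, loads (or simulates) the respondent and
#' country-metadata tables, applies eligibility filtering, and writes to
#' the output directory: `descriptives.csv` (weighted means with 95%
#' intervals per country-survey), `intra_ci.csv` (country x indicator
#' concentration indices), `inter_ci.csv` (regional indices), a rendered
#' `inequality_table.csv` (estimates with NS/NA markers, regional row
#' first), `validation.json` (dropped-row and missingness counts) and
#' `run.log`.  The run is deterministic given the config and inputs.
#'
#' Config keys: `seed`; `inputs` (`records`, `meta`, optional
#' `column_map`, `dont_know`) or `simulate` (`n_total`); `eligibility`
#' (`min_age`, `max_age`); `indicators`; `bounds` (per indicator);
#' `ci` (`normalize` = wagstaff|none, `alpha`, `relevance`); `ranking`
#' (`normalization` = minmax|zscore); `output` (`dir`).
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @param out_dir optional override of `output.dir`.
#' @return (invisibly) a list with `descriptives`, `intra`, `inter`,
#'   `rendered`, `validation`, and the output directory.
#' @export
run_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file does not exist: ", config)
    config_hash <- unname(tools::md5sum(config))
    cfg <- yaml::read_yaml(config)
  } else {
    cfg <- config
    config_hash <- NA_character_
  }
  cfg <- validate_config(cfg)
  if (!is.null(out_dir)) cfg$output$dir <- out_dir

  validation <- NULL
  if (!is.null(cfg$inputs)) {
    for (p in c(cfg$inputs$records, cfg$inputs$meta)) {
      if (!file.exists(p)) stop("input file does not exist: ", p)
    }
    records <- read_survey_table(cfg$inputs$records,
                                 column_map = cfg$inputs$column_map,
                                 dont_know = cfg$inputs$dont_know %||% "incorrect")
    validation <- attr(records, "validation")
    meta <- read_country_meta(cfg$inputs$meta)
  } else {
    sim <- simulate_region(lac_scenarios(n_total = cfg$simulate$n_total %||% 20000),
                           seed = cfg$seed)
    records <- sim$records
    meta <- sim$meta
    validation <- list(n_rows = nrow(records), n_kept = nrow(records),
                       n_dropped = 0L, dropped = list(),
                       missing_by_indicator = vapply(
                         records[, .indicator_cols, drop = FALSE],
                         function(x) sum(is.na(x)), integer(1)))
  }
  n_loaded <- nrow(records)
  records <- suppressMessages(filter_eligible(records,
                                              cfg$eligibility$min_age,
                                              cfg$eligibility$max_age))
  normalize <- identical(cfg$ci$normalize, "wagstaff")

  desc <- descriptive_table(records)
  intra <- intra_country_table(records, meta, indicators = cfg$indicators,
                               bounds = cfg$bounds, normalize = normalize,
                               alpha = cfg$ci$alpha, relevance = cfg$ci$relevance)
  inter <- inter_country_summary(records, meta, indicators = cfg$indicators,
                                 bounds = cfg$bounds, normalize = normalize,
                                 alpha = cfg$ci$alpha, relevance = cfg$ci$relevance,
                                 wealth_normalization = cfg$ranking$normalization)
  rendered <- format_inequality_table(rbind(inter, intra))

  dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(f) file.path(cfg$output$dir, f)
  utils::write.csv(desc, outfile("descriptives.csv"), row.names = FALSE, na = "NA")
  utils::write.csv(intra, outfile("intra_ci.csv"), row.names = FALSE, na = "NA")
  utils::write.csv(inter, outfile("inter_ci.csv"), row.names = FALSE, na = "NA")
  utils::write.csv(rendered, outfile("inequality_table.csv"), row.names = FALSE)
  jsonlite::write_json(validation, outfile("validation.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  per_ind_n <- vapply(cfg$indicators, function(ind) {
    sum(intra$n[intra$indicator == ind])
  }, numeric(1))
  log_lines <- c(
    sprintf("seed: %s", cfg$seed),
    sprintf("config_md5: %s", config_hash),
    sprintf("rows_loaded: %d", n_loaded),
    sprintf("rows_eligible: %d", nrow(records)),
    sprintf("rows_dropped_on_read: %d", validation$n_dropped %||% 0L),
    sprintf("countries: %d", length(unique(records$country))),
    sprintf("n_%s: %d", cfg$indicators, per_ind_n)
  )
  writeLines(log_lines, outfile("run.log"))
  message(paste(log_lines, collapse = "\n"))

  invisible(list(descriptives = desc, intra = intra, inter = inter,
                 rendered = rendered, validation = validation,
                 dir = cfg$output$dir))
}
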