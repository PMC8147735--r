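# Small in-code fixtures shared across test files.

# a minimal canonical respondent table
make_records <- function(n = 6, country = "AA", program = "MICS", year = "2015",
                         weight = rep(1, n), wealth = seq_len(n),
                         age = rep(20L, n), heard = rep(1, n),
                         k = matrix(1, n, 4), tested = rep(NA_real_, n),
                         condom = rep(NA_real_, n)) {
  data.frame(
    country = country, program = program, year = year,
    weight = weight, wealth = wealth, age = age, heard = heard,
    k_condom = k[, 1], k_partner = k[, 2], k_mosquito = k[, 3], k_food = k[, 4],
    tested = tested, condom = condom, stringsAsFactors = FALSE
  )
}

# random estimation instance with ties and unequal weights
random_instance <- function(n) {
  list(
    h = stats::rbinom(n, 1, 0.4),
    wealth = round(stats::rnorm(n), 1),  # rounding injects ties
    w = stats::rgamma(n, shape = 2, rate = 2) + 0.05
  )
}

# scenario shorthand: single binary indicator, no missingness
toy_scenario <- function(n, a, b, weight_law = "equal", country = "XX",
                         pop_share = 1, gdp = 10000) {
  country_scenario(country, n, gdp, pop_share, heard = c(a, b),
                   weight_law = weight_law,
                   missing = c(heard = 0, knowledge = 0, tested = 0, condom = 0))
}
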