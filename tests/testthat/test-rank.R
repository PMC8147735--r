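test_that("fractional ranks match hand-computed values, including ties", {
  expect_equal(fractional_rank(c(10, 20, 30), c(1, 1, 2)),
               c(0.125, 0.375, 0.75))
  # tied values share one block rank
  expect_equal(fractional_rank(c(5, 5, 10)), c(1 / 3, 1 / 3, 5 / 6))
  # a single respondent sits at the middle of the distribution
  expect_equal(fractional_rank(7, 3), 0.5)
  # ranks are returned in the original record order
  expect_equal(fractional_rank(c(30, 10, 20), c(2, 1, 1)),
               c(0.75, 0.125, 0.375))
})

test_that("ranks lie in (0,1) with weighted mean exactly 1/2", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(1:200, 1)
    x <- round(rnorm(n), 1)
    w <- rgamma(n, 2) + 0.01
    r <- fractional_rank(x, w)
    expect_true(all(r > 0 & r < 1))
    expect_equal(sum(w * r) / sum(w), 0.5, tolerance = 1e-9)
    # non-decreasing in the ranking variable
    expect_true(all(diff(r[order(x)]) >= 0))
  }
})

test_that("ranks are invariant to strictly increasing transforms", {
  set.seed(12)
  x <- rnorm(50)
  w <- rgamma(50, 3)
  r <- fractional_rank(x, w)
  expect_identical(fractional_rank(exp(x), w), r)
  expect_identical(fractional_rank(rank(x, ties.method = "min"), w), r)
  expect_identical(fractional_rank(100 + 3 * x, w), r)
})

test_that("duplicating a respondent equals doubling her weight", {
  set.seed(13)
  h <- rbinom(20, 1, 0.5)
  x <- rnorm(20)
  w <- runif(20, 0.5, 2)
  # double the weight of respondent 7
  w2 <- w; w2[7] <- 2 * w[7]
  # versus appending a duplicate record
  h3 <- c(h, h[7]); x3 <- c(x, x[7]); w3 <- c(w, w[7])
  r2 <- fractional_rank(x, w2)
  r3 <- fractional_rank(x3, w3)
  expect_equal(r3[1:20][-7], r2[-7], tolerance = 1e-12)
  expect_equal(ci_direct(h, r2, w2), ci_direct(h3, r3, w3), tolerance = 1e-12)
})

test_that("rank computation rejects invalid input", {
  expect_error(fractional_rank(numeric(0)), "empty")
  expect_error(fractional_rank(1:3, c(1, 0, 1)), "positive")
  expect_error(fractional_rank(1:3, c(1, -1, 1)), "positive")
  expect_error(fractional_rank(c(1, NA, 3)), "missing")
})

test_that("within-country wealth normalization is min-max per country", {
  expect_equal(normalize_wealth(c(2, 4, 6), rep("A", 3)), c(0, 0.5, 1))
  # countries are rescaled independently
  expect_equal(normalize_wealth(c(1, 3, 1, 3), c("A", "A", "B", "B")),
               c(0, 1, 0, 1))
  expect_warning(out <- normalize_wealth(c(5, 5), c("A", "A")), "constant")
  expect_equal(out, c(0.5, 0.5))
  # z-score alternative is centered and scaled per country
  z <- normalize_wealth(c(1, 2, 3), rep("A", 3), method = "zscore")
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
})

test_that("GDP scaling multiplies normalized wealth and orders across countries", {
  meta <- data.frame(country_code = c("P", "R"), pc_gdp_ppp = c(10000, 40000))
  expect_equal(scale_wealth_gdp(0.5, "R", meta)[1], 20000)
  # richest of the poorer country ranks below richest of the richer country
  s <- scale_wealth_gdp(c(1, 1), c("P", "R"), meta)
  expect_lt(s[1], s[2])
  expect_equal(scale_wealth_gdp(0, "R", meta)[1], 0)
  expect_error(scale_wealth_gdp(0.5, "Q", meta), "Q")
})

test_that("intra-mode weights have mean 1 within each country-survey", {
  w <- normalize_survey_weights(c(1, 3), c("A", "A"), mode = "intra")
  expect_equal(w, c(0.5, 1.5))
  w2 <- normalize_survey_weights(c(1, 3, 10, 30), c("A", "A", "B", "B"),
                                 mode = "intra")
  expect_equal(w2, c(0.5, 1.5, 0.5, 1.5))
  # distinct surveys within a country form separate cells
  w3 <- normalize_survey_weights(c(1, 3, 10, 30), rep("A", 4),
                                 survey = c("MICS", "MICS", "DHS", "DHS"),
                                 mode = "intra")
  expect_equal(w3, c(0.5, 1.5, 0.5, 1.5))
})

test_that("inter-mode weights give each country its population share exactly", {
  meta <- data.frame(country_code = c("A", "B"), pop_share = c(0.75, 0.25))
  w <- normalize_survey_weights(c(2, 2, 1, 3), c("A", "A", "B", "B"),
                                mode = "inter", meta = meta)
  expect_equal(w, c(0.375, 0.375, 0.0625, 0.1875))
  expect_identical(sum(w[1:2]), 0.75)
  expect_identical(sum(w[3:4]), 0.25)
  # single country with share 1
  w1 <- normalize_survey_weights(c(5, 7), c("A", "A"), mode = "inter",
                                 meta = data.frame(country_code = "A",
                                                   pop_share = 1))
  expect_equal(sum(w1), 1)
  expect_error(normalize_survey_weights(1, "A", mode = "inter"), "pop_share")
  expect_error(
    normalize_survey_weights(c(1, 1), c("A", "B"), mode = "inter",
                             meta = data.frame(country_code = c("A", "B"),
                                               pop_share = c(0.5, 0.4))),
    "sums")
})
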