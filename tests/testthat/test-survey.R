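write_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a well-formed table reads fully with an empty validation report", {
  p <- write_fixture(c(
    "country,program,year,weight,wealth,age,heard,k_condom,k_partner,k_mosquito,k_food,tested,condom",
    "AA,MICS,2015,1.2,0.5,18,yes,correct,correct,incorrect,dk,no,NA",
    "AA,MICS,2015,0.8,1.5,22,no,NA,NA,NA,NA,NA,NA",
    "AA,MICS,2015,1.0,2.5,15,yes,1,0,1,1,yes,yes"))
  rec <- read_survey_table(p)
  expect_equal(nrow(rec), 3)
  v <- attr(rec, "validation")
  expect_equal(v$n_dropped, 0)
  # yes/no and correct/incorrect/dk spellings are parsed; dk -> incorrect
  expect_equal(rec$heard, c(1, 0, 1))
  expect_equal(rec$k_food, c(0, NA, 1))
  expect_equal(rec$tested, c(0, NA, 1))
})

test_that("hard-validation failures are dropped and counted", {
  p <- write_fixture(c(
    "country,program,year,weight,wealth,age,heard",
    "AA,MICS,2015,0,0.5,18,yes",     # non-positive weight
    "AA,MICS,2015,1.0,abc,19,yes",   # unparseable wealth
    "AA,MICS,2015,1.0,2.0,20,yes"))
  rec <- suppressWarnings(read_survey_table(p))
  expect_equal(nrow(rec), 1)
  v <- attr(rec, "validation")
  expect_equal(v$n_dropped, 2)
  expect_equal(unname(v$dropped["nonpositive_or_missing_weight"]), 1L)
  expect_equal(unname(v$dropped["missing_wealth"]), 1L)
})

test_that("schema errors name the offending column; empty files error", {
  p <- write_fixture(c("country,program,year,weight,age", "AA,MICS,2015,1,18"))
  expect_error(read_survey_table(p), "wealth")
  p2 <- write_fixture("country,program,year,weight,wealth,age")
  expect_error(read_survey_table(p2), "empty")
  expect_error(read_survey_table(file.path(tempdir(), "nope.csv")), "exist")
})

test_that("column_map renames file columns onto the canonical schema", {
  p <- write_fixture(c(
    "pais,prog,anio,pondera,riqueza,edad,oyo",
    "AA,MICS,2015,1.0,3.5,17,yes"))
  rec <- read_survey_table(p, column_map = list(
    country = "pais", program = "prog", year = "anio", weight = "pondera",
    wealth = "riqueza", age = "edad", heard = "oyo"))
  expect_equal(rec$wealth, 3.5)
  expect_equal(rec$heard, 1)
  expect_error(read_survey_table(p, column_map = list(riches = "riqueza")),
               "unknown canonical")
})

test_that("don't-know coding on knowledge items is configurable", {
  p <- write_fixture(c(
    "country,program,year,weight,wealth,age,heard,k_condom",
    "AA,MICS,2015,1,1,18,yes,dk"))
  expect_equal(read_survey_table(p)$k_condom, 0)
  expect_true(is.na(read_survey_table(p, dont_know = "missing")$k_condom))
})

test_that("records round-trip through the delimited format unchanged", {
  set.seed(41)
  rec <- simulate_survey(
    country_scenario("AA", 40, 9000, 1, weight_law = "gamma"), seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_table(rec, path)
  back <- read_survey_table(path)
  expect_equal(back, rec, ignore_attr = TRUE)
})

test_that("eligibility filter keeps exactly ages 15-24 and is idempotent", {
  rec <- make_records(4, age = c(14L, 15L, 24L, 25L))
  out <- suppressMessages(filter_eligible(rec))
  expect_equal(out$age, c(15L, 24L))
  expect_identical(suppressMessages(filter_eligible(out)), out)
  # all in range: unchanged
  rec2 <- make_records(3, age = c(15L, 20L, 24L))
  expect_identical(suppressMessages(filter_eligible(rec2)), rec2)
  # all out of range: empty with a warning
  rec3 <- make_records(2, age = c(10L, 30L))
  expect_warning(out3 <- suppressMessages(filter_eligible(rec3)), "no eligible")
  expect_equal(nrow(out3), 0)
})

test_that("knowledge score counts correct items and handles awareness gating", {
  k <- rbind(c(1, 1, 1, 1), c(0, 0, 0, 0), c(1, 1, 0, 0),
             c(1, NA, 1, 1), c(1, 1, 1, 1), c(NA, NA, NA, NA))
  rec <- make_records(6, heard = c(1, 1, 1, 1, 0, NA), k = k)
  s <- knowledge_score(rec)
  expect_equal(s, c(4, 0, 2, NA, 0, NA))
  # never-heard respondents can alternatively be excluded from the scale
  s2 <- knowledge_score(rec, never_heard = "missing")
  expect_true(is.na(s2[5]))
  # the score is the sum of the items, hence permutation-invariant
  perm <- rec
  perm[, c("k_condom", "k_partner", "k_mosquito", "k_food")] <-
    rec[, c("k_food", "k_mosquito", "k_condom", "k_partner")]
  expect_equal(knowledge_score(perm), s)
  expect_equal(s[1:3], rowSums(k)[1:3])
})

test_that("pooling concatenates surveys and keeps per-survey labels", {
  a <- make_records(100, country = "GY", program = "MICS", year = "2009")
  b <- make_records(150, country = "GY", program = "DHS", year = "2014")
  pooled <- pool_surveys(a, b)
  expect_equal(nrow(pooled), 250)
  expect_setequal(unique(pooled$program), c("MICS", "DHS"))
  # per-survey descriptives remain computable after pooling
  desc <- descriptive_table(pooled)
  expect_equal(length(unique(paste(desc$program, desc$year))), 2)
  # empty set pools with a warning
  expect_warning(pool_surveys(a[0, ], b), "empty")
  # conflicting countries under a single-country pool request
  cc <- make_records(10, country = "DO")
  expect_error(pool_surveys(a, cc, expect_country = "GY"), "DO")
})
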