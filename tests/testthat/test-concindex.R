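test_that("toy configurations give the textbook index values", {
  r <- fractional_rank(1:4)
  # perfectly pro-rich binary half-prevalence sample
  expect_equal(ci_direct(c(0, 0, 1, 1), r), 0.5)
  # alternating outcome: hand covariance -0.0625, mean 0.5
  expect_equal(ci_direct(c(1, 0, 1, 0), r), -0.25)
  # constant indicator carries no inequality
  expect_equal(ci_direct(rep(1, 4), r), 0)
})

test_that("regression slope equals the covariance formula and lm's WLS fit", {
  set.seed(21)
  for (i in 1:40) {
    inst <- random_instance(sample(3:300, 1))
    if (sum(inst$h) == 0) inst$h[1] <- 1  # keep the mean nonzero
    r <- fractional_rank(inst$wealth, inst$w)
    reg <- ci_regression(inst$h, r, inst$w)
    expect_equal(reg$value, ci_direct(inst$h, r, inst$w), tolerance = 1e-12)
    # independent route: the same WLS through stats::lm
    wt <- inst$w / sum(inst$w)
    mu <- sum(wt * inst$h)
    s2r <- sum(wt * (r - sum(wt * r))^2)
    fit <- lm(y ~ r, data = data.frame(y = 2 * s2r * inst$h / mu, r = r),
              weights = inst$w)
    expect_equal(reg$value, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(reg$se, unname(summary(fit)$coefficients[2, 2]),
                 tolerance = 1e-10)
  }
})

test_that("Wagstaff normalization follows the bounded closed form", {
  expect_equal(wagstaff_normalize(0.5, 0.5), 1)
  expect_equal(wagstaff_normalize(0, 0.3), 0)
  # 0-4 composite: CI * mu * (b-a) / ((mu-a)(b-mu))
  expect_equal(wagstaff_normalize(0.1, 2, c(0, 4)), 0.2)
  expect_error(wagstaff_normalize(0.1, 1, c(0, 1)), "degenerate")
  expect_error(wagstaff_normalize(0.1, 0, c(0, 1)), "degenerate")
  expect_error(wagstaff_normalize(0.1, 5, c(0, 4)), "outside")
})

test_that("index is invariant to positive scaling of indicator and weights", {
  set.seed(22)
  h <- rbinom(80, 1, 0.3) + 0.0
  x <- rnorm(80)
  w <- rgamma(80, 2)
  r <- fractional_rank(x, w)
  base <- ci_direct(h, r, w)
  expect_equal(ci_direct(3.7 * h, r, w), base, tolerance = 1e-12)
  expect_equal(ci_direct(h, r, 100 * w), base, tolerance = 1e-12)
  expect_equal(ci_regression(h, r, 100 * w)$se, ci_regression(h, r, w)$se,
               tolerance = 1e-12)
})

test_that("Wagstaff-normalized binary index stays within [-1, 1]", {
  set.seed(23)
  for (i in 1:30) {
    n <- sample(5:200, 1)
    h <- rbinom(n, 1, runif(1, 0.1, 0.9))
    if (min(h) == max(h)) next
    x <- rnorm(n)
    fit <- concindex(h, ranker = x, normalize = TRUE)
    expect_true(abs(fit$value) <= 1 + 1e-12)
  }
  # perfect concentration attains exactly +/-1 with equal weights, mu = 1/2
  expect_equal(concindex(c(0, 0, 1, 1), ranker = 1:4)$value, 1)
  expect_equal(concindex(c(1, 1, 0, 0), ranker = 1:4)$value, -1)
})

test_that("the fit classifies sign, significance and relevance", {
  set.seed(24)
  # strong positive gradient, large sample: significant, relevant, pro-rich
  d <- simulate_survey(toy_scenario(5000, 0.2, 0.5), seed = 1)
  fit <- concindex(d$heard, ranker = d$wealth)
  expect_true(fit$significant)
  expect_true(fit$pro_rich)
  expect_true(fit$relevant)
  expect_equal(fit$ci95, fit$value + c(-1.96, 1.96) * fit$se, tolerance = 1e-9)
  # pro-poor gradient carries a negative sign
  d2 <- simulate_survey(toy_scenario(5000, 0.6, -0.4), seed = 2)
  fit2 <- concindex(d2$heard, ranker = d2$wealth)
  expect_false(fit2$pro_rich)
  expect_true(fit2$significant)
  # constant indicator: zero index, no significance claimed
  fitc <- concindex(rep(1, 10), ranker = 1:10)
  expect_equal(fitc$value, 0)
  expect_false(fitc$significant)
  expect_false(fitc$relevant)
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(ci_direct(c(0, 0), fractional_rank(1:2)), "mean.*zero")
  expect_error(ci_direct(1, 0.5), "two observations")
  expect_error(ci_regression(c(1, 0), c(0.5, 0.5)), "zero-variance")
  expect_error(concindex(c(0.5, 1, 2), ranker = 1:3, normalize = TRUE),
               "bounds")
  expect_error(concindex(c(0, 1, NA), ranker = 1:3, na.action = "fail"),
               "missing")
})

test_that("formula interface and accessor methods agree with the default call", {
  set.seed(25)
  d <- simulate_survey(toy_scenario(400, 0.3, 0.2, weight_law = "gamma"), seed = 3)
  f1 <- concindex(heard ~ wealth, data = d, weights = weight)
  f2 <- concindex(d$heard, ranker = d$wealth, weights = d$weight)
  expect_equal(f1$value, f2$value)
  expect_equal(f1$se, f2$se)
  expect_equal(unname(coef(f1)), f1$value)
  ci <- confint(f1)
  expect_equal(unname(ci[1, ]), f1$value + c(-1, 1) * qnorm(0.975) * f1$se)
  s <- summary(f1)
  expect_s3_class(s, "data.frame")
  expect_equal(s$value, f1$value)
  expect_output(print(f1), "concentration index")
})
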