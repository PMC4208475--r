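test_that("single-covariate Poisson RR equals the ratio of means", {
  y <- c(rep(1, 10), rep(0, 40), rep(1, 5), rep(0, 45))
  x <- rep(c(1, 0), each = 50)
  tab <- fit_poisson_rr(y, data.frame(exposed = x))
  expect_equal(tab$RR, 2.0, tolerance = 1e-10)
  expect_true(tab$estimable)
  expect_identical(tab$n_used, 100L)

  # weighted fit: ratio of weighted means
  set.seed(41)
  for (k in 1:20) {
    n <- 400
    x <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, 0.05 + 0.1 * x)
    w <- runif(n, 0.5, 2)
    if (sum(y[x == 0]) == 0) next
    tab <- fit_poisson_rr(y, data.frame(x = x), weights = w)
    oracle <- weighted.mean(y[x == 1], w[x == 1]) /
      weighted.mean(y[x == 0], w[x == 0])
    expect_equal(tab$RR, oracle, tolerance = 1e-10)
  }
})

test_that("Wald intervals contain the estimate and are log-symmetric", {
  set.seed(2)
  x <- rbinom(300, 1, 0.3)
  y <- rbinom(300, 1, 0.1 + 0.1 * x)
  tab <- fit_poisson_rr(y, data.frame(x = x))
  expect_true(tab$ci_low <= tab$RR && tab$RR <= tab$ci_high)
  expect_equal(log(tab$RR) - log(tab$ci_low), log(tab$ci_high) - log(tab$RR))
})

test_that("a null covariate has mean rate ratio near 1", {
  set.seed(8)
  rr <- vapply(1:200, function(i) {
    x <- rbinom(1000, 1, 0.3)
    y <- rbinom(1000, 1, 0.15)
    fit_poisson_rr(y, data.frame(x = x))$RR
  }, numeric(1))
  expect_gt(mean(rr), 0.97)
  expect_lt(mean(rr), 1.03)
})

test_that("inestimable cells get markers, not numbers", {
  # covariate constant within the stratum (no exposed household)
  y <- rbinom(60, 1, 0.3)
  tab <- fit_poisson_rr(y, data.frame(x = rep(0, 60)))
  expect_false(tab$estimable)
  expect_true(is.na(tab$RR))

  # separation: the exposure perfectly predicts the outcome
  x <- rep(0:1, each = 30)
  tab2 <- fit_poisson_rr(x, data.frame(x = x))
  expect_false(tab2$estimable)
})

test_that("stratified fits keep strata independent", {
  set.seed(12)
  n <- 1200
  q <- rep(1:3, each = n / 3)
  x <- rbinom(n, 1, 0.4)
  p <- ifelse(q == 1, 0.08 * ifelse(x == 1, 3, 1), 0.08)
  y <- rbinom(n, 1, p)
  tab <- fit_poisson_rr(y, data.frame(x = x), quintile = q)
  expect_identical(nrow(tab), 3L)
  oracle1 <- mean(y[q == 1 & x == 1]) / mean(y[q == 1 & x == 0])
  expect_equal(tab$RR[tab$quintile == 1], oracle1, tolerance = 1e-10)
})

test_that("chi-squared prevalence comparison matches hand computation", {
  # identical prevalence in every quintile
  f <- rep(c(1, 0), times = c(50, 450))
  q <- rep(1:5, times = 100)
  r <- chisq_quintile_prevalence(f, q)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # 2 x 2 with expected 15 per cell
  f2 <- rep(c(0, 1, 0, 1), times = c(10, 20, 20, 10))
  q2 <- rep(c(1, 2), each = 30)
  r2 <- chisq_quintile_prevalence(f2, q2)
  expect_equal(r2$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(r2$p_value, 1 - pchisq(20 / 3, 1))
  expect_lt(abs(r2$p_value - 0.0098), 5e-4)

  # a stratum with no households is degenerate
  expect_error(
    chisq_quintile_prevalence(c(1, 0, 1), factor(rep(1, 3), levels = 1:2)),
    "degenerate"
  )
})

test_that("chi-squared test holds its level under the null", {
  set.seed(3)
  reject <- vapply(1:1000, function(i) {
    q <- sample(1:5, 2000, replace = TRUE)
    f <- rbinom(2000, 1, 0.1)
    chisq_quintile_prevalence(f, q)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.035)
  expect_lte(mean(reject), 0.065)
})
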