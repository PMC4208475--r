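test_that("concentration index matches hand-computed cases", {
  r4 <- fractional_rank(1:4)
  expect_equal(concentration_index(rep(3, 4), r4), 0)
  expect_equal(concentration_index(1:4, r4), 0.25)
  expect_equal(concentration_index(c(0, 0, 1, 1), r4), 0.5)
  expect_equal(concentration_index(c(1, 1, 0, 0), r4), -0.5)
  expect_error(concentration_index(c(0, 0), fractional_rank(1:2)),
               "mean of `y` is zero")
})

test_that("covariance form equals the sorted-pairs brute force (n <= 12)", {
  set.seed(101)
  for (k in 1:200) {
    n <- sample(3:12, 1)
    y <- runif(n, 0, 5)
    r <- fractional_rank(runif(n))
    expect_equal(concentration_index(y, r), brute_force_ci(y, r),
                 tolerance = 1e-12)
  }
})

test_that("index is scale-free in y and antisymmetric in rank order", {
  set.seed(5)
  y <- rexp(30); v <- runif(30); w <- runif(30, 0.5, 2)
  r <- fractional_rank(v, w)
  C <- concentration_index(y, r, w)
  expect_equal(concentration_index(7.3 * y, r, w), C)
  r_rev <- fractional_rank(-v, w)
  expect_equal(concentration_index(y, r_rev, w), -C)
  expect_true(abs(C) <= 1)
})

test_that("random rank permutations average to zero concentration", {
  set.seed(23)
  y <- rexp(80)
  r <- fractional_rank(runif(80))
  perm <- vapply(1:200, function(i) concentration_index(y, r[sample(80)]),
                 numeric(1))
  expect_lt(abs(mean(perm)), 3 * sd(perm) / sqrt(200))
})

test_that("delta-method SE comes from the convenient regression", {
  r <- fractional_rank(runif(20))
  const <- ci_delta_se(rep(2, 20), r)
  expect_equal(const$C, 0)
  expect_equal(const$se, 0)
  expect_error(ci_delta_se(1:2, fractional_rank(1:2)), "at least 3")

  # the WLS slope is exactly the concentration index
  set.seed(77)
  y <- rexp(100); v <- runif(100); w <- runif(100, 0.5, 2)
  rk <- fractional_rank(v, w)
  expect_equal(ci_delta_se(y, rk, w)$C, concentration_index(y, rk, w))
})

test_that("delta SE tracks the sampling SD of the estimator", {
  set.seed(55)
  n <- 2000
  est <- se <- numeric(300)
  for (i in 1:300) {
    v <- runif(n)
    y <- as.numeric(runif(n) < 0.19016 - 0.10433 * v)
    r <- fractional_rank(v)
    est[i] <- concentration_index(y, r)
    if (i <= 50) se[i] <- ci_delta_se(y, r)$se
  }
  expect_lt(abs(mean(se[1:50]) - sd(est)) / sd(est), 0.25)
})

test_that("cluster bootstrap is deterministic and handles degenerate input", {
  g <- generate_survey(true_params(), n_psu = 15, m_households = 10, seed = 2)
  hh <- g$households
  s <- oop_share(oop_total(hh), hh$total_expenditure)
  y <- as.numeric(s > 0.1)
  ls <- living_standards(hh)
  b1 <- ci_bootstrap(y, ls$per_ae_expenditure, hh$weight, hh$psu_id,
                     B = 50, seed = 9)
  b2 <- ci_bootstrap(y, ls$per_ae_expenditure, hh$weight, hh$psu_id,
                     B = 50, seed = 9)
  expect_identical(b1$ci95, b2$ci95)
  expect_true(b1$ci95[1] <= b1$C && b1$C <= b1$ci95[2] ||
                b1$ci95[1] <= b1$ci95[2])

  # constant y: every replicate gives 0
  bc <- ci_bootstrap(rep(1, nrow(hh)), ls$per_ae_expenditure, hh$weight,
                     hh$psu_id, B = 20, seed = 1)
  expect_equal(bc$ci95, c(0, 0))
  expect_equal(bc$p_value, 1)

  expect_error(
    ci_bootstrap(y, ls$per_ae_expenditure, hh$weight,
                 rep("P1", nrow(hh)), B = 10, seed = 1),
    "resample_households"
  )
})

test_that("equity_result asserts the binary feasibility bounds", {
  g <- generate_survey(true_params(gradient = c(0.19016, -0.10433)),
                       n_psu = 25, m_households = 20, seed = 14)
  hh <- g$households
  s <- oop_share(oop_total(hh), hh$total_expenditure)
  y <- as.numeric(s > 0.1)
  ls <- living_standards(hh)
  eq <- equity_result(y, ls$per_ae_expenditure, hh$weight, hh$psu_id,
                      B = 50, seed = 3)
  mu <- weighted.mean(y, hh$weight)
  expect_true(eq$C >= mu - 1 && eq$C <= 1 - mu)
  expect_true(eq$ci95[1] <= eq$ci95[2])
  expect_identical(eq$B, 50L)
  expect_lt(eq$C, 0)  # gradient concentrates catastrophe among the poor
})
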