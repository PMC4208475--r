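test_that("generate_design matches the two-stage sampling structure", {
  d <- generate_design(100, 20, 0, seed = 1)
  expect_identical(nrow(d), 2000L)
  expect_true(all(d$weight == 1))

  d2 <- generate_design(1, 5, 0, seed = 7)
  expect_identical(nrow(d2), 5L)
  expect_identical(length(unique(d2$psu_id)), 1L)

  expect_error(generate_design(0, 10), "positive")
  expect_error(generate_design(10, 10, -0.1), "non-negative")

  # dispersed weights: positive, constant within PSU, mean exactly 1
  d3 <- generate_design(30, 10, 0.4, seed = 3)
  expect_true(all(d3$weight > 0))
  expect_equal(mean(d3$weight), 1)
  expect_true(all(tapply(d3$weight, d3$psu_id, function(w)
    length(unique(w))) == 1))
})

test_that("generation is deterministic in (params, seed)", {
  expect_identical(generate_design(10, 5, 0.3, seed = 9),
                   generate_design(10, 5, 0.3, seed = 9))
  p <- true_params(gradient = c(0.19016, -0.10433))
  g1 <- generate_survey(p, n_psu = 10, m_households = 10, seed = 5)
  g2 <- generate_survey(p, n_psu = 10, m_households = 10, seed = 5)
  expect_identical(g1$households, g2$households)
  expect_identical(g1$episodes, g2$episodes)
})

test_that("generator output passes validation across seeds", {
  for (seed in 1:50) {
    g <- generate_survey(true_params(), n_psu = 10, m_households = 10,
                         seed = seed)
    expect_identical(nrow(validate_survey(g$households, g$episodes)), 0L)
  }
})

test_that("zero catastrophe probability yields no catastrophic household", {
  p <- true_params(p_cat = 0)
  g <- generate_survey(p, n_psu = 20, m_households = 20, seed = 4)
  s <- oop_share(oop_total(g$households), g$households$total_expenditure)
  expect_identical(sum(s > 0.10), 0L)
})

test_that("realized catastrophic fraction converges to p_cat", {
  p <- true_params(p_cat = 0.138)
  g <- generate_survey(p, n_psu = 100, m_households = 200, seed = 8)
  s <- oop_share(oop_total(g$households), g$households$total_expenditure)
  frac <- mean(s > 0.10)
  # binomial 3-sigma band at n = 20 000
  expect_lt(abs(frac - 0.138), 3 * sqrt(0.138 * 0.862 / 20000))
})

test_that("gradient truth record states C = b/(6 mu) and matches brute force", {
  a <- 0.19016; b <- -0.10433
  p <- true_params(gradient = c(a, b))
  g <- generate_survey(p, n_psu = 10, m_households = 10, seed = 2)
  mu <- a + b / 2
  expect_equal(g$truth$true_C, b / (6 * mu))

  # independent brute-force simulation of the population index
  set.seed(99)
  n <- 1e5
  r <- runif(n)
  y <- as.numeric(runif(n) < a + b * r)
  C_sim <- 2 * cov(y, r) * (n - 1) / n / mean(y)
  expect_lt(abs(C_sim - g$truth$true_C), 0.02)
})

test_that("gradient generator concentrates catastrophe among the poor", {
  p <- true_params(gradient = c(0.19016, -0.10433))
  poor <- rich <- 0L; n_poor <- n_rich <- 0L
  for (seed in 1:20) {
    g <- generate_survey(p, seed = seed)
    s <- oop_share(oop_total(g$households), g$households$total_expenditure)
    E <- s > 0.10
    r <- g$truth$wealth_rank
    poor <- poor + sum(E[r < 0.1]); n_poor <- n_poor + sum(r < 0.1)
    rich <- rich + sum(E[r > 0.9]); n_rich <- n_rich + sum(r > 0.9)
  }
  expect_gt(poor / n_poor, rich / n_rich)
})

test_that("household-level illness prevalence is calibrated", {
  # cold/cough/fever at 12.8% of households; mean across replicated surveys
  p <- true_params()
  prev <- vapply(1:200, function(seed) {
    g <- generate_survey(p, seed = seed)
    flags <- illness_flags(g$episodes, g$households$household_id)
    mean(flags[, "cold_cough_fever"])
  }, numeric(1))
  expect_lt(abs(mean(prev) - 0.128), 0.002)
})

test_that("calibration errors are raised instead of silently capping", {
  expect_error(true_params(gradient = c(0.9, 0.3)), "\\[0, 1\\]")
  expect_error(true_params(p_cat = 1.2), "\\[0, 1\\]")
  p <- true_params(p_cat = 0.5,
                   rr_map = setNames(c(rep(1, 9), 4), illness_codes),
                   illness_prevalence = setNames(rep(0.5, 10), illness_codes))
  expect_error(generate_survey(p, n_psu = 10, m_households = 10, seed = 1),
               "calibration")
})
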