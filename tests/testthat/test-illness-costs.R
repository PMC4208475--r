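test_that("single-illness groups bypass the regression", {
  ep <- make_episodes("H001", "injury", "G1", 400)
  res <- allocate_joint_costs(ep)
  expect_equal(res$allocations$allocated, 400)
  expect_identical(res$allocations$method, "single")
})

test_that("OLS recovers exact allocations on a noiseless additive model", {
  # cost = 100 * arthritis + 300 * asthma
  ep <- make_episodes(
    household_id = c("H001", "H002", "H003", "H003"),
    illness_code = c("arthritis", "asthma", "arthritis", "asthma"),
    cost_group_id = c("G1", "G2", "G3", "G3"),
    reported_cost = c(100, 300, 400, NA)
  )
  res <- allocate_joint_costs(ep)
  joint <- res$allocations[res$allocations$cost_group_id == "G3", ]
  expect_equal(joint$allocated[joint$illness_code == "arthritis"], 100)
  expect_equal(joint$allocated[joint$illness_code == "asthma"], 300)
  expect_identical(unique(joint$method), "regression")
  expect_equal(unname(res$coefficients[c("arthritis", "asthma")]), c(100, 300))
})

test_that("negative predicted components are floored then renormalized", {
  # three pure-A groups at 10 and one joint group at 5 force beta_B = -5
  ep <- make_episodes(
    household_id = c("H001", "H002", "H003", "H004", "H004"),
    illness_code = c("injury", "injury", "injury", "injury", "asthma"),
    cost_group_id = c("G1", "G2", "G3", "G4", "G4"),
    reported_cost = c(10, 10, 10, 5, NA)
  )
  res <- allocate_joint_costs(ep)
  expect_equal(unname(res$coefficients["asthma"]), -5)
  joint <- res$allocations[res$allocations$cost_group_id == "G4", ]
  expect_equal(joint$allocated[joint$illness_code == "injury"], 5)
  expect_equal(joint$allocated[joint$illness_code == "asthma"], 0)
})

test_that("an all-floored group falls back to an equal split", {
  ep <- make_episodes(
    household_id = c("H001", "H002", "H003", "H003"),
    illness_code = c("injury", "asthma", "injury", "asthma"),
    cost_group_id = c("G1", "G2", "G3", "G3"),
    reported_cost = c(0, 0, 0, NA)
  )
  res <- allocate_joint_costs(ep)
  joint <- res$allocations[res$allocations$cost_group_id == "G3", ]
  expect_identical(unique(joint$method), "equal_split_fallback")
  expect_equal(joint$allocated, c(0, 0))
})

test_that("confounded illness codes raise a rank-deficiency error", {
  # diabetes and hypertension only ever occur together
  ep <- make_episodes(
    household_id = c("H001", "H001", "H002", "H002", "H003"),
    illness_code = c("diabetes", "hypertension", "diabetes", "hypertension",
                     "injury"),
    cost_group_id = c("G1", "G1", "G2", "G2", "G3"),
    reported_cost = c(900, NA, 700, NA, 100)
  )
  expect_error(allocate_joint_costs(ep), "rank deficient.*(diabetes|hypertension)")
})

test_that("allocations conserve group totals and respect relabeling", {
  set.seed(17)
  g <- generate_survey(true_params(), seed = 17)
  res <- allocate_joint_costs(g$episodes)
  tot <- tapply(res$allocations$allocated, res$allocations$cost_group_id, sum)
  rep_cost <- with(g$episodes, tapply(reported_cost, cost_group_id,
                                      function(x) x[!is.na(x)]))
  expect_equal(tot, rep_cost[names(tot)], tolerance = 1e-12)
  expect_true(all(res$allocations$allocated >= 0))

  # permuting illness labels permutes the allocations identically
  ep <- make_episodes(
    household_id = c("H001", "H002", "H003", "H003"),
    illness_code = c("arthritis", "asthma", "arthritis", "asthma"),
    cost_group_id = c("G1", "G2", "G3", "G3"),
    reported_cost = c(120, 340, 500, NA)
  )
  swap <- c(arthritis = "asthma", asthma = "arthritis")
  ep2 <- ep
  ep2$illness_code <- unname(swap[ep$illness_code])
  a1 <- allocate_joint_costs(ep)$allocations
  a2 <- allocate_joint_costs(ep2)$allocations
  a2$illness_code <- unname(swap[a2$illness_code])
  a2 <- a2[order(a2$cost_group_id, a2$illness_code), ]
  a1 <- a1[order(a1$cost_group_id, a1$illness_code), ]
  expect_equal(a1$allocated, a2$allocated)
})

test_that("allocated_cost_matrix aligns with the household table", {
  ep <- make_episodes(c("H002", "H002", "H001", "H003"),
                      c("injury", "asthma", "injury", "asthma"),
                      c("G1", "G1", "G2", "G3"), c(600, NA, 100, 200))
  res <- allocate_joint_costs(ep)
  M <- allocated_cost_matrix(res$allocations, c("H001", "H002", "H003"))
  expect_equal(dim(M), c(3L, 10L))
  expect_equal(sum(M["H002", ]), 600)
  expect_equal(sum(M["H001", ]), 100)
  expect_equal(sum(M["H003", ]), 200)
})
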