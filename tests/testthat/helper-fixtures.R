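# Small in-code fixtures shared across test files.

# a minimal valid household table
make_households <- function(n = 3,
                            shares = NULL,
                            total_expenditure = rep(50000, n),
                            weight = rep(1, n)) {
  oop <- if (is.null(shares)) rep(1000, n) else shares * total_expenditure
  data.frame(
    household_id = sprintf("H%03d", seq_len(n)),
    psu_id = sprintf("P%02d", seq_len(n)),
    weight = weight,
    member_ages = rep("40;38;10", n),
    head_age = rep(40, n),
    head_sex = rep("male", n),
    head_education = rep("secondary", n),
    total_expenditure = total_expenditure,
    food = 0.5 * total_expenditure,
    nonfood = 0.2 * total_expenditure,
    housing = 0.2 * total_expenditure,
    durables = 0.1 * total_expenditure,
    oop_outpatient = oop,
    oop_inpatient = rep(0, n),
    oop_ayurvedic = rep(0, n),
    oop_traditional = rep(0, n),
    oop_transport = rep(0, n),
    oop_aggregated_estimate = oop,
    hospitalized_30d = rep(FALSE, n),
    provider_type = rep("private", n),
    stringsAsFactors = FALSE
  )
}

make_episodes <- function(household_id = character(0),
                          illness_code = character(0),
                          cost_group_id = character(0),
                          reported_cost = numeric(0)) {
  data.frame(
    household_id = household_id,
    illness_code = illness_code,
    adult_only = illness_code %in% adult_only_codes,
    cost_group_id = cost_group_id,
    reported_cost = reported_cost,
    stringsAsFactors = FALSE
  )
}

# independent pairwise (sorted-pairs) form of the concentration index,
# valid for equal weights: C = sum_ij (y_i - y_j) sign(r_i - r_j) / (2 n^2 mu)
brute_force_ci <- function(y, r) {
  n <- length(y)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- s + (y[i] - y[j]) * sign(r[i] - r[j])
    }
  }
  s / (2 * n^2 * mean(y))
}
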