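#' Ground-truth parameters for the synthetic survey generator
#'
#' Defines the data-generating process emulated by [generate_survey()]: a
#' 100-cluster urban household survey with household-level illness
#' prevalences, lognormal total expenditure, zero-inflated OOP budget
#' shares, and a configurable true catastrophe process — either a constant
#' probability `p_cat` or a linear gradient \eqn{p(r) = a + b r} over the
#' wealth rank \eqn{r \in [0,1]}, optionally multiplied by illness-specific
#' rate ratios.
#'
#' For the linear gradient, the population concentration index of the
#' catastrophe indicator has the closed form \eqn{C = b / (6 (a + b/2))},
#' which the generator records in its truth record as the recovery target.
#'
#' @param p_cat Constant true catastrophe probability (used when `gradient`
#'   is `NULL`). Default 0.138.
#' @param gradient Optional numeric `c(a, b)` for the linear probability
#'   gradient over wealth rank.
#' @param illness_prevalence Named household-level probabilities for the ten
#'   illness codes. Defaults to the all-household column of the source
#'   survey's morbidity table.
#' @param rr_map Named multiplicative effects of illness presence on the
#'   catastrophe probability (default all 1).
#' @param expenditure_mu,expenditure_sigma Log-scale parameters of 30-day
#'   total household expenditure (currency units; defaults give a median of
#'   about 25 000 rupees).
#' @param oop_share_targets Per-quintile mean OOP budget-share targets
#'   (poorest to wealthiest).
#' @param mean_household_size Expected number of members (default 4.4).
#' @param overshoot_mean Mean excess share above the threshold among
#'   catastrophic households (default 0.332).
#' @param weight_dispersion Log-scale SD of PSU-level weight variation
#'   (default 0.25; 0 gives self-weighting).
#' @param p_any_oop Probability a non-catastrophic household reports any OOP
#'   spending (default 0.76).
#' @param joint_cost_prob Probability that a household with several episodes
#'   reports their costs jointly as one comorbidity group (default 0.5).
#' @param illness_cost_means Named mean 30-day treatment costs per illness,
#'   used for episode-level reported costs.
#' @return An object of class `true_params`.
#' @export
true_params <- function(p_cat = 0.138,
                        gradient = NULL,
                        illness_prevalence = c(
                          cold_cough_fever = 0.128,
                          gastritis_peptic_ulcer = 0.036,
                          arthritis = 0.029,
                          asthma = 0.011,
                          migraine_headache = 0.009,
                          injury = 0.007,
                          heart_disease = 0.006,
                          diabetes = 0.037,
                          hypertension = 0.105,
                          hyperuricaemia = 0.007),
                        rr_map = setNames(rep(1, 10), illness_codes),
                        expenditure_mu = log(25000),
                        expenditure_sigma = 0.7,
                        oop_share_targets = c(0.107, 0.148, 0.083, 0.103, 0.069),
                        mean_household_size = 4.4,
                        overshoot_mean = 0.332,
                        weight_dispersion = 0.25,
                        p_any_oop = 0.76,
                        joint_cost_prob = 0.5,
                        illness_cost_means = c(
                          cold_cough_fever = 1500,
                          gastritis_peptic_ulcer = 2500,
                          arthritis = 3000,
                          asthma = 3500,
                          migraine_headache = 1200,
                          injury = 9000,
                          heart_disease = 12000,
                          diabetes = 4000,
                          hypertension = 2500,
                          hyperuricaemia = 1800)) {
  stopifnot(all(illness_codes %in% names(illness_prevalence)),
            all(illness_codes %in% names(rr_map)),
            all(illness_codes %in% names(illness_cost_means)))
  if (any(illness_prevalence < 0 | illness_prevalence > 1)) {
    stop("illness prevalences must lie in [0, 1]", call. = FALSE)
  }
  if (any(rr_map <= 0)) stop("rate ratios must be positive", call. = FALSE)
  if (is.null(gradient)) {
    if (p_cat < 0 || p_cat > 1) stop("`p_cat` must lie in [0, 1]", call. = FALSE)
  } else {
    a <- gradient[1]; b <- gradient[2]
    if (a < 0 || a > 1 || a + b < 0 || a + b > 1) {
      stop("gradient p(r) = a + b*r must stay in [0, 1] on [0, 1]",
           call. = FALSE)
    }
  }
  structure(
    list(p_cat = p_cat, gradient = gradient,
         illness_prevalence = illness_prevalence[illness_codes],
         rr_map = rr_map[illness_codes],
         expenditure_mu = expenditure_mu,
         expenditure_sigma = expenditure_sigma,
         oop_share_targets = oop_share_targets,
         mean_household_size = mean_household_size,
         overshoot_mean = overshoot_mean,
         weight_dispersion = weight_dispersion,
         p_any_oop = p_any_oop,
         joint_cost_prob = joint_cost_prob,
         illness_cost_means = illness_cost_means[illness_codes]),
    class = "true_params"
  )
}

#' Population concentration index of a linear probability gradient
#'
#' For a binary indicator drawn with probability \eqn{p(r) = a + b r} over
#' the fractional rank \eqn{r}, integrating \eqn{2\,\mathrm{cov}(y, r)/\mu}
#' over \eqn{r \sim U(0,1)} gives \eqn{C = b / (6 \mu)} with
#' \eqn{\mu = a + b/2}.
#'
#' @param a,b Intercept and slope of the gradient.
#' @return The population concentration index.
#' @export
gradient_true_ci <- function(a, b) {
  mu <- a + b / 2
  if (mu <= 0) stop("gradient mean must be positive", call. = FALSE)
  b / (6 * mu)
}

#' Generate the two-stage sampling design
#'
#' Emulates a design of `n_psu` enumeration areas selected with probability
#' proportional to size, each contributing a fixed cluster of `m_households`
#' households. Weights are constant within PSU (lognormal across PSUs with
#' log-scale SD `weight_dispersion`), normalized to mean 1 over households;
#' `weight_dispersion = 0` gives a self-weighting design with all weights
#' exactly 1.
#'
#' @param n_psu Number of primary sampling units (default 100).
#' @param m_households Households per PSU (default 20).
#' @param weight_dispersion Log-scale SD of PSU weight variation.
#' @param seed Integer seed; `NULL` continues from the current RNG state.
#' @return Data frame with columns `psu_id`, `household_id`, `weight`.
#' @export
generate_design <- function(n_psu = 100L, m_households = 20L,
                            weight_dispersion = 0, seed = NULL) {
  if (n_psu < 1 || m_households < 1) {
    stop("`n_psu` and `m_households` must be positive", call. = FALSE)
  }
  if (weight_dispersion < 0) {
    stop("`weight_dispersion` must be non-negative", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  g <- if (weight_dispersion == 0) rep(1, n_psu) else
    exp(rnorm(n_psu, 0, weight_dispersion))
  w <- rep(g, each = m_households)
  w <- w / mean(w)
  n <- n_psu * m_households
  data.frame(
    psu_id = rep(sprintf("P%03d", seq_len(n_psu)), each = m_households),
    household_id = sprintf("H%05d", seq_len(n)),
    weight = w,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic household survey with known ground truth
#'
#' Draws a complete two-table survey (households and illness episodes) from
#' the process described by [true_params()], together with a truth record of
#' every realized ground-truth quantity, so downstream estimators can be
#' validated by parameter recovery.
#'
#' The catastrophe process works backwards from the truth: each household's
#' catastrophe probability is `p_cat` (or `a + b*r` over its wealth rank
#' `r`), multiplied by the rate-ratio factor of every illness it carries;
#' its OOP total is then scaled so the budget share exceeds the threshold
#' `z` exactly when the drawn status says so, with the excess above `z`
#' exponential with mean `overshoot_mean`. Wealth ranks are endogenous:
#' they come from the generated per-adult-equivalent expenditure, as in the
#' downstream analysis.
#'
#' @param params A [true_params()] object.
#' @param n_psu,m_households Design dimensions (default 100 x 20).
#' @param seed Integer seed; identical `(params, seed)` give identical
#'   microdata.
#' @param config An [analysis_config()]; supplies the threshold `z` and the
#'   equivalence-scale parameters used for the endogenous wealth ranks.
#' @return A list with elements `households`, `episodes` (data frames
#'   passing [validate_survey()]) and `truth` (list of realized ground-truth
#'   quantities, including the population concentration index
#'   `true_C = b/(6 mu)` in the gradient case).
#' @export
generate_survey <- function(params = true_params(), n_psu = 100L,
                            m_households = 20L, seed = 1L,
                            config = analysis_config()) {
  stopifnot(inherits(params, "true_params"))
  set.seed(seed)
  design <- generate_design(n_psu, m_households, params$weight_dispersion,
                            seed = NULL)
  n <- nrow(design)
  z <- config$z

  # demographics: household head always an adult; member mix gives roughly
  # 9% under-5 and 5% over-65 as in the source population
  size <- 1L + rpois(n, params$mean_household_size - 1)
  head_age <- pmin(pmax(round(rnorm(n, 46, 13)), 21), 90)
  n_other <- sum(size - 1L)
  cat_draw <- sample.int(3L, n_other, replace = TRUE,
                         prob = c(0.10, 0.055, 0.845))
  other_age <- integer(n_other)
  other_age[cat_draw == 1L] <- sample(0:4, sum(cat_draw == 1L), replace = TRUE)
  other_age[cat_draw == 2L] <- sample(66:85, sum(cat_draw == 2L), replace = TRUE)
  other_age[cat_draw == 3L] <- sample(5:65, sum(cat_draw == 3L), replace = TRUE)
  others <- vector("list", n)
  sp <- split(other_age, rep(seq_len(n), size - 1L))
  others[as.integer(names(sp))] <- sp
  ages <- mapply(c, head_age, others, SIMPLIFY = FALSE)

  head_sex <- ifelse(runif(n) < 0.159, "female", "male")
  head_education <- sample(c("none", "primary", "secondary", "higher"), n,
                           replace = TRUE, prob = c(0.24, 0.134, 0.316, 0.31))

  # consumption
  x <- rlnorm(n, params$expenditure_mu, params$expenditure_sigma)
  shares <- matrix(rgamma(4 * n, shape = rep(c(9, 5, 4, 2), each = n)), n, 4)
  shares <- shares / rowSums(shares)
  consumption <- shares * x
  colnames(consumption) <- consumption_component_columns

  # endogenous wealth ranks from per-AE expenditure
  ae <- adult_equivalents(ages, config$child_weight, config$equivalence_theta)
  r <- fractional_rank(x / ae, design$weight)
  quintile <- assign_quintiles(x / ae, design$weight, config$n_quintiles)

  # illness flags (household level); adult-only codes need a member > 20
  has_adult20 <- vapply(ages, function(a) any(a > 20), logical(1))
  flags <- matrix(FALSE, n, length(illness_codes),
                  dimnames = list(NULL, illness_codes))
  for (code in illness_codes) {
    eligible <- if (code %in% adult_only_codes) has_adult20 else rep(TRUE, n)
    flags[, code] <- eligible &
      (runif(n) < params$illness_prevalence[[code]])
  }

  # catastrophe status with rate-ratio injection
  p_base <- if (is.null(params$gradient)) rep(params$p_cat, n) else
    params$gradient[1] + params$gradient[2] * r
  rr_factor <- exp(flags %*% log(params$rr_map))
  p_cat_i <- as.numeric(p_base * rr_factor)
  if (any(p_cat_i > 1 + 1e-12)) {
    stop("calibration error: catastrophe probability exceeds 1 after ",
         "rate-ratio multiplication; lower the baseline or the rate ratios",
         call. = FALSE)
  }
  E <- runif(n) < p_cat_i

  # OOP budget shares: exceed z exactly when E, stay at or below z otherwise
  target <- params$oop_share_targets[quintile]
  sigma_s <- 0.8
  s0 <- (runif(n) < params$p_any_oop) *
    rlnorm(n, log(target / params$p_any_oop) - sigma_s^2 / 2, sigma_s)
  s <- ifelse(s0 <= z, s0, z * runif(n))
  s[E] <- z + rexp(sum(E), rate = 1 / params$overshoot_mean)
  oop <- s * x

  # split the OOP total over the five payment components
  hospitalized <- runif(n) < (0.05 + 0.25 * E)
  comp_shape <- cbind(outpatient = rep(5, n),
                      inpatient = ifelse(hospitalized, 12, 0.05),
                      ayurvedic = rep(1, n),
                      traditional = rep(0.6, n),
                      transport = rep(1, n))
  comp <- matrix(rgamma(5 * n, shape = comp_shape), n, 5)
  rs <- rowSums(comp)
  rs[rs == 0] <- 1
  comp <- comp / rs * oop
  colnames(comp) <- oop_component_columns

  provider_type <- ifelse(oop <= 0, "none",
                          sample(c("public", "private", "both"), n,
                                 replace = TRUE, prob = c(0.3, 0.5, 0.2)))
  aggregated <- oop * rlnorm(n, 0, 0.05)

  households <- data.frame(
    household_id = design$household_id,
    psu_id = design$psu_id,
    weight = design$weight,
    member_ages = vapply(ages, paste, character(1), collapse = ";"),
    head_age = head_age,
    head_sex = head_sex,
    head_education = head_education,
    total_expenditure = x,
    consumption,
    comp,
    oop_aggregated_estimate = aggregated,
    hospitalized_30d = hospitalized,
    provider_type = provider_type,
    stringsAsFactors = FALSE
  )

  episodes <- generate_episodes(flags, design$household_id, params)

  truth <- list(
    seed = seed, n = n, n_psu = n_psu, m_households = m_households,
    p_cat = params$p_cat, gradient = params$gradient,
    true_C = if (is.null(params$gradient)) 0 else
      gradient_true_ci(params$gradient[1], params$gradient[2]),
    rr_map = params$rr_map,
    illness_prevalence = params$illness_prevalence,
    catastrophe_flags = E,
    realized_H = sum(design$weight * E) / sum(design$weight),
    realized_prevalence = colMeans(flags),
    wealth_rank = r, quintile = quintile, z = z
  )
  list(households = households, episodes = episodes, truth = truth)
}

# build the long episode table with jointly reported comorbidity costs
generate_episodes <- function(flags, household_ids, params) {
  idx <- which(flags, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(household_id = character(0), illness_code = character(0),
                      adult_only = logical(0), cost_group_id = character(0),
                      reported_cost = numeric(0), stringsAsFactors = FALSE))
  }
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  hh <- household_ids[idx[, 1]]
  code <- colnames(flags)[idx[, 2]]
  mean_cost <- params$illness_cost_means[code]
  sigma_c <- 0.5
  cost <- rlnorm(length(hh), log(mean_cost) - sigma_c^2 / 2, sigma_c)

  # within a multi-episode household, costs are reported jointly with
  # probability joint_cost_prob, as one comorbidity cost group
  n_ep <- table(hh)[unique(hh)]
  joint <- setNames(runif(length(n_ep)) < params$joint_cost_prob &
                      n_ep > 1L, names(n_ep))
  group <- character(length(hh))
  reported <- rep(NA_real_, length(hh))
  gid <- 0L
  for (h in names(n_ep)) {
    rows <- which(hh == h)
    if (joint[[h]]) {
      gid <- gid + 1L
      group[rows] <- sprintf("G%05d", gid)
      reported[rows[1]] <- sum(cost[rows])
    } else {
      for (rw in rows) {
        gid <- gid + 1L
        group[rw] <- sprintf("G%05d", gid)
        reported[rw] <- cost[rw]
      }
    }
  }
  data.frame(
    household_id = hh,
    illness_code = code,
    adult_only = code %in% adult_only_codes,
    cost_group_id = group,
    reported_cost = reported,
    stringsAsFactors = FALSE
  )
}
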