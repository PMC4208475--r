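#' Adult-equivalent household size
#'
#' Converts a household's member ages into adult-consumption units using the
#' two-parameter equivalence scale
#' \deqn{AE = (n_{adults} + c \cdot n_{children})^{\theta},}
#' where a child is any member younger than 15 years, \eqn{c} is the child
#' consumption weight and \eqn{\theta} the economies-of-scale exponent.
#' Living standard downstream is total expenditure per adult equivalent.
#'
#' @param member_ages Numeric vector of member ages in years (one household),
#'   or a list of such vectors.
#' @param child_weight Consumption weight for members under 15. Default 0.5.
#' @param theta Economies-of-scale exponent in (0, 1]. Default 0.9.
#' @return The AE score (scalar, or vector when `member_ages` is a list).
#' @examples
#' adult_equivalents(c(30, 28))              # 2
#' adult_equivalents(c(35, 33, 7, 4), 0.5, 0.9) # 3^0.9 = 2.688
#' @export
adult_equivalents <- function(member_ages, child_weight = 0.5, theta = 0.9) {
  if (is.list(member_ages)) {
    return(vapply(member_ages, adult_equivalents, numeric(1),
                  child_weight = child_weight, theta = theta))
  }
  if (length(member_ages) == 0L) {
    stop("`member_ages` must contain at least one member", call. = FALSE)
  }
  n_adults <- sum(member_ages >= 15)
  n_children <- sum(member_ages < 15)
  (n_adults + child_weight * n_children)^theta
}

#' Weighted fractional rank
#'
#' Positions each household in the ascending living-standard ordering at the
#' midpoint of its normalized-weight interval: with normalized weights
#' \eqn{\hat w} and households sorted ascending,
#' \eqn{r_i = \sum_{j<i} \hat w_j + \hat w_i / 2}. Tied values share the
#' midpoint rank of their tied block, which keeps the weighted mean rank at
#' exactly 0.5 under ties. These ranks are the wealth variable of the
#' concentration index.
#'
#' @param values Numeric living-standard values (e.g. per-AE expenditure).
#' @param weights Positive sampling weights, same length as `values`.
#' @return Numeric vector of ranks in (0, 1), in the input order.
#' @examples
#' fractional_rank(c(10, 20, 30, 40)) # 0.125 0.375 0.625 0.875
#' @export
fractional_rank <- function(values, weights = rep(1, length(values))) {
  n <- length(values)
  if (n == 0L) stop("`values` must be nonempty", call. = FALSE)
  if (length(weights) != n) {
    stop("`weights` must match `values` in length", call. = FALSE)
  }
  if (any(is.na(weights)) || any(weights <= 0)) {
    stop("all weights must be positive", call. = FALSE)
  }
  w <- weights / sum(weights)
  ord <- order(values)                      # stable: ties keep input order
  ws <- w[ord]
  cum <- cumsum(ws)
  # tied blocks share the weighted mid-block rank
  vs <- values[ord]
  block <- cumsum(c(TRUE, vs[-1] != vs[-n]))
  block_lo <- c(0, cum)[match(block, block)]          # cum weight before block
  block_w <- tapply(ws, block, sum)
  r_sorted <- as.numeric(block_lo + block_w[block] / 2)
  r <- numeric(n)
  r[ord] <- r_sorted
  r
}

#' Assign economic quintiles from per-adult-equivalent expenditure
#'
#' Households are ranked by living standard with [fractional_rank()] and cut
#' at weighted ranks 0.2, 0.4, 0.6, 0.8 (for the default five strata).
#' Label 1 is the poorest stratum, `n_quintiles` the wealthiest. A household
#' whose weight interval straddles a cut point is assigned to the lower
#' stratum; tied living standards share one label.
#'
#' @param values Per-AE expenditure (or any living-standard measure).
#' @param weights Positive sampling weights.
#' @param n_quintiles Number of strata (default 5).
#' @return Integer vector of labels in `1:n_quintiles`, input order.
#' @export
assign_quintiles <- function(values, weights = rep(1, length(values)),
                             n_quintiles = 5L) {
  n <- length(values)
  if (n < n_quintiles) {
    stop("need at least as many households as quintiles", call. = FALSE)
  }
  r <- fractional_rank(values, weights)
  # midpoint rank exactly on a cut point goes to the lower stratum
  q <- ceiling(r * n_quintiles - 1e-9)
  as.integer(pmin(pmax(q, 1L), n_quintiles))
}

#' Living-standard table for a household survey
#'
#' Convenience wrapper joining AE scores, per-AE expenditure, fractional
#' ranks and quintile labels to the household table.
#'
#' @param households Household data frame (see [read_survey()]).
#' @param config An [analysis_config()] object.
#' @return A data frame with columns `household_id`, `ae_score`,
#'   `per_ae_expenditure`, `frac_rank`, `quintile`, in household order.
#' @export
living_standards <- function(households, config = analysis_config()) {
  ages <- parse_member_ages(households$member_ages)
  ae <- adult_equivalents(ages, config$child_weight, config$equivalence_theta)
  per_ae <- households$total_expenditure / ae
  w <- households$weight
  if (config$quintile_weighting == "person") {
    w <- w * vapply(ages, length, integer(1))
  }
  data.frame(
    household_id = as.character(households$household_id),
    ae_score = ae,
    per_ae_expenditure = per_ae,
    frac_rank = fractional_rank(per_ae, w),
    quintile = assign_quintiles(per_ae, w, config$n_quintiles),
    stringsAsFactors = FALSE
  )
}
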