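#' Total out-of-pocket health spending
#'
#' Sums the five OOP components (outpatient, inpatient, ayurvedic, other
#' traditional, transport) into the household's 30-day OOP total. The
#' transport component can be excluded for sensitivity analyses.
#'
#' @param households Household data frame, or a numeric vector/matrix of the
#'   five components (columns in the order outpatient, inpatient, ayurvedic,
#'   traditional, transport).
#' @param include_transport Include the transport component (default `TRUE`).
#' @return Numeric vector of OOP totals.
#' @export
oop_total <- function(households, include_transport = TRUE) {
  if (is.data.frame(households)) {
    comp <- as.matrix(households[oop_component_columns])
  } else {
    comp <- rbind(c(households))
    if (is.matrix(households)) comp <- households
    colnames(comp) <- oop_component_columns
  }
  if (anyNA(comp) || any(comp < 0)) {
    stop("OOP components must be present and non-negative", call. = FALSE)
  }
  if (!include_transport) comp <- comp[, setdiff(colnames(comp), "oop_transport"), drop = FALSE]
  unname(rowSums(comp))
}

#' Out-of-pocket budget share
#'
#' The share of total household expenditure devoted to health,
#' \eqn{s_i = T_i / x_i}. The share may exceed 1: health spending financed
#' from savings or borrowing is not capped by current consumption. The
#' denominator is total reported consumption including the health spending
#' itself (the standard share-of-total definition).
#'
#' @param oop Household OOP totals \eqn{T_i}.
#' @param total_expenditure Total household expenditure \eqn{x_i}, positive.
#' @return Numeric vector of budget shares.
#' @export
oop_share <- function(oop, total_expenditure) {
  if (any(is.na(total_expenditure)) || any(total_expenditure <= 0)) {
    stop("`total_expenditure` must be positive", call. = FALSE)
  }
  if (any(is.na(oop)) || any(oop < 0)) {
    stop("`oop` must be non-negative", call. = FALSE)
  }
  oop / total_expenditure
}

#' Compare aggregated and disaggregated OOP estimates
#'
#' Respondents report both a single aggregated estimate of 30-day health
#' spending and separate component amounts. This compares the two by the
#' Wilcoxon rank-sum (Mann-Whitney) test: the z statistic uses the normal
#' approximation with tie correction; the p-value is exact for small
#' tie-free samples and otherwise uses the same normal approximation
#' (mirroring [stats::wilcox.test()]).
#'
#' @param disaggregated Component-sum OOP totals (one value per household).
#' @param aggregated The single-figure estimates; households with a missing
#'   aggregated estimate are dropped pairwise.
#' @return A list with elements `z`, `p_value`, `n`.
#' @export
compare_aggregation <- function(disaggregated, aggregated) {
  if (length(disaggregated) != length(aggregated)) {
    stop("`disaggregated` and `aggregated` must be per-household vectors ",
         "of equal length", call. = FALSE)
  }
  keep <- !is.na(aggregated) & !is.na(disaggregated)
  x <- disaggregated[keep]
  y <- aggregated[keep]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 households with both estimates", call. = FALSE)
  }
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all values tied across both groups; comparison is degenerate")
    return(list(z = 0, p_value = 1, n = length(x)))
  }
  nx <- length(x); ny <- length(y)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2   # Mann-Whitney U for x
  mu <- nx * ny / 2
  ties <- table(pooled)
  sigma2 <- nx * ny / 12 *
    ((nx + ny + 1) - sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
  z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
  p <- suppressWarnings(
    wilcox.test(x, y, exact = NULL, correct = FALSE)$p.value
  )
  list(z = z, p_value = p, n = nx)
}
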