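#' Catastrophic expenditure flag
#'
#' A household is catastrophic when its OOP budget share exceeds the
#' threshold `z` — strictly ("more than") by default.
#'
#' @param share OOP budget shares \eqn{s_i}.
#' @param z Threshold fraction (default 0.10).
#' @param strict If `TRUE` (default) flag `share > z`, else `share >= z`.
#' @return Logical vector.
#' @export
catastrophic_flag <- function(share, z = 0.10, strict = TRUE) {
  if (any(is.na(share)) || any(share < 0)) {
    stop("`share` must be non-negative", call. = FALSE)
  }
  if (strict) share > z else share >= z
}

#' Weighted catastrophic headcount
#'
#' The weighted proportion of households flagged catastrophic,
#' \eqn{H = \sum w_i E_i / \sum w_i}, with a standard error by Taylor
#' linearization of the ratio estimator. When PSU identifiers are supplied
#' the linearization clusters on PSUs (with-replacement first-stage
#' approximation); otherwise each household is its own cluster.
#'
#' @param shares OOP budget shares.
#' @param weights Positive sampling weights.
#' @param z Catastrophic threshold.
#' @param strict Strict threshold comparison (default `TRUE`).
#' @param psu_ids Optional cluster identifiers for the variance estimate.
#' @return A list with `H` (headcount ratio), `se` (linearization SE) and
#'   `n_flagged` (unweighted count of catastrophic households).
#' @export
headcount <- function(shares, weights = rep(1, length(shares)), z = 0.10,
                      strict = TRUE, psu_ids = NULL) {
  n <- length(shares)
  if (n == 0L) stop("`shares` must be nonempty", call. = FALSE)
  if (length(weights) != n || any(weights <= 0)) {
    stop("`weights` must be positive and match `shares`", call. = FALSE)
  }
  E <- catastrophic_flag(shares, z, strict)
  W <- sum(weights)
  H <- sum(weights * E) / W
  # linearized score of the ratio estimator
  u <- weights * (E - H) / W
  if (is.null(psu_ids)) psu_ids <- seq_len(n)
  zc <- tapply(u, psu_ids, sum)
  k <- length(zc)
  se <- if (k > 1) sqrt(k / (k - 1) * sum((zc - mean(zc))^2)) else NA_real_
  list(H = H, se = se, n_flagged = sum(E))
}

#' Catastrophic overshoot and mean positive overshoot
#'
#' The overshoot \eqn{O = \sum w_i (s_i - z) E_i / \sum w_i} averages the
#' excess budget share above the threshold over all households; the mean
#' positive overshoot \eqn{MPO = O / H} averages it over catastrophic
#' households only. When no household is catastrophic, `MPO` is `NA` with
#' `mpo_defined = FALSE` — never zero, so the identity \eqn{O = H \cdot MPO}
#' stays checkable whenever it is defined.
#'
#' @inheritParams headcount
#' @return A list with `O`, `MPO`, `mpo_defined`.
#' @export
overshoot <- function(shares, weights = rep(1, length(shares)), z = 0.10,
                      strict = TRUE) {
  n <- length(shares)
  if (n == 0L) stop("`shares` must be nonempty", call. = FALSE)
  E <- catastrophic_flag(shares, z, strict)
  W <- sum(weights)
  O <- sum(weights * (shares - z) * E) / W
  H <- sum(weights * E) / W
  if (H > 0) {
    list(O = O, MPO = O / H, mpo_defined = TRUE)
  } else {
    list(O = 0, MPO = NA_real_, mpo_defined = FALSE)
  }
}

#' Catastrophe summary for a survey
#'
#' Computes the full incidence/intensity summary at threshold `z`: weighted
#' headcount ratio `H` with linearization SE, catastrophic overshoot `O`,
#' mean positive overshoot `MPO`, and the unweighted flagged count.
#'
#' @inheritParams headcount
#' @return An object of class `catastrophe_summary`.
#' @export
catastrophe_summary <- function(shares, weights = rep(1, length(shares)),
                                z = 0.10, strict = TRUE, psu_ids = NULL) {
  hc <- headcount(shares, weights, z, strict, psu_ids)
  ov <- overshoot(shares, weights, z, strict)
  structure(
    list(z = z, H = hc$H, se_H = hc$se, O = ov$O, MPO = ov$MPO,
         mpo_defined = ov$mpo_defined, n_flagged = hc$n_flagged,
         n = length(shares)),
    class = "catastrophe_summary"
  )
}

#' @export
print.catastrophe_summary <- function(x, ...) {
  cat("<catastrophic expenditure summary>\n")
  cat(sprintf("  threshold z       : %.3f\n", x$z))
  cat(sprintf("  headcount H       : %.4f (SE %.4f), %d of %d households\n",
              x$H, x$se_H, x$n_flagged, x$n))
  cat(sprintf("  overshoot O       : %.4f\n", x$O))
  if (x$mpo_defined) {
    cat(sprintf("  mean pos. overshoot: %.4f\n", x$MPO))
  } else {
    cat("  mean pos. overshoot: undefined (H = 0)\n")
  }
  invisible(x)
}

#' Illness-specific catastrophe measures
#'
#' For each illness, treats the household's illness-allocated OOP cost (from
#' [allocate_joint_costs()]) as that illness's spending, forms illness
#' budget shares against total expenditure, and computes headcount,
#' overshoot and mean positive overshoot. A household contributes to an
#' illness only through its allocated cost for that illness.
#'
#' @param allocated_costs Matrix or data frame of per-household allocated
#'   costs, one column per illness code (rows align with `households`).
#' @param total_expenditures Positive household totals \eqn{x_i}.
#' @param weights Positive sampling weights.
#' @param z Catastrophic threshold.
#' @param strict Strict threshold comparison.
#' @param psu_ids Optional PSU identifiers for the headcount SE.
#' @return A data frame with one row per illness: `illness_code`, `H`,
#'   `se_H`, `O`, `MPO` (`NA` when no household is flagged), `n_flagged`.
#' @export
illness_catastrophe <- function(allocated_costs, total_expenditures,
                                weights = rep(1, length(total_expenditures)),
                                z = 0.10, strict = TRUE, psu_ids = NULL) {
  ac <- as.matrix(allocated_costs)
  bad <- setdiff(colnames(ac), illness_codes)
  if (length(bad)) {
    stop("unknown illness code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(ac < 0)) stop("allocated costs must be non-negative", call. = FALSE)
  rows <- lapply(colnames(ac), function(code) {
    s <- oop_share(ac[, code], total_expenditures)
    cs <- catastrophe_summary(s, weights, z, strict, psu_ids)
    data.frame(illness_code = code, H = cs$H, se_H = cs$se_H, O = cs$O,
               MPO = cs$MPO, n_flagged = cs$n_flagged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
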