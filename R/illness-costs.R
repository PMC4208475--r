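#' Allocate jointly reported comorbidity costs to illnesses
#'
#' Households treated for concurrent illnesses often report one total
#' treatment cost for the comorbidity. This allocates such joint costs to
#' individual illnesses by regression: ordinary least squares of the
#' cost-group total on illness presence indicators, with no intercept (all
#' cost must be attributable to listed illnesses). For each group the
#' predicted component of illness \eqn{j} is \eqn{c_j = \beta_j x_j}; the
#' group's reported cost is split in proportion to the non-negative parts
#' \eqn{c_j^+ = \max(c_j, 0)}, so allocations are non-negative and sum to
#' the reported cost exactly.
#'
#' Single-illness groups bypass the regression (`method = "single"`). If
#' every predicted component in a group is floored to zero, the cost is
#' split equally (`method = "equal_split_fallback"`).
#'
#' @param episodes Episode data frame (see [read_survey()]): columns
#'   `household_id`, `illness_code`, `cost_group_id`, `reported_cost` (one
#'   non-missing cost per group).
#' @return A list with:
#'   \item{allocations}{data frame with one row per (cost group, illness):
#'     `cost_group_id`, `household_id`, `illness_code`, `allocated`,
#'     `method`.}
#'   \item{coefficients}{named vector of fitted per-illness cost
#'     coefficients (`NA` for illnesses absent from multi-illness groups'
#'     design).}
#' @export
allocate_joint_costs <- function(episodes) {
  ep <- episodes
  if (!nrow(ep)) {
    return(list(
      allocations = data.frame(cost_group_id = character(0),
                               household_id = character(0),
                               illness_code = character(0),
                               allocated = numeric(0), method = character(0),
                               stringsAsFactors = FALSE),
      coefficients = setNames(numeric(0), character(0))
    ))
  }
  bad <- setdiff(unique(ep$illness_code), illness_codes)
  if (length(bad)) {
    stop("unknown illness code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  costs <- tapply(ep$reported_cost, ep$cost_group_id,
                  function(x) x[!is.na(x)])
  n_costs <- vapply(costs, length, integer(1))
  if (any(n_costs != 1L)) {
    stop("cost group(s) without exactly one reported cost: ",
         paste(names(costs)[n_costs != 1L], collapse = ", "), call. = FALSE)
  }
  group_cost <- vapply(costs, `[[`, numeric(1), 1L)
  groups <- names(group_cost)

  # group x illness presence indicators
  present <- unique(ep$illness_code)
  X <- matrix(0, length(groups), length(present),
              dimnames = list(groups, present))
  X[cbind(match(ep$cost_group_id, groups),
          match(ep$illness_code, present))] <- 1
  group_hh <- ep$household_id[match(groups, ep$cost_group_id)]
  multi <- rowSums(X) > 1

  beta <- setNames(rep(NA_real_, length(illness_codes)), illness_codes)
  if (any(multi)) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
      stop("illness indicator matrix is rank deficient; confounded code(s): ",
           paste(dropped, collapse = ", "), call. = FALSE)
    }
    fit <- lm.fit(X, group_cost)
    beta[present] <- fit$coefficients[present]
  } else {
    # no joint groups: per-illness mean costs, informational only
    for (code in present) {
      beta[code] <- mean(group_cost[X[, code] == 1])
    }
  }

  rows <- lapply(seq_along(groups), function(g) {
    codes <- present[X[g, ] == 1]
    total <- group_cost[g]
    if (length(codes) == 1L) {
      alloc <- total
      method <- "single"
    } else {
      comp <- pmax(beta[codes], 0)
      if (sum(comp) > 0) {
        alloc <- total * comp / sum(comp)
        method <- "regression"
      } else {
        alloc <- rep(total / length(codes), length(codes))
        method <- "equal_split_fallback"
      }
    }
    data.frame(cost_group_id = groups[g], household_id = group_hh[g],
               illness_code = codes, allocated = unname(alloc),
               method = method, stringsAsFactors = FALSE)
  })
  list(allocations = do.call(rbind, rows), coefficients = beta)
}

#' Per-household allocated costs by illness
#'
#' Pivots the output of [allocate_joint_costs()] into a households-by-illness
#' cost matrix aligned with a household table, for use by
#' [illness_catastrophe()].
#'
#' @param allocations `allocations` element of [allocate_joint_costs()].
#' @param household_ids Character vector defining row order.
#' @return Numeric matrix, `length(household_ids)` rows, one column per
#'   illness code (all ten, zero-filled).
#' @export
allocated_cost_matrix <- function(allocations, household_ids) {
  household_ids <- as.character(household_ids)
  M <- matrix(0, length(household_ids), length(illness_codes),
              dimnames = list(household_ids, illness_codes))
  if (nrow(allocations)) {
    i <- match(allocations$household_id, household_ids)
    j <- match(allocations$illness_code, illness_codes)
    keep <- !is.na(i)
    for (k in which(keep)) {
      M[i[k], j[k]] <- M[i[k], j[k]] + allocations$allocated[k]
    }
  }
  M
}
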