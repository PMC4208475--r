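#' Quintile-stratified Poisson rate ratios for catastrophic expenditure
#'
#' Fits a log-link Poisson model of the binary catastrophe flag on household
#' covariates, separately within each economic stratum, and reports
#' exponentiated coefficients as rate ratios with cluster-robust
#' (sandwich-over-PSU) Wald 95% confidence intervals. A Poisson model on a
#' binary outcome estimates rate (prevalence) ratios directly; the robust
#' variance repairs the misspecified Poisson variance.
#'
#' Cells that cannot be estimated — a covariate constant within the stratum
#' (e.g. no exposed household) or a separated fit with a diverging
#' coefficient — are returned with `estimable = FALSE` rather than a number.
#'
#' @param flags Binary outcome vector (catastrophe indicator).
#' @param covariates Data frame of model covariates; factors are expanded by
#'   treatment contrasts. The canonical adjustment set is hospitalization,
#'   household size, provider type, head age, head education, counts of
#'   members under 5 and over 65, and one indicator per illness.
#' @param quintile Optional stratum labels; `NULL` fits one pooled model.
#' @param psu_ids Optional PSU identifiers for the cluster-robust variance;
#'   without them the variance is heteroskedasticity-robust (each household
#'   its own cluster).
#' @param weights Optional sampling weights (default unweighted).
#' @param report Character vector of covariate names whose rate ratios to
#'   report; defaults to every column of `covariates`.
#' @return An object of class `rate_ratio_table`: a data frame with columns
#'   `term`, `quintile`, `RR`, `ci_low`, `ci_high`, `se_log`, `n_used`,
#'   `estimable`.
#' @export
fit_poisson_rr <- function(flags, covariates, quintile = NULL,
                           psu_ids = NULL, weights = NULL,
                           report = names(covariates)) {
  n <- length(flags)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) {
    stop("`covariates` must have one row per outcome", call. = FALSE)
  }
  if (is.null(quintile)) quintile <- rep(1L, n)
  if (is.null(weights)) weights <- rep(1, n)
  strata <- sort(unique(quintile))

  rows <- list()
  na_rows <- function(q, n_used) {
    do.call(rbind, lapply(report, function(term) data.frame(
      term = term, quintile = q, RR = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, se_log = NA_real_, n_used = n_used,
      estimable = FALSE, stringsAsFactors = FALSE)))
  }
  for (q in strata) {
    idx <- which(quintile == q)
    if (length(idx) < 3L || length(unique(flags[idx])) < 2L) {
      # too small a stratum, or no outcome variation: nothing is estimable
      rows[[length(rows) + 1L]] <- na_rows(q, length(idx))
      next
    }
    dat <- droplevels(covariates[idx, , drop = FALSE])
    # drop degenerate columns (no variation within the stratum), then any
    # remaining aliased design columns, so the sandwich variance is full rank
    keep_col <- vapply(dat, function(col) length(unique(col)) > 1L, logical(1))
    mm <- if (any(keep_col)) {
      model.matrix(~ ., data = dat[, keep_col, drop = FALSE])
    } else {
      cbind("(Intercept)" = rep(1, length(idx)))
    }
    qrm <- qr(mm)
    mm <- mm[, qrm$pivot[seq_len(qrm$rank)], drop = FALSE]
    y_q <- flags[idx]
    w_q <- weights[idx]
    fit <- suppressWarnings(
      glm(y_q ~ mm - 1, family = poisson(link = "log"), weights = w_q,
          control = list(epsilon = 1e-8, maxit = 100))
    )
    if (!fit$converged) {
      stop(sprintf("Poisson fit failed to converge in stratum %s after %d iterations",
                   q, fit$iter), call. = FALSE)
    }
    cl <- if (is.null(psu_ids)) seq_along(idx) else psu_ids[idx]
    V <- sandwich::vcovCL(fit, cluster = cl)
    cf <- coef(fit)
    names(cf) <- sub("^mm", "", names(cf))
    dimnames(V) <- list(names(cf), names(cf))
    for (term in report) {
      # factor covariates expand to several columns; report each contrast
      hits <- if (term %in% names(cf)) term else
        grep(paste0("^", term), names(cf), value = TRUE)
      hits <- setdiff(hits, "(Intercept)")
      if (!length(hits)) {
        rows[[length(rows) + 1L]] <- data.frame(
          term = term, quintile = q, RR = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, se_log = NA_real_, n_used = length(idx),
          estimable = FALSE, stringsAsFactors = FALSE)
        next
      }
      for (h in hits) {
        b <- cf[[h]]
        se <- if (h %in% rownames(V)) sqrt(V[h, h]) else NA_real_
        ok <- !is.na(b) && !is.na(se) && abs(b) < 15 && se < 10
        rows[[length(rows) + 1L]] <- data.frame(
          term = h, quintile = q,
          RR = if (ok) exp(b) else NA_real_,
          ci_low = if (ok) exp(b - qnorm(0.975) * se) else NA_real_,
          ci_high = if (ok) exp(b + qnorm(0.975) * se) else NA_real_,
          se_log = if (ok) se else NA_real_,
          n_used = length(idx), estimable = ok, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rate_ratio_table", class(out))
  out
}

#' @export
print.rate_ratio_table <- function(x, digits = 3, ...) {
  cat("<rate ratio table> (log-link Poisson, cluster-robust Wald 95% CI)\n")
  df <- as.data.frame(x)
  df$RR <- round(df$RR, digits)
  df$ci_low <- round(df$ci_low, digits)
  df$ci_high <- round(df$ci_high, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Chi-squared test of illness prevalence across quintiles
#'
#' Pearson chi-squared test (no continuity correction) on the 2 x K table of
#' household illness status by economic stratum, on unweighted counts.
#'
#' @param flags Binary household illness indicator.
#' @param quintile Stratum labels.
#' @return A list with `statistic`, `df`, `p_value`, and the contingency
#'   `table`.
#' @export
chisq_quintile_prevalence <- function(flags, quintile) {
  if (length(flags) != length(quintile)) {
    stop("`flags` and `quintile` must have equal length", call. = FALSE)
  }
  tbl <- table(factor(flags, levels = c(0, 1)), quintile)
  if (any(colSums(tbl) == 0)) {
    stop("degenerate table: a stratum has no households", call. = FALSE)
  }
  if (any(rowSums(tbl) == 0)) {
    # all households share one status: no variation to test
    return(list(statistic = 0, df = (ncol(tbl) - 1), p_value = 1,
                table = tbl))
  }
  ct <- suppressWarnings(chisq.test(tbl, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, table = tbl)
}
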