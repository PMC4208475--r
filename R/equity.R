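wmean <- function(x, w) sum(w * x) / sum(w)

# population-style weighted covariance (normalized weights)
wcov <- function(x, y, w) {
  w <- w / sum(w)
  sum(w * (x - sum(w * x)) * (y - sum(w * y)))
}

#' Concentration index
#'
#' The weighted concentration index \eqn{C = 2\,\mathrm{cov}_w(y, r) / \mu},
#' where \eqn{r} are weighted fractional wealth ranks (see
#' [fractional_rank()]) and \eqn{\mu} the weighted mean of `y`. Negative
#' values indicate concentration of `y` among poorer households. For a
#' binary `y`, `C` is bounded by \eqn{\mu - 1} and \eqn{1 - \mu}.
#'
#' @param y Per-household health variable (e.g. the catastrophe indicator).
#' @param ranks Fractional ranks \eqn{r_i} from [fractional_rank()].
#' @param weights Positive sampling weights.
#' @return The concentration index (scalar).
#' @examples
#' r <- fractional_rank(1:4)
#' concentration_index(1:4, r) # 0.25
#' @export
concentration_index <- function(y, ranks, weights = rep(1, length(y))) {
  if (length(y) != length(ranks) || length(y) != length(weights)) {
    stop("`y`, `ranks` and `weights` must have equal length", call. = FALSE)
  }
  mu <- wmean(y, weights)
  if (mu == 0) {
    stop("concentration index undefined: weighted mean of `y` is zero",
         call. = FALSE)
  }
  2 * wcov(y, ranks, weights) / mu
}

#' Delta-method standard error of the concentration index
#'
#' Uses the convenient-regression formulation: weighted least squares of the
#' transformed outcome \eqn{y^* = (2\,\mathrm{var}_w(r)/\mu)\, y} on the rank
#' \eqn{r} with an intercept. The slope equals the concentration index and
#' its heteroskedasticity-robust (sandwich) standard error is the
#' delta-method SE. With PSU identifiers the sandwich clusters on PSUs.
#'
#' @inheritParams concentration_index
#' @param psu_ids Optional cluster identifiers.
#' @return A list with `C` (the WLS slope) and `se` (robust SE).
#' @export
ci_delta_se <- function(y, ranks, weights = rep(1, length(y)),
                        psu_ids = NULL) {
  n <- length(y)
  if (n < 3) stop("need at least 3 households", call. = FALSE)
  mu <- wmean(y, weights)
  if (mu == 0) {
    stop("concentration index undefined: weighted mean of `y` is zero",
         call. = FALSE)
  }
  vr <- wcov(ranks, ranks, weights)
  ystar <- (2 * vr / mu) * y
  dat <- data.frame(ystar = ystar, r = ranks)
  fit <- lm(ystar ~ r, data = dat, weights = weights)
  # a perfect fit (constant y) makes summary.lm grumble; the robust SE is 0
  V <- suppressWarnings(if (is.null(psu_ids)) {
    sandwich::vcovHC(fit, type = "HC1")
  } else {
    sandwich::vcovCL(fit, cluster = psu_ids)
  })
  list(C = unname(coef(fit)[["r"]]), se = sqrt(V["r", "r"]))
}

#' Cluster-bootstrap confidence interval for the concentration index
#'
#' Resamples PSUs with replacement `B` times. Within each replicate the
#' fractional ranks are rebuilt from the resampled living-standard values —
#' resampling clusters changes the wealth distribution, so rank uncertainty
#' is propagated. Returns the percentile 95% interval and a p-value from
#' \eqn{z = \hat C / \mathrm{SD}_{boot}} against the standard normal.
#'
#' @param y Health variable.
#' @param living_standard Living-standard values (e.g. per-AE expenditure)
#'   from which ranks are computed, overall and within each replicate.
#' @param weights Positive sampling weights.
#' @param psu_ids Cluster identifiers; at least 2 distinct PSUs unless
#'   `resample_households = TRUE`.
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param resample_households Resample individual households instead of
#'   PSUs (for single-PSU data).
#' @return A list with `C`, `ci95` (length-2 vector), `p_value`, `sd_boot`,
#'   `B`, and the vector of replicate estimates `boot_estimates`.
#' @export
ci_bootstrap <- function(y, living_standard, weights = rep(1, length(y)),
                         psu_ids = NULL, B = 100L, seed = 1L,
                         resample_households = FALSE) {
  n <- length(y)
  if (is.null(psu_ids) || resample_households) psu_ids <- seq_len(n)
  psu_ids <- as.character(psu_ids)
  clusters <- unique(psu_ids)
  if (length(clusters) < 2L) {
    stop("bootstrap needs at least 2 PSUs; set `resample_households = TRUE` ",
         "to resample households instead", call. = FALSE)
  }
  idx_by_cluster <- split(seq_len(n), psu_ids)[clusters]
  ranks <- fractional_rank(living_standard, weights)
  C_hat <- concentration_index(y, ranks, weights)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  est <- vapply(seq_len(B), function(b) {
    take <- sample.int(length(clusters), replace = TRUE)
    idx <- unlist(idx_by_cluster[take], use.names = FALSE)
    rb <- fractional_rank(living_standard[idx], weights[idx])
    mu_b <- wmean(y[idx], weights[idx])
    if (mu_b == 0) return(NA_real_)
    concentration_index(y[idx], rb, weights[idx])
  }, numeric(1))
  est <- est[!is.na(est)]
  if (!length(est)) stop("all bootstrap replicates degenerate", call. = FALSE)
  ci95 <- unname(quantile(est, c(0.025, 0.975)))
  sd_boot <- sd(est)
  p <- if (is.na(sd_boot) || sd_boot == 0) {
    if (C_hat == 0) 1 else 0
  } else {
    2 * pnorm(-abs(C_hat / sd_boot))
  }
  list(C = C_hat, ci95 = ci95, p_value = p, sd_boot = sd_boot,
       B = as.integer(B), boot_estimates = est)
}

#' Full equity result for one health variable
#'
#' Combines the point estimate, delta-method SE and cluster-bootstrap
#' interval into one reporting object, the per-illness row of the equity
#' table.
#'
#' @inheritParams ci_bootstrap
#' @return An object of class `equity_result`: `C`, `mu`, `se_delta`,
#'   `p_delta`, `ci95` (bootstrap percentile), `p_value` (bootstrap-SE
#'   normal approximation), `B`.
#' @export
equity_result <- function(y, living_standard, weights = rep(1, length(y)),
                          psu_ids = NULL, B = 100L, seed = 1L,
                          resample_households = FALSE) {
  ranks <- fractional_rank(living_standard, weights)
  mu <- wmean(y, weights)
  C <- concentration_index(y, ranks, weights)
  if (C < -1 - 1e-8 || C > 1 + 1e-8) {
    stop("concentration index outside [-1, 1]: numerical failure")
  }
  if (all(y %in% c(0, 1)) && (C < (mu - 1) - 1e-8 || C > (1 - mu) + 1e-8)) {
    stop("binary concentration index outside its feasibility bounds")
  }
  delta <- ci_delta_se(y, ranks, weights, psu_ids)
  boot <- ci_bootstrap(y, living_standard, weights, psu_ids, B, seed,
                       resample_households)
  p_delta <- if (delta$se == 0) {
    if (C == 0) 1 else 0
  } else {
    2 * pnorm(-abs(C / delta$se))
  }
  structure(
    list(C = C, mu = mu, se_delta = delta$se, p_delta = p_delta,
         ci95 = boot$ci95, p_value = boot$p_value, sd_boot = boot$sd_boot,
         B = boot$B),
    class = "equity_result"
  )
}

#' @export
print.equity_result <- function(x, ...) {
  cat("<concentration index>\n")
  cat(sprintf("  C        : %.4f (delta SE %.4f, p %.4f)\n",
              x$C, x$se_delta, x$p_delta))
  cat(sprintf("  95%% CI   : (%.4f, %.4f)  [percentile bootstrap, B = %d]\n",
              x$ci95[1], x$ci95[2], x$B))
  cat(sprintf("  bootstrap p : %.4f\n", x$p_value))
  invisible(x)
}
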