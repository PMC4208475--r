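#' Analysis configuration
#'
#' Bundles the tunable parameters of the catastrophic-expenditure analysis.
#' Defaults follow the conventional 10%-of-total-expenditure rule and a
#' two-parameter adult-equivalence scale.
#'
#' @param z Catastrophic threshold as a fraction of total household
#'   expenditure. Default 0.10.
#' @param n_quintiles Number of economic strata (default 5, i.e. quintiles).
#' @param equivalence_theta Economies-of-scale exponent of the equivalence
#'   scale, in (0, 1]. Default 0.9.
#' @param child_weight Consumption weight of a household member younger than
#'   15 years, in [0, 1]. Default 0.5.
#' @param bootstrap_reps Number of bootstrap replicates B for concentration
#'   index confidence intervals. Default 100. Percentile intervals at B = 100
#'   are anti-conservative; increase B for final inference.
#' @param seed Integer master seed for all stochastic steps.
#' @param strict_threshold Logical; if `TRUE` (default) a household is
#'   catastrophic when its OOP share strictly exceeds `z`, otherwise when it
#'   is at least `z`.
#' @param include_transport Logical; include the transport component in total
#'   OOP spending (default `TRUE`).
#' @param quintile_weighting Either `"household"` (default) or `"person"`:
#'   whether quintile cut points weight households by the sampling weight or
#'   by weight times household size.
#'
#' @return An object of class `cathex_config` (a validated named list).
#' @examples
#' cfg <- analysis_config(z = 0.1, bootstrap_reps = 100, seed = 1)
#' cfg$z
#' @export
analysis_config <- function(z = 0.10,
                            n_quintiles = 5L,
                            equivalence_theta = 0.9,
                            child_weight = 0.5,
                            bootstrap_reps = 100L,
                            seed = 1L,
                            strict_threshold = TRUE,
                            include_transport = TRUE,
                            quintile_weighting = c("household", "person")) {
  quintile_weighting <- match.arg(quintile_weighting)
  cfg <- list(
    z = as.numeric(z),
    n_quintiles = as.integer(n_quintiles),
    equivalence_theta = as.numeric(equivalence_theta),
    child_weight = as.numeric(child_weight),
    bootstrap_reps = as.integer(bootstrap_reps),
    seed = as.integer(seed),
    strict_threshold = isTRUE(strict_threshold),
    include_transport = isTRUE(include_transport),
    quintile_weighting = quintile_weighting
  )
  if (!(cfg$z > 0 && cfg$z < 1)) {
    stop("`z` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (cfg$bootstrap_reps < 1L) {
    stop("`bootstrap_reps` must be at least 1", call. = FALSE)
  }
  if (!(cfg$equivalence_theta > 0 && cfg$equivalence_theta <= 1)) {
    stop("`equivalence_theta` must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$child_weight < 0 || cfg$child_weight > 1) {
    stop("`child_weight` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_quintiles < 2L) {
    stop("`n_quintiles` must be at least 2", call. = FALSE)
  }
  structure(cfg, class = "cathex_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Any field absent from the file keeps its [analysis_config()] default;
#' unknown fields are rejected so typos do not silently revert to defaults.
#'
#' @param path Path to a YAML file whose top-level keys mirror the arguments
#'   of [analysis_config()].
#' @return A `cathex_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, raw)
}

#' @export
print.cathex_config <- function(x, ...) {
  cat("<cathex analysis configuration>\n")
  cat(sprintf("  catastrophic threshold z : %.3f (%s)\n", x$z,
              if (x$strict_threshold) "share > z" else "share >= z"))
  cat(sprintf("  quintiles                : %d (%s-weighted)\n",
              x$n_quintiles, x$quintile_weighting))
  cat(sprintf("  equivalence scale        : (adults + %.2f*children)^%.2f\n",
              x$child_weight, x$equivalence_theta))
  cat(sprintf("  bootstrap replicates     : %d\n", x$bootstrap_reps))
  cat(sprintf("  transport in OOP total   : %s\n", x$include_transport))
  cat(sprintf("  seed                     : %d\n", x$seed))
  invisible(x)
}
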