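stage_seed <- function(master, stage) {
  # deterministic per-stage seed below 2^31
  (as.integer(master) + sum(utf8ToInt(stage)) * 1009L) %% 2147483647L
}

#' Household-level illness flags
#'
#' Collapses the episode table to a households-by-illness logical matrix
#' (at least one episode in the recall period).
#'
#' @param episodes Episode data frame.
#' @param household_ids Character vector defining row order.
#' @return Logical matrix with one column per illness code.
#' @export
illness_flags <- function(episodes, household_ids) {
  household_ids <- as.character(household_ids)
  M <- matrix(FALSE, length(household_ids), length(illness_codes),
              dimnames = list(household_ids, illness_codes))
  if (nrow(episodes)) {
    i <- match(as.character(episodes$household_id), household_ids)
    j <- match(episodes$illness_code, illness_codes)
    M[cbind(i, j)] <- TRUE
  }
  M
}

#' Run the full catastrophic-expenditure analysis pipeline
#'
#' Executes the complete analysis in order — validation, living standards,
#' comorbidity cost allocation, OOP aggregation, catastrophe measures,
#' concentration indices and quintile-stratified Poisson rate ratios — and
#' returns the four reporting tables: illness prevalence by quintile with
#' chi-squared p-values (`table2`), OOP spending components and budget
#' shares by quintile (`table3`), catastrophe incidence/intensity and
#' concentration indices overall and per illness (`table4`), and illness
#' rate ratios by quintile (`table5`).
#'
#' @param households,episodes Survey data frames (see [read_survey()]), or
#'   `NULL` when `simulate` is given.
#' @param config An [analysis_config()].
#' @param simulate Optional [true_params()]; when supplied, a synthetic
#'   survey is generated (100 PSUs x 20 households) instead of reading
#'   microdata.
#' @param out_dir Optional directory: the four tables are written as CSV and
#'   the run report as JSON. On any stage failure partial outputs are
#'   removed.
#' @return An object of class `cathex_run`: list with the four tables, the
#'   aggregation comparison, the configuration echo and a stage log.
#' @export
run_pipeline <- function(households = NULL, episodes = NULL,
                         config = analysis_config(), simulate = NULL,
                         out_dir = NULL) {
  log <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      if (!is.null(out_dir)) {
        unlink(file.path(out_dir, c("table2.csv", "table3.csv", "table4.csv",
                                    "table5.csv", "run_report.json")))
      }
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log[[length(log) + 1L]] <<- list(
      stage = name, elapsed = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  truth <- NULL
  if (!is.null(simulate)) {
    gen <- t_stage("simulate", generate_survey(
      simulate, seed = stage_seed(config$seed, "simulate"), config = config))
    households <- gen$households
    episodes <- gen$episodes
    truth <- gen$truth
  }
  if (is.null(households) || is.null(episodes)) {
    stop("supply `households` and `episodes`, or `simulate`", call. = FALSE)
  }

  t_stage("validate", {
    v <- validate_survey(households, episodes)
    if (nrow(v)) stop(sprintf("%d invariant violation(s); first: %s / %s",
                              nrow(v), v$household_id[1], v$rule[1]))
    NULL
  })

  w <- households$weight
  psu <- households$psu_id
  ls_tab <- t_stage("living_standards", living_standards(households, config))

  alloc <- t_stage("illness_costs", allocate_joint_costs(episodes))
  cost_mat <- allocated_cost_matrix(alloc$allocations,
                                    households$household_id)

  oop <- t_stage("expenditure", {
    tot <- oop_total(households, config$include_transport)
    list(total = tot, share = oop_share(tot, households$total_expenditure))
  })
  agg_cmp <- t_stage("aggregation_check", compare_aggregation(
    oop$total, households$oop_aggregated_estimate))

  flags <- illness_flags(episodes, households$household_id)

  table2 <- t_stage("table2", {
    rows <- lapply(illness_codes, function(code) {
      f <- flags[, code]
      prev_q <- vapply(seq_len(config$n_quintiles), function(q) {
        i <- ls_tab$quintile == q
        100 * weighted.mean(f[i], w[i])
      }, numeric(1))
      chi <- chisq_quintile_prevalence(as.integer(f), ls_tab$quintile)
      out <- data.frame(illness_code = code,
                        prevalence_all = 100 * weighted.mean(f, w))
      out[paste0("prevalence_q", seq_along(prev_q))] <- as.list(prev_q)
      out$chisq_p <- chi$p_value
      out
    })
    do.call(rbind, rows)
  })

  table3 <- t_stage("table3", {
    any_oop <- oop$total > 0
    rows <- lapply(seq_len(config$n_quintiles), function(q) {
      i <- ls_tab$quintile == q & any_oop
      comp_means <- vapply(oop_component_columns, function(col)
        weighted.mean(households[[col]][i], w[i]), numeric(1))
      data.frame(quintile = q, n_reporting = sum(i), t(comp_means),
                 mean_oop_share = 100 * weighted.mean(oop$share[i], w[i]))
    })
    do.call(rbind, rows)
  })

  table4 <- t_stage("table4", {
    seed_eq <- stage_seed(config$seed, "equity")
    overall <- catastrophe_summary(oop$share, w, config$z,
                                   config$strict_threshold, psu)
    y_any <- as.numeric(catastrophic_flag(oop$share, config$z,
                                          config$strict_threshold))
    eq <- if (sum(y_any) == 0) {
      list(C = NA_real_, ci95 = c(NA_real_, NA_real_), p_value = NA_real_)
    } else {
      equity_result(y_any, ls_tab$per_ae_expenditure, w, psu,
                    config$bootstrap_reps, seed_eq)
    }
    per_ill <- illness_catastrophe(cost_mat, households$total_expenditure,
                                   w, config$z, config$strict_threshold, psu)
    ill_eq <- lapply(illness_codes, function(code) {
      s <- oop_share(cost_mat[, code], households$total_expenditure)
      y <- as.numeric(catastrophic_flag(s, config$z, config$strict_threshold))
      if (sum(y) == 0) return(list(C = NA_real_, ci95 = c(NA, NA),
                                   p_value = NA_real_))
      equity_result(y, ls_tab$per_ae_expenditure, w, psu,
                    config$bootstrap_reps, seed_eq)
    })
    rows <- data.frame(
      illness_code = c("any", per_ill$illness_code),
      H_pct = 100 * c(overall$H, per_ill$H),
      C = c(eq$C, vapply(ill_eq, `[[`, numeric(1), "C")),
      C_ci_low = c(eq$ci95[1], vapply(ill_eq, function(e) e$ci95[1], numeric(1))),
      C_ci_high = c(eq$ci95[2], vapply(ill_eq, function(e) e$ci95[2], numeric(1))),
      C_p = c(eq$p_value, vapply(ill_eq, `[[`, numeric(1), "p_value")),
      O_pct = 100 * c(overall$O, per_ill$O),
      MPO_pct = 100 * c(overall$MPO, per_ill$MPO),
      stringsAsFactors = FALSE
    )
    rows
  })

  table5 <- t_stage("table5", {
    covars <- data.frame(
      hospitalized = as.integer(households$hospitalized_30d),
      household_size = vapply(parse_member_ages(households$member_ages),
                              length, integer(1)),
      provider_type = factor(households$provider_type,
                             levels = c("none", "public", "private", "both")),
      head_age = households$head_age,
      head_education = factor(
        ifelse(households$head_education %in% c("none", "primary"),
               "primary_or_lower", households$head_education),
        levels = c("primary_or_lower", "secondary", "higher")),
      n_under5 = vapply(parse_member_ages(households$member_ages),
                        function(a) sum(a < 5), integer(1)),
      n_over65 = vapply(parse_member_ages(households$member_ages),
                        function(a) sum(a > 65), integer(1))
    )
    ill <- as.data.frame(flags * 1L)
    covars <- cbind(covars, ill)
    y <- as.integer(catastrophic_flag(oop$share, config$z,
                                      config$strict_threshold))
    fit_poisson_rr(y, covars, quintile = ls_tab$quintile, psu_ids = psu,
                   report = illness_codes)
  })

  run <- structure(
    list(table2 = table2, table3 = table3, table4 = table4, table5 = table5,
         aggregation_comparison = agg_cmp, config = config, truth = truth,
         n_households = nrow(households), log = log),
    class = "cathex_run"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(table2, file.path(out_dir, "table2.csv"), row.names = FALSE)
    write.csv(table3, file.path(out_dir, "table3.csv"), row.names = FALSE)
    write.csv(table4, file.path(out_dir, "table4.csv"), row.names = FALSE)
    write.csv(as.data.frame(table5), file.path(out_dir, "table5.csv"),
              row.names = FALSE)
    report <- list(
      config = unclass(config),
      n_households = nrow(households),
      aggregation_comparison = agg_cmp[c("z", "p_value", "n")],
      log = log
    )
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.cathex_run <- function(x, ...) {
  cat("<cathex pipeline run>\n")
  cat(sprintf("  households analysed : %d\n", x$n_households))
  any_row <- x$table4[x$table4$illness_code == "any", ]
  cat(sprintf("  catastrophic headcount : %.1f%%  (overshoot %.1f%%, MPO %.1f%%)\n",
              any_row$H_pct, any_row$O_pct, any_row$MPO_pct))
  cat(sprintf("  concentration index    : %.3f (95%% CI %.3f to %.3f)\n",
              any_row$C, any_row$C_ci_low, any_row$C_ci_high))
  cat(sprintf("  aggregated vs disaggregated OOP: z = %.3f, p = %.3f\n",
              x$aggregation_comparison$z, x$aggregation_comparison$p_value))
  cat("  tables: $table2 (prevalence), $table3 (OOP), $table4 (catastrophe),",
      "$table5 (rate ratios)\n")
  invisible(x)
}
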