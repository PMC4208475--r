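#' @keywords internal
household_columns <- c(
  "household_id", "psu_id", "weight", "member_ages", "head_age", "head_sex",
  "head_education", "total_expenditure",
  "food", "nonfood", "housing", "durables",
  "oop_outpatient", "oop_inpatient", "oop_ayurvedic", "oop_traditional",
  "oop_transport", "oop_aggregated_estimate", "hospitalized_30d",
  "provider_type"
)

#' @keywords internal
episode_columns <- c(
  "household_id", "illness_code", "adult_only", "cost_group_id",
  "reported_cost"
)

oop_component_columns <- c(
  "oop_outpatient", "oop_inpatient", "oop_ayurvedic", "oop_traditional",
  "oop_transport"
)

consumption_component_columns <- c("food", "nonfood", "housing", "durables")

#' Parse a serialized member-age field
#'
#' Member ages are stored in the household table as a single
#' semicolon-separated string (e.g. `"34;31;6"`), keeping the table one row
#' per household and CSV-serializable.
#'
#' @param x Character vector of serialized age strings.
#' @return A list of numeric age vectors, one element per household.
#' @export
parse_member_ages <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), as.numeric)
}

#' Read household survey microdata
#'
#' Reads the two-table survey layout: a wide household table (one row per
#' household: design information, demographics, consumption components and
#' out-of-pocket health spending components) and a long illness-episode table
#' (one row per reported episode, with jointly reported treatment costs
#' linked by `cost_group_id` and carried on exactly one row per group).
#'
#' Both files are comma-separated UTF-8 text with a mandatory header row and
#' `.` decimal mark. Currency columns are unit-agnostic plain numbers.
#' Unknown columns are preserved; row order is preserved.
#'
#' @param household_path,episode_path Paths to the two CSV files.
#' @return A list with elements `households` and `episodes`, both data frames
#'   validated against the survey invariants.
#' @seealso [write_survey()], [validate_survey()]
#' @export
read_survey <- function(household_path, episode_path) {
  for (p in c(household_path, episode_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  hh <- read.csv(household_path, stringsAsFactors = FALSE)
  ep <- read.csv(episode_path, stringsAsFactors = FALSE)

  missing_hh <- setdiff(household_columns, names(hh))
  if (length(missing_hh)) {
    stop("household table is missing required column(s): ",
         paste(missing_hh, collapse = ", "), call. = FALSE)
  }
  missing_ep <- setdiff(episode_columns, names(ep))
  if (length(missing_ep)) {
    stop("episode table is missing required column(s): ",
         paste(missing_ep, collapse = ", "), call. = FALSE)
  }

  hh$household_id <- as.character(hh$household_id)
  hh$psu_id <- as.character(hh$psu_id)
  hh$member_ages <- as.character(hh$member_ages)
  hh$hospitalized_30d <- as.logical(hh$hospitalized_30d)
  ep$household_id <- as.character(ep$household_id)
  ep$cost_group_id <- as.character(ep$cost_group_id)
  ep$adult_only <- as.logical(ep$adult_only)

  dangling <- setdiff(unique(ep$household_id), hh$household_id)
  if (length(dangling)) {
    stop("episode table references absent household(s): ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }

  viol <- validate_survey(hh, ep)
  if (nrow(viol)) {
    stop(sprintf(
      "survey data violate invariants (%d violation(s)); first: household %s, field %s, rule '%s'",
      nrow(viol), viol$household_id[1], viol$field[1], viol$rule[1]
    ), call. = FALSE)
  }
  list(households = hh, episodes = ep)
}

#' Write household survey microdata
#'
#' Inverse of [read_survey()]: serializes the two tables as comma-separated
#' UTF-8 text. `read_survey(write_survey(...))` is the identity on valid
#' records.
#'
#' @param households,episodes Data frames as returned by [read_survey()] or
#'   [generate_survey()].
#' @param household_path,episode_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_survey <- function(households, episodes, household_path, episode_path) {
  write.csv(households, household_path, row.names = FALSE, na = "")
  write.csv(episodes, episode_path, row.names = FALSE, na = "")
  invisible(c(household_path, episode_path))
}

violation <- function(household_id, field, rule) {
  data.frame(household_id = as.character(household_id), field = field,
             rule = rule, stringsAsFactors = FALSE)
}

#' Validate survey microdata against the domain invariants
#'
#' Checks every record-level invariant of the survey data model and returns
#' the violations as a data frame rather than raising: positive sampling
#' weights, non-negative currency fields, positive total expenditure, at
#' least one household member, head age at least 15, illness codes drawn
#' from the ten-code list, and exactly one reported cost per cost group.
#'
#' @inheritParams write_survey
#' @return A data frame with columns `household_id`, `field`, `rule`; zero
#'   rows if and only if every invariant holds.
#' @export
validate_survey <- function(households, episodes) {
  v <- list()
  hh <- households
  id <- as.character(hh$household_id)

  add <- function(bad, field, rule, ids = id) {
    bad <- which(bad)
    if (length(bad)) v[[length(v) + 1L]] <<- violation(ids[bad], field, rule)
  }

  if (anyDuplicated(id)) {
    add(duplicated(id), "household_id", "household_id unique")
  }
  add(!(hh$weight > 0) | is.na(hh$weight), "weight", "weight > 0")
  add(!(hh$total_expenditure > 0) | is.na(hh$total_expenditure),
      "total_expenditure", "total_expenditure > 0")
  for (col in c(consumption_component_columns, oop_component_columns)) {
    add(is.na(hh[[col]]) | hh[[col]] < 0, col, paste(col, ">= 0"))
  }
  # aggregated estimate may be absent, but never negative
  agg <- hh$oop_aggregated_estimate
  add(!is.na(agg) & agg < 0, "oop_aggregated_estimate",
      "oop_aggregated_estimate >= 0")
  ages <- parse_member_ages(hh$member_ages)
  n_members <- vapply(ages, length, integer(1))
  bad_ages <- vapply(ages, function(a) length(a) == 0L || anyNA(a) || any(a < 0),
                     logical(1))
  add(bad_ages | n_members < 1L, "member_ages", "at least one valid member age")
  add(is.na(hh$head_age) | hh$head_age < 15, "head_age", "head_age >= 15")
  add(!hh$head_sex %in% c("male", "female"), "head_sex",
      "head_sex in {male, female}")
  add(!hh$head_education %in% c("none", "primary", "secondary", "higher"),
      "head_education", "head_education in {none, primary, secondary, higher}")
  add(!hh$provider_type %in% c("none", "public", "private", "both"),
      "provider_type", "provider_type in {none, public, private, both}")

  ep <- episodes
  if (nrow(ep)) {
    eid <- as.character(ep$household_id)
    add(!ep$illness_code %in% illness_codes, "illness_code",
        "illness_code in the 10-code list", ids = eid)
    add(ep$adult_only != (ep$illness_code %in% adult_only_codes), "adult_only",
        "adult_only consistent with illness_code", ids = eid)
    add(!is.na(ep$reported_cost) & ep$reported_cost < 0, "reported_cost",
        "reported_cost >= 0", ids = eid)
    n_costs <- tapply(!is.na(ep$reported_cost), ep$cost_group_id, sum)
    bad_groups <- names(n_costs)[n_costs != 1L]
    if (length(bad_groups)) {
      first_hh <- vapply(bad_groups, function(g) {
        eid[match(g, ep$cost_group_id)]
      }, character(1))
      v[[length(v) + 1L]] <- violation(first_hh, "cost_group_id",
                                       "one cost per group")
    }
    dangling <- !eid %in% id
    add(dangling, "household_id", "episode household_id exists", ids = eid)
  }

  if (length(v)) do.call(rbind, v) else violation(character(0), character(0),
                                                  character(0))
}

#' Survey response rate
#'
#' Proportion of selected households from which data were collected,
#' expressed as a percentage.
#'
#' @param n_responded Number of households with a completed interview.
#' @param n_selected Number of households selected into the sample.
#' @return The response rate in percent.
#' @examples
#' response_rate(1997, 2000) # 99.85, printed as 99.8% at one decimal
#' @export
response_rate <- function(n_responded, n_selected) {
  if (n_selected <= 0) stop("`n_selected` must be positive", call. = FALSE)
  if (n_responded < 0 || n_responded > n_selected) {
    stop("`n_responded` must lie in [0, n_selected]", call. = FALSE)
  }
  100 * n_responded / n_selected
}
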