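abundance_levels <- c("single", "low_aggregation", "intermediate_aggregation",
                      "potential_outbreak")

#' Four-level semi-quantitative abundance scale
#'
#' Maps a per-report COTS count to the semi-quantitative scale used to triage
#' citizen observations: a single starfish; low aggregations (2-10 starfish);
#' intermediate aggregations (11-100 starfish); potential outbreaks (more
#' than 100 starfish in one observation). The four intervals partition the
#' positive integers, so every positive count maps to exactly one level.
#'
#' @param count Positive integer vector of per-report COTS counts.
#' @return Factor with levels `single < low_aggregation <
#'   intermediate_aggregation < potential_outbreak`.
#' @export
#' @examples
#' categorize_abundance(c(1, 10, 11, 150))
categorize_abundance <- function(count) {
  if (any(is.na(count)) || any(count < 1) || any(count != floor(count))) {
    rlang::abort("count must be a positive integer",
                 class = "cotswatch_domain_error")
  }
  lev <- ifelse(count == 1, "single",
         ifelse(count <= 10, "low_aggregation",
         ifelse(count <= 100, "intermediate_aggregation",
                "potential_outbreak")))
  factor(lev, levels = abundance_levels, ordered = TRUE)
}

#' Two-level management priority
#'
#' Reports of at most ten starfish can typically be handled with low priority
#' when monitoring resources are limited; more than ten starfish in a single
#' report marks a candidate site for verification surveys ("elevated").
#' Equivalently, priority is elevated exactly when the abundance category is
#' intermediate aggregation or potential outbreak.
#'
#' @param reports Normalized report tibble (or an integer vector of counts).
#' @return Character vector `"low"`/`"elevated"`; `NA` for absence reports
#'   (count 0), which carry no priority.
#' @export
#' @examples
#' assign_priority(c(5, 10, 11))
assign_priority <- function(reports) {
  count <- if (is.data.frame(reports)) reports$abundance_count else reports
  if (any(count < 0, na.rm = TRUE)) {
    rlang::abort("count must be non-negative", class = "cotswatch_domain_error")
  }
  out <- ifelse(count > 10, "elevated", "low")
  out[is.na(count) | count == 0] <- NA_character_
  out
}

#' Summarize reports by abundance category
#'
#' Tallies accepted reports on the four-level abundance scale, optionally
#' stratified (e.g. by `observer_class` or `country`). Absence reports
#' (count 0) and reports whose abundance could not be parsed are excluded
#' from the tally; the number excluded is attached as attribute
#' `n_excluded` and explains why analysis n can be below the ingested total.
#'
#' @param reports Normalized report tibble.
#' @param by Optional character vector of stratification columns.
#' @return A tibble with the stratification columns, `level`, `n` and `prop`
#'   (proportions sum to one within each stratum). Attributes `n_used` and
#'   `n_excluded` record the tally basis.
#' @export
summarize_categories <- function(reports, by = NULL) {
  stopifnot(is.data.frame(reports))
  usable <- dplyr::filter(reports, !is.na(.data$abundance_count),
                          .data$abundance_count >= 1)
  if (nrow(usable) == 0L) {
    rlang::abort("no reports with parseable positive abundance",
                 class = "cotswatch_domain_error")
  }
  usable$level <- categorize_abundance(usable$abundance_count)
  grouped <- dplyr::group_by(usable, dplyr::across(dplyr::all_of(c(by, "level"))),
                             .drop = FALSE)
  out <- dplyr::summarise(grouped, n = dplyr::n(), .groups = "drop")
  out <- dplyr::group_by(out, dplyr::across(dplyr::all_of(by)))
  out <- dplyr::mutate(out, prop = .data$n / sum(.data$n))
  out <- dplyr::ungroup(out)
  attr(out, "n_used") <- nrow(usable)
  attr(out, "n_excluded") <- nrow(reports) - nrow(usable)
  out
}

#' Share of low-abundance reports
#'
#' Convenience helper: the proportion of reports with at most ten starfish
#' (categories `single` + `low_aggregation`), i.e. the share of records that
#' the two-level triage marks low priority.
#'
#' @param summary A category summary from [summarize_categories()] (pooled,
#'   no strata).
#' @return Numeric proportion in `[0, 1]`.
#' @export
prop_low_priority <- function(summary) {
  sum(summary$prop[summary$level %in% c("single", "low_aggregation")])
}

#' Compare abundance distributions across observer classes
#'
#' Builds the observer-class by abundance-category contingency table over
#' reports with parseable positive abundance and tests for distributional
#' differences with a Pearson chi-square test (no continuity correction;
#' expected counts from the row/column margins). Categories empty in both
#' classes are dropped before testing, so df = (rows-1) x (occupied
#' categories - 1).
#'
#' @param reports Normalized report tibble with both observer classes
#'   represented.
#' @return A list with `statistic`, `df`, `p_value`, `table` (the 2 x k
#'   contingency table) and `n` (reports used).
#' @export
compare_observer_distributions <- function(reports) {
  usable <- dplyr::filter(reports, !is.na(.data$abundance_count),
                          .data$abundance_count >= 1)
  usable$level <- categorize_abundance(usable$abundance_count)
  tab <- table(usable$observer_class, usable$level)
  if (nrow(tab) < 2L || any(rowSums(tab) == 0)) {
    rlang::abort("both observer classes must have at least one report",
                 class = "cotswatch_domain_error")
  }
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(
    statistic = unname(ht$statistic),
    df = as.integer(unname(ht$parameter)),
    p_value = unname(ht$p.value),
    table = tab,
    n = sum(tab)
  )
}
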