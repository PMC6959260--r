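#' Default qualitative abundance mapping
#'
#' Citizen observers may describe crown-of-thorns starfish (COTS) abundance
#' with free-text terms rather than numbers. This table maps the qualitative
#' terms the package understands to a representative count used in downstream
#' categorization. The mapping is deliberately editable: projects can pass
#' their own table (or load one from a YAML config, see
#' [read_run_config()]) wherever a `mapping` argument is accepted.
#'
#' The shipped defaults are: `"several"` = 5, `"dozens"` = 24,
#' `"large aggregation"` / `"large aggregations"` = 150, `"hundreds"` = 300,
#' and `"none"` / `"absent"` = 0 (an absence record).
#'
#' @return A tibble with columns `term` (lower-case) and `count`
#'   (representative non-negative integer).
#' @export
#' @examples
#' default_qualitative_mapping()
default_qualitative_mapping <- function() {
  tibble::tibble(
    term = c(
      "several", "dozens", "large aggregation", "large aggregations",
      "hundreds", "none", "absent"
    ),
    count = c(5L, 24L, 150L, 150L, 300L, 0L, 0L)
  )
}

#' Parse a raw abundance entry
#'
#' The online report form accepts quantitative (`"10"`), semi-quantitative
#' (`"2-5"`) and qualitative (`"dozens"`, `"large aggregations"`) abundance
#' entries. This function normalizes any of these into an abundance payload
#' with a representative count:
#'
#' * plain integers parse to kind `"exact"` (or `"absence"` when 0);
#' * ranges `"N-M"` (hyphen or en-dash) parse to kind `"range"` with the
#'   representative count at the midpoint, rounded down;
#' * known qualitative terms are looked up in `mapping`;
#' * unknown terms raise a classed error (`cotswatch_unparseable_abundance`)
#'   so that ingestion can flag the report for moderation and exclude it from
#'   abundance statistics rather than guess.
#'
#' @param text Character scalar, the raw abundance entry.
#' @param mapping Qualitative-term table, as from
#'   [default_qualitative_mapping()].
#' @return A list with elements `kind` (one of `"exact"`, `"range"`,
#'   `"qualitative"`, `"absence"`), `count` (non-negative integer), `lower`,
#'   `upper` (integers, `NA` unless a range) and `term` (the original
#'   qualitative string, `NA` otherwise).
#' @export
#' @examples
#' parse_abundance("10")
#' parse_abundance("2-5")
#' parse_abundance("large aggregations")
parse_abundance <- function(text, mapping = default_qualitative_mapping()) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop_unparseable("empty abundance entry")
  }
  txt <- trimws(as.character(text))
  # normalize unicode dashes so "2–5" behaves like "2-5"
  txt_ascii <- gsub("[‐-―−]", "-", txt)

  if (grepl("^[0-9]+$", txt_ascii)) {
    n <- as.integer(txt_ascii)
    kind <- if (n == 0L) "absence" else "exact"
    return(abundance_payload(kind, n))
  }
  m <- regmatches(
    txt_ascii,
    regexec("^([0-9]+)[[:space:]]*-[[:space:]]*([0-9]+)$", txt_ascii)
  )[[1]]
  if (length(m) == 3L) {
    lo <- as.integer(m[2]); hi <- as.integer(m[3])
    if (lo > hi) stop_unparseable(sprintf("range '%s' has lower > upper", txt))
    mid <- as.integer((lo + hi) %/% 2L)  # midpoint, rounded down
    return(abundance_payload("range", mid, lower = lo, upper = hi))
  }
  key <- tolower(gsub("[[:punct:]]+$", "", txt))
  hit <- match(key, mapping$term)
  if (!is.na(hit)) {
    n <- as.integer(mapping$count[hit])
    kind <- if (n == 0L) "absence" else "qualitative"
    return(abundance_payload(kind, n, term = txt))
  }
  stop_unparseable(sprintf("unknown qualitative abundance term '%s'", txt))
}

abundance_payload <- function(kind, count, lower = NA_integer_,
                              upper = NA_integer_, term = NA_character_) {
  stopifnot(count >= 0L)
  list(kind = kind, count = as.integer(count), lower = as.integer(lower),
       upper = as.integer(upper), term = term)
}

stop_unparseable <- function(msg) {
  rlang::abort(msg, class = "cotswatch_unparseable_abundance")
}

stop_validation <- function(msg) {
  rlang::abort(msg, class = "cotswatch_validation_error")
}

#' Classify an observer as professional or non-professional
#'
#' Reports are stratified by observer expertise: professionals (scientists,
#' experts, trained volunteers) versus non-professionals (recreational
#' fishers, snorkelers, divers, community members). Research and government
#' stakeholders always classify as professional; private individuals as
#' non-professional; NGO and business observers are professional only when
#' flagged as trained — the trained-volunteer pathway is the only professional
#' route for those groups.
#'
#' @param stakeholder Character vector with values in
#'   `c("private_individual", "business", "NGO", "government", "research")`.
#' @param trained Logical vector (recycled), whether the observer has been
#'   trained by the project.
#' @param mapping Named character vector giving the base class per
#'   stakeholder; entries `"trained_only"` become professional only with
#'   `trained = TRUE`.
#' @return Character vector, `"professional"` or `"non_professional"`.
#' @export
#' @examples
#' classify_observer("research")
#' classify_observer("NGO", trained = TRUE)
classify_observer <- function(stakeholder, trained = FALSE,
                              mapping = default_observer_mapping()) {
  stakeholder <- as.character(stakeholder)
  bad <- setdiff(unique(stakeholder), names(mapping))
  if (length(bad)) {
    stop_validation(sprintf("unknown stakeholder category: %s",
                            paste(bad, collapse = ", ")))
  }
  trained <- rep_len(as.logical(trained), length(stakeholder))
  base <- unname(mapping[stakeholder])
  ifelse(base == "trained_only",
         ifelse(trained, "professional", "non_professional"),
         base)
}

#' @rdname classify_observer
#' @export
default_observer_mapping <- function() {
  c(research = "professional",
    government = "professional",
    private_individual = "non_professional",
    NGO = "trained_only",
    business = "trained_only")
}

report_mandatory_fields <- c(
  "observer_name", "observer_contact", "date", "lon", "lat",
  "context", "abundance_raw"
)

report_columns <- c(
  "report_id", "observer_name", "observer_contact", "date", "lon", "lat",
  "country", "context", "depth_min", "depth_max", "abundance_raw",
  "abundance_kind", "abundance_count", "abundance_lower", "abundance_upper",
  "abundance_term", "stakeholder", "trained", "observer_class",
  "swim_duration", "distance_covered", "juveniles_seen", "live_coral_cover",
  "feeding_scars", "survey_method", "moderation"
)

#' Parse and validate one raw observation report
#'
#' Validates a single raw record against the standardized report form:
#' mandatory fields (observer name and contact, date, position, activity
#' context, abundance entry) must be present, coordinates must be valid WGS84
#' decimal degrees, and the date must not be in the future. The abundance
#' entry is parsed with [parse_abundance()] and the observer class derived
#' with [classify_observer()]. New reports always start with
#' `moderation = "pending"`.
#'
#' @param raw A named list (or one-row data frame) of raw form fields. Field
#'   names follow the normalized schema: `observer_name`, `observer_contact`,
#'   `date`, `lon`, `lat`, `context`, `abundance_raw`, and optionally
#'   `report_id`, `country`, `depth_min`, `depth_max`, `stakeholder`,
#'   `trained`, `swim_duration`, `distance_covered`, `juveniles_seen`,
#'   `live_coral_cover`, `feeding_scars`, `survey_method`.
#' @param mapping Qualitative-term table for [parse_abundance()].
#' @param observer_mapping Stakeholder-to-class table for
#'   [classify_observer()].
#' @param today Upper bound for report dates (default the current date);
#'   exposed so ingestion of historical archives is reproducible.
#' @return A one-row tibble in the normalized report schema.
#' @export
#' @examples
#' parse_report(list(
#'   observer_name = "A. Diver", observer_contact = "a@example.org",
#'   date = "2015-11-03", lon = 166.9, lat = -22.4,
#'   context = "snorkeling", abundance_raw = "10",
#'   stakeholder = "private_individual"
#' ))
parse_report <- function(raw, mapping = default_qualitative_mapping(),
                         observer_mapping = default_observer_mapping(),
                         today = Sys.Date()) {
  if (is.data.frame(raw)) raw <- as.list(raw)
  get1 <- function(name, default = NA) {
    v <- raw[[name]]
    if (is.null(v) || length(v) == 0L) default else v[[1]]
  }

  missing_fields <- report_mandatory_fields[vapply(
    report_mandatory_fields,
    function(f) {
      v <- raw[[f]]
      is.null(v) || length(v) == 0L || is.na(v[[1]]) ||
        (is.character(v[[1]]) && !nzchar(trimws(v[[1]])))
    },
    logical(1)
  )]
  if (length(missing_fields)) {
    stop_validation(sprintf("%s required", missing_fields[1]))
  }

  date <- tryCatch(as.Date(as.character(get1("date"))), error = function(e) NA)
  if (is.na(date)) stop_validation("date unparseable (expected ISO 8601)")
  if (date > today) stop_validation("date is in the future")

  lon <- suppressWarnings(as.numeric(get1("lon")))
  lat <- suppressWarnings(as.numeric(get1("lat")))
  if (is.na(lon) || is.na(lat)) stop_validation("coordinates unparseable")
  if (lon < -180 || lon > 180) stop_validation("longitude outside [-180, 180]")
  if (lat < -90 || lat > 90) stop_validation("latitude outside [-90, 90]")

  context <- as.character(get1("context"))
  if (!context %in% c("snorkeling", "scuba", "other")) {
    stop_validation(sprintf("unknown activity context '%s'", context))
  }

  stakeholder <- as.character(get1("stakeholder", "private_individual"))
  trained <- isTRUE(as.logical(get1("trained", FALSE)))
  ab <- parse_abundance(as.character(get1("abundance_raw")), mapping)

  tibble::tibble(
    report_id = as.character(get1("report_id", paste0("R", format(date, "%Y%m%d"), "-", substr(rlang::hash(raw), 1, 8)))),
    observer_name = as.character(get1("observer_name")),
    observer_contact = as.character(get1("observer_contact")),
    date = date,
    lon = lon, lat = lat,
    country = as.character(get1("country", "other")),
    context = context,
    depth_min = suppressWarnings(as.numeric(get1("depth_min"))),
    depth_max = suppressWarnings(as.numeric(get1("depth_max"))),
    abundance_raw = as.character(get1("abundance_raw")),
    abundance_kind = ab$kind,
    abundance_count = ab$count,
    abundance_lower = ab$lower,
    abundance_upper = ab$upper,
    abundance_term = ab$term,
    stakeholder = stakeholder,
    trained = trained,
    observer_class = classify_observer(stakeholder, trained, observer_mapping),
    swim_duration = suppressWarnings(as.numeric(get1("swim_duration"))),
    distance_covered = suppressWarnings(as.numeric(get1("distance_covered"))),
    juveniles_seen = as.logical(get1("juveniles_seen", NA)),
    live_coral_cover = suppressWarnings(as.numeric(get1("live_coral_cover"))),
    feeding_scars = as.logical(get1("feeding_scars", NA)),
    survey_method = as.character(get1("survey_method", NA_character_)),
    moderation = "pending"
  )
}

#' Moderate a report
#'
#' Observation reports are validated by a project moderator before entering
#' any analysis; only accepted reports are used downstream. A report can be
#' moderated exactly once.
#'
#' @param report A one-row report tibble with `moderation = "pending"`.
#' @param decision `"accepted"` or `"rejected"`.
#' @return The report with its moderation state set.
#' @export
moderate <- function(report, decision = c("accepted", "rejected")) {
  decision <- match.arg(decision)
  stopifnot(is.data.frame(report), nrow(report) == 1L)
  if (!identical(report$moderation, "pending")) {
    rlang::abort(
      sprintf("report %s already moderated (%s)", report$report_id,
              report$moderation),
      class = "cotswatch_state_error"
    )
  }
  report$moderation <- decision
  report
}

#' Keep only moderator-accepted reports
#'
#' @param reports Normalized report tibble.
#' @return The accepted subset.
#' @export
accepted_reports <- function(reports) {
  dplyr::filter(reports, .data$moderation == "accepted")
}
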