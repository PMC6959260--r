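# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk unless a test writes it first.

raw_report <- function(...) {
  utils::modifyList(
    list(
      observer_name = "A. Diver",
      observer_contact = "diver@example.org",
      date = "2015-11-03",
      lon = 166.9, lat = -22.4,
      country = "NC",
      context = "snorkeling",
      abundance_raw = "10",
      stakeholder = "private_individual"
    ),
    list(...)
  )
}

# Normalized accepted reports with given counts / classes / positions,
# bypassing the form parser (counts are already representative integers).
make_reports <- function(counts,
                         observer_class = "non_professional",
                         lon = 166.45, lat = -22.25,
                         country = "NC") {
  n <- length(counts)
  tibble::tibble(
    report_id = sprintf("F%03d", seq_len(n)),
    observer_name = "Fixture",
    observer_contact = "fixture@example.org",
    date = as.Date("2016-06-01"),
    lon = rep_len(lon, n), lat = rep_len(lat, n),
    country = rep_len(country, n),
    context = "snorkeling",
    abundance_raw = as.character(counts),
    abundance_kind = ifelse(counts == 0, "absence", "exact"),
    abundance_count = as.integer(counts),
    abundance_lower = NA_integer_, abundance_upper = NA_integer_,
    abundance_term = NA_character_,
    stakeholder = ifelse(rep_len(observer_class, n) == "professional",
                         "research", "private_individual"),
    trained = FALSE,
    observer_class = rep_len(observer_class, n),
    swim_duration = NA_real_, distance_covered = NA_real_,
    juveniles_seen = NA, live_coral_cover = NA_real_, feeding_scars = NA,
    survey_method = NA_character_,
    moderation = "accepted"
  )
}

# place one report per requested quadrat index for a given spec/class
reports_in_quadrats <- function(idx, observer_class, spec) {
  cell_m <- spec$cell_km * 1000
  centers <- unproject_from_grid((idx$ix + 0.5) * cell_m,
                                 (idx$iy + 0.5) * cell_m, spec)
  out <- make_reports(rep(1L, nrow(idx)), observer_class = observer_class)
  out$lon <- centers$lon
  out$lat <- centers$lat
  out
}

make_survey <- function(site_id, method, counts, area_m2 = 100,
                        duration_min = 10) {
  tibble::tibble(
    site_id = site_id,
    method = method,
    count = as.integer(counts),
    area_m2 = ifelse(method == "belt_transect", area_m2, NA_real_),
    duration_min = ifelse(method == "timed_swim", duration_min, NA_real_),
    distance_m = NA_real_
  )
}
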