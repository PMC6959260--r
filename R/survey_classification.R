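outbreak_levels <- c("non_outbreak", "potential_outbreak", "confirmed_outbreak")

#' Belt-transect density
#'
#' Converts a belt-transect COTS count to a density in individuals per
#' hectare: `density = count / area_m2 * 10000`. Verification surveys use
#' 100 m2 belts by default, so 1 COTS on a standard belt is 100 ind/ha.
#'
#' @param count Non-negative count(s) of COTS on the transect.
#' @param area_m2 Transect area(s) in square meters (default 100).
#' @return Density in COTS per hectare.
#' @export
#' @examples
#' transect_density(7, 100)  # 700 ind/ha
transect_density <- function(count, area_m2 = 100) {
  if (any(area_m2 <= 0)) {
    rlang::abort("transect area must be positive",
                 class = "cotswatch_domain_error")
  }
  if (any(count < 0)) {
    rlang::abort("count must be non-negative",
                 class = "cotswatch_domain_error")
  }
  count / area_m2 * 10000
}

#' Area scanned during a timed swim
#'
#' The reef surface covered by a timed swim is the linear distance travelled
#' along the reef edge multiplied by the "path width" — the lateral strip an
#' observer effectively scans. An empirical path width of 2 m is used by
#' default (it varies with depth, complexity, visibility and observer).
#'
#' @param distance_m Distance swum, meters.
#' @param path_width_m Scanned width, meters (default 2).
#' @return Area in square meters.
#' @export
#' @examples
#' swim_area(250)  # 500 m2; 5 COTS here is 100 ind/ha
swim_area <- function(distance_m, path_width_m = 2) {
  if (any(distance_m <= 0) || any(path_width_m <= 0)) {
    rlang::abort("distance and path width must be positive",
                 class = "cotswatch_domain_error")
  }
  distance_m * path_width_m
}

#' Three-level outbreak classification from density
#'
#' Classifies a COTS density on the conservative three-level scale built
#' from the two threshold groups recurrent in the outbreak literature
#' (10-15 and 100-150 ind/ha): below 15 ind/ha is non-outbreak, 15-100
#' ind/ha (closed band) is a potential outbreak, above 100 ind/ha a
#' confirmed outbreak.
#'
#' @param density Non-negative density, COTS per hectare.
#' @param breaks Two increasing thresholds `c(lo, hi)` (default `c(15,
#'   100)`): densities below `lo` are non-outbreak, within `[lo, hi]`
#'   potential, above `hi` confirmed. The bands are closed on both sides at
#'   the potential level, matching the printed threshold table.
#' @return Ordered factor `non_outbreak < potential_outbreak <
#'   confirmed_outbreak`.
#' @export
#' @examples
#' classify_density(c(10, 50, 7000))
classify_density <- function(density, breaks = c(15, 100)) {
  if (any(is.na(density)) || any(density < 0)) {
    rlang::abort("density must be non-negative",
                 class = "cotswatch_domain_error")
  }
  stopifnot(length(breaks) == 2, breaks[1] < breaks[2])
  lev <- ifelse(density < breaks[1], "non_outbreak",
         ifelse(density <= breaks[2], "potential_outbreak",
                "confirmed_outbreak"))
  factor(lev, levels = outbreak_levels, ordered = TRUE)
}

#' Three-level outbreak classification from timed-swim abundance
#'
#' Classification bands for ten-minute swims, the abundance equivalent of
#' the density scale obtained with the empirical path-width conversion:
#' 0-1 COTS per swim is non-outbreak, 2-5 a potential outbreak, more than 5
#' a confirmed outbreak. Swims of other durations must be rescaled to a
#' ten-minute equivalent first (see [classify_site()]). Non-integer values
#' (e.g. a site mean) are classified against the same bands, with values
#' below 2 non-outbreak.
#'
#' @param n COTS per ten-minute swim (non-negative; may be fractional for
#'   site means).
#' @param breaks Two increasing thresholds `c(lo, hi)` (default `c(2, 5)`):
#'   below `lo` non-outbreak, within `[lo, hi]` potential, above `hi`
#'   confirmed.
#' @return Ordered factor `non_outbreak < potential_outbreak <
#'   confirmed_outbreak`.
#' @export
#' @examples
#' classify_swim(c(1, 2, 6, 605))
classify_swim <- function(n, breaks = c(2, 5)) {
  if (any(is.na(n)) || any(n < 0)) {
    rlang::abort("swim abundance must be non-negative",
                 class = "cotswatch_domain_error")
  }
  stopifnot(length(breaks) == 2, breaks[1] < breaks[2])
  lev <- ifelse(n < breaks[1], "non_outbreak",
         ifelse(n <= breaks[2], "potential_outbreak", "confirmed_outbreak"))
  factor(lev, levels = outbreak_levels, ordered = TRUE)
}

#' Classify a verification site
#'
#' Aggregates all survey records of one site into a site status. Belt
#' transects are converted to densities; timed swims are rescaled linearly
#' to ten-minute equivalents. Each method's mean is classified on the
#' three-level scale and the site takes the more severe of the two levels
#' when both methods are present. Per-method means with standard errors
#' (n - 1 denominator) and peak values are reported alongside.
#'
#' @param records A survey tibble for one site with columns `site_id`,
#'   `method` (`"belt_transect"` or `"timed_swim"`), `count`, and `area_m2`
#'   (transects) or `duration_min` (swims; `distance_m` optional).
#' @param density_breaks,swim_breaks Threshold overrides passed to
#'   [classify_density()] and [classify_swim()].
#' @return A one-row tibble: `site_id`, `level`, per-method `n`, mean, SE
#'   and peak (`density_*` for transects in ind/ha, `swim_*` in COTS per
#'   10-min swim), and `any_cots` (presence).
#' @export
classify_site <- function(records, density_breaks = c(15, 100),
                          swim_breaks = c(2, 5)) {
  if (nrow(records) == 0L) {
    rlang::abort("no survey records for site", class = "cotswatch_domain_error")
  }
  stopifnot(length(unique(records$site_id)) == 1L)
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_

  bt <- records[records$method == "belt_transect", ]
  sw <- records[records$method == "timed_swim", ]
  levels_seen <- character(0)

  dens <- numeric(0)
  if (nrow(bt) > 0) {
    area <- if ("area_m2" %in% names(bt)) dplyr::coalesce(bt$area_m2, 100) else rep(100, nrow(bt))
    dens <- transect_density(bt$count, area)
    levels_seen <- c(levels_seen,
                     as.character(classify_density(mean(dens),
                                                   density_breaks)))
  }
  ab10 <- numeric(0)
  if (nrow(sw) > 0) {
    dur <- if ("duration_min" %in% names(sw)) dplyr::coalesce(sw$duration_min, 10) else rep(10, nrow(sw))
    if (any(dur <= 0)) {
      rlang::abort("swim duration must be positive",
                   class = "cotswatch_domain_error")
    }
    ab10 <- sw$count * 10 / dur  # 10-minute equivalent
    levels_seen <- c(levels_seen,
                     as.character(classify_swim(mean(ab10), swim_breaks)))
  }
  # severity-max across methods
  level <- outbreak_levels[max(match(levels_seen, outbreak_levels))]

  tibble::tibble(
    site_id = records$site_id[1],
    level = factor(level, levels = outbreak_levels, ordered = TRUE),
    n_transects = nrow(bt),
    density_mean = if (length(dens)) mean(dens) else NA_real_,
    density_se = if (length(dens)) se(dens) else NA_real_,
    density_peak = if (length(dens)) max(dens) else NA_real_,
    n_swims = nrow(sw),
    swim_mean = if (length(ab10)) mean(ab10) else NA_real_,
    swim_se = if (length(ab10)) se(ab10) else NA_real_,
    swim_peak = if (length(ab10)) max(ab10) else NA_real_,
    any_cots = any(records$count > 0)
  )
}

#' Classify every site in a survey table
#'
#' @param surveys Survey tibble covering one or more sites.
#' @inheritParams classify_site
#' @return A site-status tibble, one row per site (see [classify_site()]).
#' @export
classify_sites <- function(surveys, density_breaks = c(15, 100),
                           swim_breaks = c(2, 5)) {
  surveys |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_split() |>
    purrr::map(classify_site, density_breaks = density_breaks,
               swim_breaks = swim_breaks) |>
    dplyr::bind_rows()
}

#' Summarize verification-site statuses
#'
#' @param statuses A site-status tibble from [classify_sites()].
#' @return A list with `n_sites`, `proportions` (tibble of level, n,
#'   percent), `presence_pct` (percent of sites where any COTS was seen) and
#'   pooled per-method means with SD (`swim_mean`, `swim_sd`,
#'   `density_mean`, `density_sd`), weighting each site's mean equally.
#' @export
summarize_sites <- function(statuses) {
  if (nrow(statuses) == 0L) {
    rlang::abort("no site statuses", class = "cotswatch_domain_error")
  }
  tab <- table(factor(statuses$level, levels = outbreak_levels))
  props <- tibble::tibble(
    level = names(tab),
    n = as.integer(tab),
    percent = as.numeric(tab) / nrow(statuses) * 100
  )
  list(
    n_sites = nrow(statuses),
    proportions = props,
    presence_pct = mean(statuses$any_cots) * 100,
    swim_mean = mean(statuses$swim_mean, na.rm = TRUE),
    swim_sd = stats::sd(statuses$swim_mean, na.rm = TRUE),
    density_mean = mean(statuses$density_mean, na.rm = TRUE),
    density_sd = stats::sd(statuses$density_mean, na.rm = TRUE)
  )
}
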