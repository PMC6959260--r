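#' Simulate a patchy reef COTS population
#'
#' Generates starfish positions on a rectangular reef as the superposition
#' of a homogeneous Poisson background and a cluster (Thomas-type) process
#' with uniform-disc offspring: each cluster contributes a
#' Poisson-distributed number of starfish placed uniformly within a disc
#' around its center. Aggregations at the tens-of-meters scale are a
#' documented feature of outbreak populations — dense patches can occupy a
#' 50 m stretch of an otherwise unaffected reef — so the default cluster
#' radius is 25 m. Offspring falling outside the extent are redrawn within
#' their disc, so the expected total point count is
#' `background_intensity * area + sum(mu)` (Campbell's formula) whenever the
#' clusters lie inside the extent.
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in meters.
#' @param background_intensity Background density, COTS per hectare.
#' @param clusters Optional data frame with columns `x`, `y` (cluster
#'   centers, meters), `radius` (disc radius, meters) and `mu` (expected
#'   starfish per cluster). `NULL` or zero rows for a purely Poisson reef.
#' @param seed Optional integer seed; identical parameters and seed give
#'   identical reefs.
#' @return An object of class `sim_reef`: a list with `points` (tibble
#'   `x`, `y`), plus the generating parameters.
#' @export
#' @examples
#' reef <- simulate_population(c(0, 500, 0, 200), background_intensity = 20,
#'                             seed = 1)
#' nrow(reef$points)
simulate_population <- function(extent, background_intensity = 0,
                                clusters = NULL, seed = NULL) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  if (background_intensity < 0) {
    rlang::abort("intensity must be non-negative",
                 class = "cotswatch_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  w <- extent[2] - extent[1]
  h <- extent[4] - extent[3]
  area_ha <- w * h / 10000

  n_bg <- stats::rpois(1, background_intensity * area_ha)
  pts <- tibble::tibble(
    x = stats::runif(n_bg, extent[1], extent[2]),
    y = stats::runif(n_bg, extent[3], extent[4])
  )

  if (!is.null(clusters) && nrow(clusters) > 0) {
    for (i in seq_len(nrow(clusters))) {
      n_off <- stats::rpois(1, clusters$mu[i])
      if (n_off == 0) next
      cx <- clusters$x[i]; cy <- clusters$y[i]; rad <- clusters$radius[i]
      ox <- numeric(n_off); oy <- numeric(n_off)
      todo <- seq_len(n_off)
      while (length(todo)) {  # rejection keeps offspring inside the extent
        r <- rad * sqrt(stats::runif(length(todo)))
        th <- stats::runif(length(todo), 0, 2 * pi)
        ox[todo] <- cx + r * cos(th)
        oy[todo] <- cy + r * sin(th)
        todo <- todo[ox[todo] < extent[1] | ox[todo] > extent[2] |
                       oy[todo] < extent[3] | oy[todo] > extent[4]]
      }
      pts <- dplyr::bind_rows(pts, tibble::tibble(x = ox, y = oy))
    }
  }

  structure(
    list(points = pts, extent = extent,
         background_intensity = background_intensity,
         clusters = clusters, seed = seed),
    class = "sim_reef"
  )
}

#' @export
print.sim_reef <- function(x, ...) {
  cat(sprintf(
    "<sim_reef> %d COTS on %.1f ha (background %.1f / ha, %d clusters)\n",
    nrow(x$points), diff(x$extent[1:2]) * diff(x$extent[3:4]) / 1e4,
    x$background_intensity,
    if (is.null(x$clusters)) 0L else nrow(x$clusters)
  ))
  invisible(x)
}

# sample a rectangle (center, angle) that fits entirely inside the extent
place_rectangles <- function(n, extent, length_m, width_m) {
  theta <- stats::runif(n, 0, 2 * pi)
  hx <- abs(cos(theta)) * length_m / 2 + abs(sin(theta)) * width_m / 2
  hy <- abs(sin(theta)) * length_m / 2 + abs(cos(theta)) * width_m / 2
  if (any(extent[1] + hx > extent[2] - hx) ||
      any(extent[3] + hy > extent[4] - hy)) {
    rlang::abort("survey unit does not fit inside the reef extent",
                 class = "cotswatch_domain_error")
  }
  tibble::tibble(
    cx = stats::runif(n, extent[1] + hx, extent[2] - hx),
    cy = stats::runif(n, extent[3] + hy, extent[4] - hy),
    theta = theta
  )
}

count_in_rectangle <- function(points, cx, cy, theta, length_m, width_m) {
  dx <- points$x - cx
  dy <- points$y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  sum(abs(u) <= length_m / 2 & abs(v) <= width_m / 2)
}

#' Simulate belt-transect surveys on a reef
#'
#' Lays `n` belt transects (default 50 m x 2 m = the standard 100 m2 belt)
#' uniformly at random positions and orientations within the reef, with
#' perfect detection inside the belt, and returns survey records ready for
#' [classify_sites()].
#'
#' @param reef A `sim_reef`.
#' @param n Number of transects.
#' @param length_m,width_m Belt dimensions, meters (defaults 50 x 2).
#' @param seed Optional integer seed.
#' @param site_id Site label stamped on the records.
#' @return A survey tibble (`site_id`, `method`, `count`, `area_m2`).
#' @export
simulate_belt_transects <- function(reef, n, length_m = 50, width_m = 2,
                                    seed = NULL, site_id = "SIM") {
  stopifnot(inherits(reef, "sim_reef"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  pos <- place_rectangles(n, reef$extent, length_m, width_m)
  counts <- vapply(seq_len(n), function(i) {
    count_in_rectangle(reef$points, pos$cx[i], pos$cy[i], pos$theta[i],
                       length_m, width_m)
  }, integer(1))
  tibble::tibble(
    site_id = site_id,
    method = "belt_transect",
    count = counts,
    area_m2 = length_m * width_m,
    duration_min = NA_real_,
    distance_m = NA_real_
  )
}

#' Simulate timed-swim surveys on a reef
#'
#' Simulates standardized timed swims as straight corridors
#' (`distance_m` x `path_width_m`) at uniform random positions and
#' orientations. Starfish inside the corridor are detected independently
#' with probability `detect_p` (binomial thinning); with `detect_p = 1` a
#' swim is geometrically identical to a belt transect of the same
#' dimensions.
#'
#' @param reef A `sim_reef`.
#' @param n Number of swims.
#' @param distance_m Distance covered per swim, meters (default 250, a
#'   typical ten-minute swim along the reef edge).
#' @param path_width_m Scanned width, meters (default 2).
#' @param detect_p Per-starfish detection probability in (0, 1].
#' @param duration_min Swim duration, minutes (default 10).
#' @param seed Optional integer seed.
#' @param site_id Site label stamped on the records.
#' @return A survey tibble (`site_id`, `method`, `count`, `duration_min`,
#'   `distance_m`).
#' @export
simulate_timed_swims <- function(reef, n, distance_m = 250, path_width_m = 2,
                                 detect_p = 1, duration_min = 10,
                                 seed = NULL, site_id = "SIM") {
  stopifnot(inherits(reef, "sim_reef"), n >= 1)
  if (detect_p <= 0 || detect_p > 1) {
    rlang::abort("detect_p must be in (0, 1]",
                 class = "cotswatch_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  pos <- place_rectangles(n, reef$extent, distance_m, path_width_m)
  counts <- vapply(seq_len(n), function(i) {
    inside <- count_in_rectangle(reef$points, pos$cx[i], pos$cy[i],
                                 pos$theta[i], distance_m, path_width_m)
    stats::rbinom(1, inside, detect_p)
  }, integer(1))
  tibble::tibble(
    site_id = site_id,
    method = "timed_swim",
    count = counts,
    area_m2 = NA_real_,
    duration_min = duration_min,
    distance_m = distance_m
  )
}

#' Default observer models for report simulation
#'
#' Two observer classes with contrasting spatial behaviour: professionals
#' work in a few spatially-defined project zones (positions drawn around
#' zone centers), while non-professional volunteers report
#' opportunistically from anywhere on the reef, giving them a broader
#' spatial spread. Abundance entries are occasionally semi-quantitative
#' (qualitative terms) rather than exact counts. These behavioural
#' parameters are declared assumptions of the simulator, not field
#' estimates.
#'
#' @param extent Reef extent, meters, used to place the professional
#'   project zones.
#' @param n_professional,n_non_professional Reports per class.
#' @return A list of two observer model lists.
#' @export
default_observer_models <- function(extent, n_professional = 40,
                                    n_non_professional = 90) {
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  zones <- tibble::tibble(
    x = extent[1] + w * c(0.25, 0.7),
    y = extent[3] + h * c(0.5, 0.4),
    sd = min(w, h) * 0.06
  )
  list(
    list(class = "professional", n_reports = n_professional, zones = zones,
         encounter_radius = 50, qualitative_frac = 0.05,
         stakeholders = c(research = 0.5, government = 0.3, NGO = 0.2)),
    list(class = "non_professional", n_reports = n_non_professional,
         zones = NULL, encounter_radius = 50, qualitative_frac = 0.2,
         stakeholders = c(private_individual = 0.8, business = 0.2))
  )
}

count_to_term <- function(count) {
  if (count > 100) "large aggregations"
  else if (count >= 12) "dozens"
  else "several"
}

#' Simulate a stream of citizen observation reports
#'
#' Draws report positions per observer class (professionals around project
#' zones, volunteers uniformly over the reef), sets each reported count
#' from the local starfish density — the number of simulated starfish
#' within the observer's encounter radius, perturbed by multiplicative
#' lognormal perception noise — renders a configurable fraction of entries
#' as qualitative terms, and returns the stream as normalized, accepted
#' reports georeferenced about `anchor` (the reef's local-meter coordinates
#' are mapped to WGS84 with the inverse grid projection).
#'
#' @param reef A `sim_reef`.
#' @param observers Observer model list, as from
#'   [default_observer_models()].
#' @param anchor `c(lon, lat)` of the reef origin.
#' @param country Country code stamped on reports.
#' @param perception_sigma Lognormal sigma of the multiplicative counting
#'   noise (default 0.3).
#' @param dates Date range reports are drawn from.
#' @param seed Optional integer seed.
#' @return A normalized report tibble with `moderation = "accepted"`.
#' @export
simulate_reports <- function(reef, observers = default_observer_models(reef$extent),
                             anchor = c(166.4, -22.3), country = "NC",
                             perception_sigma = 0.3,
                             dates = as.Date(c("2014-01-01", "2018-12-31")),
                             seed = NULL) {
  stopifnot(inherits(reef, "sim_reef"))
  if (!is.null(seed)) set.seed(seed)
  spec <- grid_spec(anchor[1], anchor[2])
  ext <- reef$extent
  rows <- list()
  idx <- 0L
  for (model in observers) {
    n <- model$n_reports
    if (n == 0) next
    if (is.null(model$zones)) {
      px <- stats::runif(n, ext[1], ext[2])
      py <- stats::runif(n, ext[3], ext[4])
    } else {
      zi <- sample.int(nrow(model$zones), n, replace = TRUE)
      px <- pmin(pmax(stats::rnorm(n, model$zones$x[zi], model$zones$sd[zi]),
                      ext[1]), ext[2])
      py <- pmin(pmax(stats::rnorm(n, model$zones$y[zi], model$zones$sd[zi]),
                      ext[3]), ext[4])
    }
    rad <- model$encounter_radius
    local_n <- vapply(seq_len(n), function(i) {
      sum((reef$points$x - px[i])^2 + (reef$points$y - py[i])^2 <= rad^2)
    }, integer(1))
    noisy <- round(local_n * stats::rlnorm(n, 0, perception_sigma))
    qual <- stats::runif(n) < model$qualitative_frac & noisy >= 1
    raw <- ifelse(qual, vapply(noisy, count_to_term, character(1)),
                  as.character(noisy))
    ll <- unproject_from_grid(px, py, spec)
    stakeholder <- sample(names(model$stakeholders), n, replace = TRUE,
                          prob = model$stakeholders)
    trained <- model$class == "professional" &
      stakeholder %in% c("NGO", "business")
    day <- sample.int(as.integer(dates[2] - dates[1]) + 1L, n, replace = TRUE)
    for (i in seq_len(n)) {
      idx <- idx + 1L
      rows[[idx]] <- list(
        report_id = sprintf("SIM-%04d", idx),
        observer_name = sprintf("Observer %d", idx),
        observer_contact = sprintf("obs%d@example.org", idx),
        date = as.character(dates[1] + day[i] - 1L),
        lon = ll$lon[i], lat = ll$lat[i],
        country = country,
        context = sample(c("snorkeling", "scuba"), 1),
        abundance_raw = raw[i],
        stakeholder = stakeholder[i],
        trained = trained[i]
      )
    }
  }
  reports <- dplyr::bind_rows(lapply(rows, parse_report,
                                     today = as.Date("2019-01-01")))
  reports$moderation <- "accepted"  # simulated stream is pre-moderated
  reports
}
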