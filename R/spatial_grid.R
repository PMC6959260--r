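#' Define a 5 km x 5 km analysis grid
#'
#' Reports are summarized on a square grid of equal geographical quadrats
#' (default 5 km x 5 km). Positions are projected with a local
#' equirectangular projection about the anchor: `x = R cos(lat0) * dlon`,
#' `y = R * dlat` (radians, `R` = 6371 km). At the latitude spans involved
#' (tropical Pacific countries) the cell-area distortion of this projection
#' is small, and the anchor is recorded so grids are reproducible.
#'
#' Cells are half-open squares `[x, x + s) x [y, y + s)` in projected meters:
#' a point exactly on an edge belongs to the cell north-east of it.
#'
#' @param anchor_lon,anchor_lat WGS84 anchor (grid origin), decimal degrees.
#' @param cell_km Cell side, kilometers (default 5).
#' @param extent_km Optional maximum absolute projected offset from the
#'   anchor, kilometers; positions beyond it are flagged out-of-extent.
#' @return An object of class `cots_grid_spec`.
#' @export
#' @examples
#' grid_spec(166.4, -22.3)
grid_spec <- function(anchor_lon, anchor_lat, cell_km = 5, extent_km = Inf) {
  stopifnot(cell_km > 0, extent_km > 0,
            anchor_lon >= -180, anchor_lon <= 180,
            anchor_lat >= -90, anchor_lat <= 90)
  structure(
    list(anchor_lon = anchor_lon, anchor_lat = anchor_lat,
         cell_km = cell_km, extent_km = extent_km),
    class = "cots_grid_spec"
  )
}

#' @export
print.cots_grid_spec <- function(x, ...) {
  cat(sprintf("<cots_grid_spec> %.0f km cells anchored at (%.4f, %.4f)\n",
              x$cell_km, x$anchor_lon, x$anchor_lat))
  invisible(x)
}

EARTH_RADIUS_M <- 6371 * 1000

#' Project positions to local grid meters
#'
#' @param lon,lat Numeric vectors, decimal degrees.
#' @param spec A [grid_spec()].
#' @return A tibble with projected `x`, `y` in meters east/north of the
#'   anchor.
#' @export
project_to_grid <- function(lon, lat, spec) {
  d2r <- pi / 180
  tibble::tibble(
    x = EARTH_RADIUS_M * cos(spec$anchor_lat * d2r) * (lon - spec$anchor_lon) * d2r,
    y = EARTH_RADIUS_M * (lat - spec$anchor_lat) * d2r
  )
}

#' Invert the grid projection
#'
#' @inheritParams project_to_grid
#' @param x,y Meters east/north of the anchor.
#' @return A tibble with `lon`, `lat`.
#' @export
unproject_from_grid <- function(x, y, spec) {
  r2d <- 180 / pi
  tibble::tibble(
    lon = spec$anchor_lon + x / (EARTH_RADIUS_M * cos(spec$anchor_lat * pi / 180)) * r2d,
    lat = spec$anchor_lat + y / EARTH_RADIUS_M * r2d
  )
}

#' Assign positions to grid quadrats
#'
#' Deterministically maps positions to quadrat indices by flooring the
#' projected offsets: `ix = floor(x / s)`, `iy = floor(y / s)`. A tolerance
#' of one part in 1e9 of a cell absorbs floating-point jitter for points
#' sitting exactly on a cell edge (half-open convention: edges belong to the
#' north-east cell).
#'
#' @inheritParams project_to_grid
#' @return A tibble with `ix`, `iy` (integer indices), `quadrat_id`
#'   (`"ix:iy"`) and `in_extent` (logical; `FALSE` rows fall outside the
#'   spec's extent and are excluded from grid statistics).
#' @export
#' @examples
#' sp <- grid_spec(166.4, -22.3)
#' assign_quadrat(166.4, -22.3, sp)  # anchor cell (0, 0)
assign_quadrat <- function(lon, lat, spec) {
  pr <- project_to_grid(lon, lat, spec)
  s <- spec$cell_km * 1000
  eps <- 1e-9
  ix <- as.integer(floor(pr$x / s + eps))
  iy <- as.integer(floor(pr$y / s + eps))
  tibble::tibble(
    ix = ix, iy = iy,
    quadrat_id = paste(ix, iy, sep = ":"),
    in_extent = abs(pr$x) <= spec$extent_km * 1000 &
      abs(pr$y) <= spec$extent_km * 1000
  )
}

#' Summarize reports on the quadrat grid
#'
#' Produces one record per non-empty quadrat with report counts and
#' occupancy per observer class, total COTS reported, and per-class report
#' counts in the three detection bands used for observer-contribution
#' analysis (single = 1 COTS, aggregation = 2-100, potential outbreak
#' > 100). Only accepted, geolocated reports inside the grid extent are
#' counted; the number excluded as out-of-extent is attached as attribute
#' `n_out_of_extent`.
#'
#' @param reports Normalized report tibble (accepted reports).
#' @param spec A [grid_spec()].
#' @return A tibble of quadrat records; attribute `n_out_of_extent` counts
#'   retained-but-excluded reports.
#' @export
grid_summary <- function(reports, spec) {
  stopifnot(inherits(spec, "cots_grid_spec"))
  if (nrow(reports) == 0L) {
    rlang::warn("no reports; empty grid")
    out <- tibble::tibble(
      ix = integer(), iy = integer(), quadrat_id = character(),
      n_professional = integer(), n_non_professional = integer(),
      n_total = integer(), cots_total = integer(),
      occupied_professional = logical(), occupied_non_professional = logical(),
      occupied_combined = logical(),
      single_professional = integer(), aggregation_professional = integer(),
      outbreak_professional = integer(), single_non_professional = integer(),
      aggregation_non_professional = integer(),
      outbreak_non_professional = integer()
    )
    attr(out, "n_out_of_extent") <- 0L
    return(out)
  }
  q <- assign_quadrat(reports$lon, reports$lat, spec)
  dat <- dplyr::bind_cols(reports, q)
  n_out <- sum(!dat$in_extent)
  dat <- dplyr::filter(dat, .data$in_extent)
  cnt <- dplyr::coalesce(dat$abundance_count, 0L)
  dat$band <- dplyr::case_when(
    cnt == 1 ~ "single",
    cnt >= 2 & cnt <= 100 ~ "aggregation",
    cnt > 100 ~ "outbreak",
    TRUE ~ NA_character_
  )
  out <- dat |>
    dplyr::group_by(.data$ix, .data$iy, .data$quadrat_id) |>
    dplyr::summarise(
      n_professional = sum(.data$observer_class == "professional"),
      n_non_professional = sum(.data$observer_class == "non_professional"),
      n_total = dplyr::n(),
      cots_total = sum(dplyr::coalesce(.data$abundance_count, 0L)),
      single_professional = sum(.data$observer_class == "professional" &
                                  .data$band == "single", na.rm = TRUE),
      aggregation_professional = sum(.data$observer_class == "professional" &
                                       .data$band == "aggregation", na.rm = TRUE),
      outbreak_professional = sum(.data$observer_class == "professional" &
                                    .data$band == "outbreak", na.rm = TRUE),
      single_non_professional = sum(.data$observer_class == "non_professional" &
                                      .data$band == "single", na.rm = TRUE),
      aggregation_non_professional = sum(.data$observer_class == "non_professional" &
                                           .data$band == "aggregation", na.rm = TRUE),
      outbreak_non_professional = sum(.data$observer_class == "non_professional" &
                                        .data$band == "outbreak", na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      occupied_professional = .data$n_professional >= 1L,
      occupied_non_professional = .data$n_non_professional >= 1L,
      occupied_combined = TRUE,
      .after = "cots_total"
    )
  attr(out, "n_out_of_extent") <- n_out
  out
}

#' Observer-contribution analysis
#'
#' Quantifies how combining professional and non-professional observers
#' extends COTS detection: range size (number of occupied quadrats) per
#' class and combined; the percent range increase of non-professionals over
#' professionals, rounded to the nearest integer; mean observation density
#' (reports per occupied quadrat) per class; and per-class detection counts
#' in the single / aggregation (2-100) / potential outbreak (> 100) bands.
#'
#' @param grid A quadrat table from [grid_summary()].
#' @return A list with elements `range_professional`,
#'   `range_non_professional`, `range_combined`, `range_increase_pct`
#'   (`NA` when no professional quadrat is occupied),
#'   `mean_density_professional`, `mean_density_non_professional`,
#'   `reports_professional`, `reports_non_professional`,
#'   `reports_increase_pct`, and `detections` (a tibble of band counts per
#'   class).
#' @export
contribution_analysis <- function(grid) {
  r_prof <- sum(grid$occupied_professional)
  r_nonp <- sum(grid$occupied_non_professional)
  r_comb <- sum(grid$occupied_combined)
  n_prof <- sum(grid$n_professional)
  n_nonp <- sum(grid$n_non_professional)
  inc <- if (r_prof == 0) NA_real_ else round(100 * (r_nonp - r_prof) / r_prof)
  rep_inc <- if (n_prof == 0) NA_real_ else round(100 * (n_nonp - n_prof) / n_prof)
  detections <- tibble::tibble(
    observer_class = rep(c("professional", "non_professional"), each = 3),
    band = rep(c("single", "aggregation", "outbreak"), 2),
    n = c(sum(grid$single_professional), sum(grid$aggregation_professional),
          sum(grid$outbreak_professional), sum(grid$single_non_professional),
          sum(grid$aggregation_non_professional),
          sum(grid$outbreak_non_professional))
  )
  list(
    range_professional = r_prof,
    range_non_professional = r_nonp,
    range_combined = r_comb,
    range_increase_pct = inc,
    mean_density_professional = if (r_prof > 0) n_prof / r_prof else NA_real_,
    mean_density_non_professional = if (r_nonp > 0) n_nonp / r_nonp else NA_real_,
    reports_professional = n_prof,
    reports_non_professional = n_nonp,
    reports_increase_pct = rep_inc,
    detections = detections
  )
}

#' Mann-Whitney U test (rank-sum)
#'
#' Two-sided Mann-Whitney U test used to compare per-quadrat report counts
#' between observer classes. For pooled sample sizes of at most
#' `exact_limit` the null distribution of U is obtained by exhaustive
#' enumeration of all group assignments (valid under ties); for larger
#' samples a normal approximation with the usual tie correction of the
#' variance (and no continuity correction) is used.
#'
#' @param x,y Numeric samples.
#' @param exact_limit Pooled size at or below which the exact enumeration is
#'   used (default 20).
#' @return A list with `U` (for the `x` sample), `p_value`, `method`,
#'   `mean_x`, `mean_y`, `n` (pooled size).
#' @export
#' @examples
#' mann_whitney_u(c(1, 1, 2), c(5, 6, 7))
mann_whitney_u <- function(x, y, exact_limit = 20) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 == 0L || n2 == 0L) {
    rlang::abort("both samples must be non-empty",
                 class = "cotswatch_domain_error")
  }
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_stat <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
  U <- u_stat(seq_len(n1))
  mu <- n1 * n2 / 2
  if (n <= exact_limit) {
    splits <- utils::combn(n, n1)
    u_all <- apply(splits, 2, u_stat)
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation, tie-corrected"
  }
  list(U = U, p_value = min(p, 1), method = method,
       mean_x = mean(x), mean_y = mean(y), n = n)
}

#' Compare per-quadrat report counts between observer classes
#'
#' The samples are the numbers of reports per occupied quadrat for each
#' observer class (a quadrat occupied by both classes contributes one
#' observation to each sample, so n equals the total number of
#' occupied-quadrat observations across classes).
#'
#' @param grid A quadrat table from [grid_summary()].
#' @return A list as from [mann_whitney_u()], with `mean_professional` and
#'   `mean_non_professional` aliases.
#' @export
compare_reports_per_quadrat <- function(grid) {
  prof <- grid$n_professional[grid$occupied_professional]
  nonp <- grid$n_non_professional[grid$occupied_non_professional]
  if (length(prof) == 0L || length(nonp) == 0L) {
    rlang::abort("each observer class must occupy at least one quadrat",
                 class = "cotswatch_domain_error")
  }
  res <- mann_whitney_u(nonp, prof)
  res$mean_non_professional <- res$mean_x
  res$mean_professional <- res$mean_y
  res
}
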