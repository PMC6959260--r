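#' Read observation reports from CSV or GeoJSON
#'
#' Reads a report file, validates every record with [parse_report()], and
#' separates clean reports from rejected rows. CSV files are one report per
#' row (UTF-8, header row); GeoJSON files are FeatureCollections of Point
#' features whose properties hold the form fields (coordinates in
#' lon, lat order). The same fixture encoded both ways normalizes
#' identically.
#'
#' @param path Input file.
#' @param format `"csv"`, `"geojson"`, or `"auto"` (by file extension).
#' @param strict If `TRUE`, the first invalid row aborts ingestion instead
#'   of being logged and skipped.
#' @param mapping,observer_mapping Passed to [parse_report()].
#' @param today Passed to [parse_report()] (date upper bound).
#' @return A list with `reports` (normalized tibble, moderation pending)
#'   and `rejections` (tibble `row`, `report_id`, `reason`).
#' @export
read_reports <- function(path, format = c("auto", "csv", "geojson"),
                         strict = FALSE,
                         mapping = default_qualitative_mapping(),
                         observer_mapping = default_observer_mapping(),
                         today = Sys.Date()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
      "geojson"
    } else {
      "csv"
    }
  }
  raws <- if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  } else {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!identical(gj$type, "FeatureCollection")) {
      rlang::abort("GeoJSON input must be a FeatureCollection",
                   class = "cotswatch_validation_error")
    }
    lapply(gj$features, function(f) {
      props <- f$properties
      props$lon <- f$geometry$coordinates[[1]]
      props$lat <- f$geometry$coordinates[[2]]
      props
    })
  }

  reports <- list()
  rejections <- list()
  for (i in seq_along(raws)) {
    parsed <- tryCatch(
      parse_report(raws[[i]], mapping = mapping,
                   observer_mapping = observer_mapping, today = today),
      error = function(e) e
    )
    if (inherits(parsed, "error")) {
      if (strict) {
        rlang::abort(sprintf("row %d: %s", i, conditionMessage(parsed)),
                     class = "cotswatch_validation_error")
      }
      rejections[[length(rejections) + 1L]] <- tibble::tibble(
        row = i,
        report_id = as.character(raws[[i]]$report_id %||% NA_character_),
        reason = conditionMessage(parsed)
      )
    } else {
      reports[[length(reports) + 1L]] <- parsed
    }
  }
  rej <- if (length(rejections)) {
    dplyr::bind_rows(rejections)
  } else {
    tibble::tibble(row = integer(), report_id = character(),
                   reason = character())
  }
  list(reports = dplyr::bind_rows(reports), rejections = rej)
}

`%||%` <- rlang::`%||%`

#' Write normalized reports to CSV
#'
#' @param reports Normalized report tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  readr::write_csv(reports, path, na = "")
  invisible(path)
}

#' Read verification-survey records from CSV
#'
#' Expected columns: `site_id`, `method` (`belt_transect` or `timed_swim`),
#' `count`, and `area_m2` (transects) or `duration_min` / `distance_m`
#' (swims); `lon`, `lat`, `date` optional.
#'
#' @param path Input CSV.
#' @return A survey tibble.
#' @export
read_surveys <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("site_id", "method", "count")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    rlang::abort(sprintf("survey file missing columns: %s",
                         paste(missing, collapse = ", ")),
                 class = "cotswatch_validation_error")
  }
  bad <- setdiff(unique(df$method), c("belt_transect", "timed_swim"))
  if (length(bad)) {
    rlang::abort(sprintf("unknown survey method: %s",
                         paste(bad, collapse = ", ")),
                 class = "cotswatch_validation_error")
  }
  if (any(df$count < 0, na.rm = TRUE)) {
    rlang::abort("survey counts must be non-negative",
                 class = "cotswatch_validation_error")
  }
  df
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration holding input paths, the grid anchor, an
#' optional qualitative-term mapping, optional threshold overrides and a
#' seed. Threshold overrides are checked at load time: the density and swim
#' bands must still partition their domains (no overlap, no gap).
#'
#' @param path YAML file, or a pre-built list.
#' @return A validated config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    cell_km = 5,
    anchor = c(166.4, -22.3),
    seed = 1L,
    density_breaks = c(15, 100),   # non < 15 <= potential <= 100 < confirmed
    swim_breaks = c(2, 5),
    qualitative_mapping = NULL
  )
  cfg <- utils::modifyList(defaults, cfg)
  for (nm in c("density_breaks", "swim_breaks")) {
    br <- as.numeric(cfg[[nm]])
    if (length(br) != 2 || is.unsorted(br, strictly = TRUE) || br[1] <= 0) {
      rlang::abort(
        sprintf("%s must be two increasing positive values", nm),
        class = "cotswatch_validation_error"
      )
    }
    cfg[[nm]] <- br
  }
  if (!is.null(cfg$qualitative_mapping) &&
      !is.data.frame(cfg$qualitative_mapping)) {
    cfg$qualitative_mapping <- tibble::tibble(
      term = tolower(names(cfg$qualitative_mapping)),
      count = as.integer(unlist(cfg$qualitative_mapping))
    )
  }
  cfg
}

run_metadata <- function(cfg) {
  list(
    package = "cotswatch",
    version = as.character(utils::packageVersion("cotswatch")),
    config_hash = rlang::hash(cfg),
    anchor = cfg$anchor,
    cell_km = cfg$cell_km,
    seed = cfg$seed,
    density_breaks = cfg$density_breaks,
    swim_breaks = cfg$swim_breaks
  )
}

#' Run the full surveillance pipeline
#'
#' Executes ingestion (or simulation), abundance triage, the quadrat grid
#' and observer-contribution analysis, and verification-survey
#' classification, writing every artifact plus run metadata (package
#' version, config hash, grid anchor, thresholds, seed) to `out_dir`.
#' Outputs are deterministic given inputs and seed.
#'
#' @param config A config list or YAML path for [read_run_config()].
#'   Recognized entries: `reports` / `surveys` (input paths) or
#'   `simulate: true` (generate both with the synthetic-data module);
#'   `anchor`, `cell_km`, `seed`.
#' @param out_dir Output directory (created if needed). `NULL` skips
#'   writing and just returns the artifact list.
#' @return A list of artifacts: `reports`, `rejections`,
#'   `category_summary`, `chisq`, `grid`, `contribution`, `mann_whitney`,
#'   `site_status`, `site_summary`, `metadata`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "cotswatch_stage_error")
    })
  }

  if (isTRUE(cfg$simulate)) {
    sim <- stage("simulate", {
      extent <- cfg$extent %||% c(0, 8000, 0, 6000)
      reef <- simulate_population(
        extent,
        background_intensity = cfg$background_intensity %||% 2,
        clusters = cfg$clusters %||% tibble::tibble(
          x = extent[1] + diff(extent[1:2]) * c(0.3, 0.75),
          y = extent[3] + diff(extent[3:4]) * c(0.4, 0.6),
          radius = 25, mu = c(250, 400)
        ),
        seed = cfg$seed
      )
      reports <- simulate_reports(reef, anchor = cfg$anchor,
                                  seed = cfg$seed + 1L)
      surveys <- dplyr::bind_rows(
        simulate_belt_transects(reef, 20, seed = cfg$seed + 2L,
                                site_id = "SIM-A"),
        simulate_timed_swims(reef, 10, seed = cfg$seed + 3L,
                             site_id = "SIM-B")
      )
      list(reports = reports, surveys = surveys)
    })
    reports <- sim$reports
    rejections <- tibble::tibble(row = integer(), report_id = character(),
                                 reason = character())
    surveys <- sim$surveys
  } else {
    ing <- stage("ingest", read_reports(
      cfg$reports,
      mapping = cfg$qualitative_mapping %||% default_qualitative_mapping()
    ))
    reports <- ing$reports
    reports$moderation <- "accepted"  # batch mode: file is the accepted set
    rejections <- ing$rejections
    surveys <- if (!is.null(cfg$surveys)) {
      stage("surveys", read_surveys(cfg$surveys))
    } else {
      NULL
    }
  }

  acc <- accepted_reports(reports)
  category_summary <- stage("triage",
                            summarize_categories(acc, by = "observer_class"))
  chisq <- stage("triage", tryCatch(compare_observer_distributions(acc),
                                    cotswatch_domain_error = function(e) NULL))
  spec <- grid_spec(cfg$anchor[1], cfg$anchor[2], cell_km = cfg$cell_km)
  grid <- stage("grid", grid_summary(acc, spec))
  contribution <- stage("grid", contribution_analysis(grid))
  mw <- stage("grid", tryCatch(compare_reports_per_quadrat(grid),
                               cotswatch_domain_error = function(e) NULL))
  site_status <- if (!is.null(surveys)) {
    stage("classify-surveys",
          classify_sites(surveys, density_breaks = cfg$density_breaks,
                         swim_breaks = cfg$swim_breaks))
  } else {
    NULL
  }
  site_summary <- if (!is.null(site_status)) summarize_sites(site_status)

  artifacts <- list(
    reports = reports, rejections = rejections,
    category_summary = category_summary, chisq = chisq,
    grid = grid, contribution = contribution, mann_whitney = mw,
    site_status = site_status, site_summary = site_summary,
    metadata = run_metadata(cfg)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_reports(reports, file.path(out_dir, "reports.csv"))
    readr::write_csv(rejections, file.path(out_dir, "rejections.csv"), na = "")
    readr::write_csv(category_summary,
                     file.path(out_dir, "category_summary.csv"), na = "")
    readr::write_csv(grid, file.path(out_dir, "grid.csv"), na = "")
    contrib_out <- contribution
    contrib_out$detections <- NULL
    jsonlite::write_json(
      c(contrib_out, list(metadata = artifacts$metadata)),
      file.path(out_dir, "contribution.json"),
      auto_unbox = TRUE, digits = NA, na = "null"
    )
    if (!is.null(chisq)) {
      jsonlite::write_json(
        list(statistic = chisq$statistic, df = chisq$df,
             p_value = chisq$p_value, n = chisq$n,
             metadata = artifacts$metadata),
        file.path(out_dir, "chisq.json"), auto_unbox = TRUE, digits = NA
      )
    }
    if (!is.null(site_status)) {
      readr::write_csv(site_status, file.path(out_dir, "sites.csv"), na = "")
      jsonlite::write_json(
        c(site_summary[names(site_summary) != "proportions"],
          list(proportions = site_summary$proportions,
               metadata = artifacts$metadata)),
        file.path(out_dir, "site_summary.json"),
        auto_unbox = TRUE, digits = NA, na = "null"
      )
    }
    jsonlite::write_json(artifacts$metadata,
                         file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  artifacts
}
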