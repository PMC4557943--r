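# File formats and the end-to-end pipeline. All CSVs are comma-separated
# UTF-8 with a mandatory header row and '.' decimal separator; times are
# seconds from drive start, angles degrees, distances metres (feet only at
# the reporting boundary). Every pipeline output directory carries a run
# manifest (config snapshot, seeds, input digests, package version).

DRIVE_LOG_COLS <- c("t", "car_along_track_m", "car_speed_mps", "car_heading_deg",
                    "ped_id", "ped_x_m", "ped_y_m", "ped_visible", "horn")
GAZE_LOG_COLS <- c("t", "gaze_azimuth_deg", "gaze_elevation_deg", "valid")

#' Read and write pipeline CSV files
#'
#' Readers validate the column contract of each log type and fail before any
#' computation when a required column is missing. Writers emit plain
#' comma-separated UTF-8 with a header row; written tables round-trip
#' exactly.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_drive_log <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_cols(df, DRIVE_LOG_COLS, "drive log")
  df$ped_id <- as.character(df$ped_id)
  df
}

#' @rdname read_drive_log
#' @export
read_gaze_log <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_cols(df, GAZE_LOG_COLS, "gaze log")
  df$valid <- as.logical(df$valid)
  df
}

#' @rdname read_drive_log
#' @param x Tibble to write.
#' @export
write_pipeline_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_drive_log
#' @export
read_event_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_cols(df, c("event_id", "participant_id", "drive_type", "eccentricity",
                   "detected", "reaction_time", "timely", "occlusion_time",
                   "gaze_usable"), "event table")
  class(df) <- c("event_table", class(df))
  df
}

check_cols <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing_cols, collapse = ", ")))
  }
  invisible(df)
}

#' Read a study configuration file
#'
#' YAML key-value configuration for the pipeline. Recognised keys:
#' `seed` (integer, required), `simulate` (logical), `n_appearances`,
#' `drive_types`, `eccentricities`, `participants` (list of
#' `id`/`field` entries; `field` is a visual-field JSON path relative to the
#' config file, or empty for a normal-vision control), plus any
#' [scenario_config()], [gaze_behavior_params()] or
#' [response_model_params()] field under `scenario:`, `gaze:`, `response:`.
#'
#' @param path YAML file path.
#' @return A validated config list.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "simulate", "n_appearances", "drive_types", "eccentricities",
             "participants", "scenario", "gaze", "response")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$seed)) abort("config must set a seed")
  if (is.null(cfg$participants) || length(cfg$participants) == 0) {
    abort("config must list at least one participant")
  }
  for (p in cfg$participants) {
    if (is.null(p$id)) abort("every participant entry needs an id")
  }
  cfg$dir <- dirname(normalizePath(path))
  cfg
}

#' Run the full pipeline from a configuration file
#'
#' Simulate (when `simulate: true`) then score every participant drive and
#' compute the statistical report. Writes, under `out_dir`: the drive and
#' gaze CSVs and visual-field JSONs (simulated runs), `events.csv`,
#' `report.json` and `manifest.json`. Idempotent given the seeds: re-running
#' the same config reproduces identical tables.
#'
#' @param config Path to a YAML config, or a list as returned by
#'   [read_study_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed overriding the config's.
#' @return Invisibly, a list with `events`, `report`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) read_study_config(config) else config
  seed <- as.integer(seed %||% cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fields <- lapply(cfg$participants, function(p) {
    if (is.null(p$field) || identical(p$field, "")) {
      visual_field(list(), participant_id = p$id)
    } else {
      path <- p$field
      if (!file.exists(path) && !is.null(cfg$dir)) path <- file.path(cfg$dir, p$field)
      if (!file.exists(path)) abort(sprintf("visual-field file not found: %s", p$field))
      f <- read_visual_field(path)
      f$participant_id <- p$id
      f
    }
  })
  names(fields) <- vapply(cfg$participants, `[[`, character(1), "id")

  scen_args <- cfg$scenario %||% list()
  if (!is.null(cfg$n_appearances)) scen_args$n_appearances <- cfg$n_appearances
  if (!is.null(cfg$eccentricities)) scen_args$eccentricities <- cfg$eccentricities
  base_cfg <- do.call(scenario_config, c(list(drive_type = "city"), scen_args))
  gaze_p <- do.call(gaze_behavior_params, cfg$gaze %||% list())
  resp_p <- do.call(response_model_params, cfg$response %||% list())
  drive_types <- cfg$drive_types %||% c("city", "highway")

  n_events <- 0L
  if (isTRUE(cfg$simulate)) {
    study <- generate_study(fields, base_cfg, gaze_p, resp_p,
                            drive_types = drive_types, seed = seed)
    purrr::pwalk(study$logs, function(participant_id, drive_type, drive, gaze, cfg) {
      write_pipeline_csv(drive, file.path(out_dir, sprintf("drive_%s_%s.csv", participant_id, drive_type)))
      write_pipeline_csv(gaze, file.path(out_dir, sprintf("gaze_%s_%s.csv", participant_id, drive_type)))
    })
    for (f in fields) write_visual_field(f, file.path(out_dir, sprintf("field_%s.json", f$participant_id)))
    write_pipeline_csv(study$ground_truth, file.path(out_dir, "ground_truth.csv"))
    events <- score_study(study)
    message(sprintf("simulate: %d drives, %d appearances", nrow(study$logs), nrow(study$ground_truth)))
  } else {
    abort("non-simulated runs go through score_drive(); set simulate: true in the config")
  }
  write_pipeline_csv(events, file.path(out_dir, "events.csv"))
  message(sprintf("score: %d events, %d gaze-usable", nrow(events), sum(events$gaze_usable)))

  report <- stats_report(events, seed = seed)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  message("stats: report written")

  manifest <- run_manifest(cfg, seed, out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(events = events, report = report, manifest = manifest))
}

#' Score one logged drive into an event table
#'
#' The scoring entry point for externally recorded data: drive log + gaze
#' log + visual-field JSON in, event table out.
#'
#' @param drive_path,gaze_path,field_path Input file paths.
#' @param cfg A [scenario_config()] describing the drive.
#' @param out Optional path for the events CSV.
#' @return The `event_table` (invisibly when `out` is given).
#' @export
score_drive <- function(drive_path, gaze_path, field_path, cfg, out = NULL) {
  drive <- read_drive_log(drive_path)
  gaze <- read_gaze_log(gaze_path)
  field <- read_visual_field(field_path)
  events <- build_event_table(drive, gaze, field, cfg)
  if (!is.null(out)) {
    write_pipeline_csv(events, out)
    return(invisible(events))
  }
  events
}

#' Statistical report for an event table
#'
#' All summaries in one versioned structure: detection and untimely
#' proportions by stratum, the occlusion-by-timeliness contingency test,
#' median reaction times with bootstrap intervals, the occlusion-time /
#' reaction-time correlation and the log-RT regression (computed over
#' gaze-usable detected scotoma-group events when a `group` column is
#' present).
#'
#' @param events An `event_table`.
#' @param seed Seed for the bootstrap intervals.
#' @return A list (report schema `scotowatch-report/1`).
#' @export
stats_report <- function(events, seed = 1L) {
  has_group <- "group" %in% names(events)
  by <- if (has_group) "group" else "participant_id"
  unt <- untimely_summary(events)
  med <- median_summary(events, by = by, seed = seed)
  avail <- gaze_availability_check(events)

  reg_events <- events |>
    dplyr::filter(.data$detected, .data$gaze_usable, !is.na(.data$reaction_time))
  if (has_group) reg_events <- dplyr::filter(reg_events, .data$group == "CFL")
  corr <- NULL; fit_sum <- NULL
  if (nrow(reg_events) >= 10 && sd(reg_events$occlusion_time) > 0) {
    corr <- pearson_r(reg_events$occlusion_time, reg_events$reaction_time)
    fit <- ols_logrt(reg_events)
    fit_sum <- list(
      occ_slope = fit$occ_slope,
      occ_slope_ci = fit$occ_slope_ci,
      glance = as.list(glance(fit))
    )
  }
  list(
    schema = "scotowatch-report/1",
    n_events = nrow(events),
    n_detected = sum(events$detected),
    n_gaze_usable = sum(events$gaze_usable),
    untimely = list(
      by_stratum = unt$by_stratum,
      contingency = unt$contingency,
      test = unt$test
    ),
    medians = med,
    gaze_availability = avail,
    occlusion_rt = list(correlation = corr, regression = fit_sum)
  )
}

run_manifest <- function(cfg, seed, out_dir) {
  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in% "manifest.json"]
  digests <- tools::md5sum(outputs)
  cfg$dir <- NULL
  list(
    package = "scotowatch",
    version = as.character(utils::packageVersion("scotowatch")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = cfg,
    file_digests = as.list(setNames(unname(digests), basename(outputs)))
  )
}

#' Reaction time against occlusion time
#'
#' Diagnostic scatter of reaction time (log scale) against scotoma occlusion
#' time over gaze-usable detected events, the relationship at the centre of
#' the analysis.
#'
#' @param events An `event_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_occlusion_rt <- function(events, ...) {
  df <- dplyr::filter(events, .data$detected, .data$gaze_usable,
                      !is.na(.data$reaction_time))
  aes_pt <- if ("group" %in% names(df)) {
    ggplot2::aes(x = .data$occlusion_time, y = .data$reaction_time, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$occlusion_time, y = .data$reaction_time)
  }
  ggplot2::ggplot(df, aes_pt) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Occlusion time (s)", y = "Reaction time (s, log scale)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.event_table <- function(object, ...) plot_occlusion_rt(object, ...)
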