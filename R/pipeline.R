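#' Pipeline configuration
#'
#' Collects every tunable of the full reconstruction pipeline with the
#' field's customary defaults: 1-s feature windows, scale-free msDTW
#' threshold, 0.6 deg/s walking zero-velocity rule, mid-stance +/- 5 sample
#' windows for jogging/running, sigma_a = sigma_w = 0.01, and either a
#' fixed sigma_v or the 0.001..0.05 m/s sweep on closed loops.
#'
#' @param activity_override force `"walk"`, `"jog"`, or `"run"` instead of
#'   classifying (`NULL` = classify).
#' @param templates named list of [build_template()] templates; `NULL` uses
#'   [default_templates()].
#' @param msdtw_threshold segmentation threshold (scale-free).
#' @param tolerance event-scoring tolerance fraction.
#' @param sigma_a,sigma_w,sigma_v filter noise parameters (see
#'   [filter_params()]).
#' @param sigma_v_mode `"fixed"` or `"sweep"` (sweep needs
#'   `known_endpoint`).
#' @param known_endpoint closed-loop endpoint (m) for RPE and the sigma_v
#'   sweep; `NULL` disables both.
#' @param zones optional list of corridor polygons for
#'   [strides_out_of_trajectory()].
#' @param static_interval calibration interval `c(start, end)`; `NULL`
#'   auto-detects.
#' @param zv_threshold_dps,zv_half_window zero-velocity detection tunables.
#' @param seed integer seed recorded in the manifest and used for any
#'   stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(activity_override = NULL, templates = NULL,
                            msdtw_threshold = default_msdtw_threshold,
                            tolerance = 0.15,
                            sigma_a = 0.01, sigma_w = 0.01, sigma_v = 0.01,
                            sigma_v_mode = c("fixed", "sweep"),
                            known_endpoint = NULL, zones = NULL,
                            static_interval = NULL,
                            zv_threshold_dps = 0.6, zv_half_window = 5L,
                            seed = 1L) {
  sigma_v_mode <- match.arg(sigma_v_mode)
  if (!is.null(activity_override) &&
      !activity_override %in% c("walk", "jog", "run")) {
    abort("activity_override must be walk/jog/run", class = "ipdr_value_error")
  }
  stopifnot(msdtw_threshold >= 0, tolerance > 0, tolerance < 1,
            sigma_a > 0, sigma_w > 0, sigma_v > 0, zv_threshold_dps > 0)
  structure(list(activity_override = activity_override,
                 templates = templates,
                 msdtw_threshold = msdtw_threshold, tolerance = tolerance,
                 sigma_a = sigma_a, sigma_w = sigma_w, sigma_v = sigma_v,
                 sigma_v_mode = sigma_v_mode,
                 known_endpoint = known_endpoint, zones = zones,
                 static_interval = static_interval,
                 zv_threshold_dps = zv_threshold_dps,
                 zv_half_window = zv_half_window,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML/JSON
#'
#' Scalar fields map directly onto [pipeline_config()] arguments;
#' `templates` may be a named list of template JSON paths and `zones` a
#' list of polygons (`x`/`y` arrays).
#'
#' @param path YAML or JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$templates) && is.character(unlist(raw$templates))) {
    raw$templates <- lapply(raw$templates, read_template)
  }
  if (!is.null(raw$zones)) {
    raw$zones <- lapply(raw$zones, as.data.frame)
  }
  do.call(pipeline_config, raw)
}

#' Run the full trajectory-reconstruction pipeline
#'
#' Calibrate (gyro bias from a static interval) -> classify the activity
#' (majority vote over windowed features, unless overridden) -> select the
#' activity's stride template -> segment strides by subsequence DTW ->
#' restitch toe-off to toe-off and detect events -> detect zero velocity
#' (gyroscope-magnitude rule for walking, mid-stance windows for
#' jogging/running) -> strapdown + ZUPT error-state Kalman filter ->
#' stride-level trajectory and metrics.
#'
#' @param input an [imu_sequence()] or a file path readable by
#'   [read_imu()].
#' @param config a [pipeline_config()].
#' @param model activity model; `NULL` uses [default_activity_model()]
#'   (only consulted when `activity_override` is unset).
#' @param out_dir when non-`NULL`, artifacts are written there:
#'   `trajectory.csv`, `events.csv`, `states.csv`, `report.json`,
#'   `manifest.json`.
#' @return A list of class `ipdr_run`: `activity`, `calibration`,
#'   `segments`, `events`, `zv`, `nav`, `trajectory`, `report` (tibble),
#'   `sigma_v`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), model = NULL,
                         out_dir = NULL) {
  seq <- if (inherits(input, "imu_sequence")) input else read_imu(input)
  rate <- imu_rate(seq)

  cal <- estimate_gyro_bias(seq, static_interval = config$static_interval)
  seq <- apply_calibration(seq, cal)

  activity <- config$activity_override
  if (is.null(activity)) {
    model <- model %||% default_activity_model()
    activity <- classify_bout(model, extract_features(seq))
  }

  templates <- config$templates %||% default_templates()
  template <- templates[[activity]]
  if (is.null(template)) {
    abort(sprintf("no template for activity '%s'", activity),
          class = "ipdr_value_error")
  }

  segments <- subsequence_dtw(seq$gz, template, config$msdtw_threshold)
  strides <- restitch_to_to(segments, seq$gz, rate)
  events <- detect_events(strides, seq$gz)
  if (nrow(events) == 0L) {
    abort("no strides detected", class = "ipdr_pipeline_error")
  }

  zv_mode <- if (activity == "walk") "gyro_threshold" else "ms_window"
  zv <- detect_zero_velocity(seq, activity, ms_indices = events$ms,
                             strides = events,
                             threshold_dps = config$zv_threshold_dps,
                             half_window = config$zv_half_window)

  params <- filter_params(config$sigma_a, config$sigma_w, config$sigma_v,
                          gravity_mag = cal$gravity_mag)
  sigma_v <- config$sigma_v
  if (config$sigma_v_mode == "sweep") {
    if (is.null(config$known_endpoint)) {
      abort("sigma_v sweep needs known_endpoint", class = "ipdr_value_error")
    }
    sw <- sweep_sigma_v(seq, zv, config$known_endpoint, params = params)
    sigma_v <- sw$sigma_v
    params$sigma_v <- sigma_v
  }
  nav <- zupt_kalman(seq, zv, params = params)
  traj <- stride_trajectory(nav, events$ms)

  report <- tibble::tibble(activity = activity,
                           n_segments = nrow(segments),
                           n_strides = nrow(events),
                           total_distance_m = attr(traj, "total_distance"),
                           mean_stride_length_m = mean(traj$sl),
                           sigma_v = sigma_v)
  if (!is.null(config$known_endpoint)) {
    rpe <- return_position_error(traj, config$known_endpoint)
    report$rpe_m <- rpe$rpe_m
    report$rpe_pct <- rpe$rpe_pct
  }
  if (!is.null(config$zones)) {
    sot <- strides_out_of_trajectory(traj, config$zones)
    report$sot_count <- sot$sot_count
    report$sot_pct <- sot$sot_pct
  }

  run <- structure(list(activity = activity, calibration = cal,
                        segments = segments, events = events, zv = zv,
                        nav = nav, trajectory = traj, report = report,
                        sigma_v = sigma_v, config = config),
                   class = "ipdr_run")
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

#' @export
print.ipdr_run <- function(x, ...) {
  cat(sprintf("<ipdr_run: %s, %d strides, %.1f m>\n", x$activity,
              nrow(x$events), attr(x$trajectory, "total_distance")))
  print(x$report)
  invisible(x)
}

#' @export
glance.ipdr_run <- function(x, ...) x$report

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(as.data.frame(run$trajectory),
                   file.path(out_dir, "trajectory.csv"))
  readr::write_csv(as.data.frame(run$events), file.path(out_dir, "events.csv"))
  nav <- as.data.frame(run$nav)
  readr::write_csv(nav, file.path(out_dir, "states.csv"))
  jsonlite::write_json(as.list(run$report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- run$config
  cfg$templates <- NULL
  manifest <- list(
    package = "ipdr",
    version = as.character(utils::packageVersion("ipdr")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
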