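#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_all()]. Every
#' default matches the analysis conventions of the displacement design the
#' package models: 58-h Argos duty cycle, onset = 2 consecutive >= 50 km
#' movements within +/-90 degrees of south, milestones at 500 and 1,000 km,
#' null steps > 100 km, 1..15 steps x 1,000 simulated tracks, westward
#' compensation, outlier levels 0.05 and 0.001.
#'
#' @param input Path to a Movebank-dialect CSV, or `NULL` to synthesise a
#'   cohort with [gen_cohort()].
#' @param metadata Optional per-bird metadata table for [read_tracks()].
#' @param column_map Column mapping for [read_tracks()].
#' @param duty_cycle_hours Duty-cycle length in hours.
#' @param onset Named list of [detect_migration_onset()] arguments.
#' @param thresholds_km Strictly ascending milestone distances.
#' @param min_step_km Null-model step threshold (strict, km).
#' @param simulation Named list: `k_min`, `k_max`, `tracks_per_k`.
#' @param classification Named list: `sign`, `lat_band_deg`.
#' @param seed Integer seed used for synthesis and simulation.
#' @param output_dir Directory for the report bundle, or `NULL` to skip
#'   writing files.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, metadata = NULL,
                            column_map = movebank_columns(),
                            duty_cycle_hours = 58,
                            onset = list(sector_center_deg = 180,
                                         sector_halfwidth_deg = 90,
                                         k_consecutive = 2, min_step_km = 50),
                            thresholds_km = c(500, 1000),
                            min_step_km = 100,
                            simulation = list(k_min = 1, k_max = 15,
                                              tracks_per_k = 1000),
                            classification = list(sign = "westward",
                                                  lat_band_deg = NULL),
                            seed = 1L, output_dir = NULL) {
  if (is.unsorted(thresholds_km, strictly = TRUE)) {
    abort("`thresholds_km` must be strictly ascending.")
  }
  stopifnot(duty_cycle_hours > 0, min_step_km > 0,
            simulation$k_min >= 1, simulation$k_max >= simulation$k_min,
            simulation$tracks_per_k >= 1)
  if (!classification$sign %in% c("westward", "eastward")) {
    abort("`classification$sign` must be \"westward\" or \"eastward\".")
  }
  structure(list(input = input, metadata = metadata, column_map = column_map,
                 duty_cycle_hours = duty_cycle_hours, onset = onset,
                 thresholds_km = thresholds_km, min_step_km = min_step_km,
                 simulation = simulation, classification = classification,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of
#' [pipeline_config()]; absent keys take the defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  defaults <- formals(pipeline_config)
  for (k in c("onset", "simulation", "classification")) {
    if (k %in% names(raw)) raw[[k]] <- utils::modifyList(eval(defaults[[k]]), raw[[k]])
  }
  if ("thresholds_km" %in% names(raw)) raw$thresholds_km <- unlist(raw$thresholds_km)
  do.call(pipeline_config, raw)
}

#' Run the whole displacement analysis
#'
#' Executes the full stage chain on a configuration: load or synthesise
#' tracks, filter and reduce them, compute per-bird metrics, run the group
#' comparisons (endpoint bearings, longitudinal displacement, timing, the
#' two-factor screen), build the clock-and-compass null cloud from the
#' young birds' steps and classify displaced birds as compensating
#' outliers. When `output_dir` is set the bundle (metrics CSV, comparison
#' JSON, cloud CSV, calls CSV, log) is written with a config hash stamped
#' in every file name's sidecar log.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `metrics`, `comparisons`, `steps`,
#'   `cloud`, `calls`, `config`, `config_hash` and (if synthesised)
#'   `truth`.
#' @export
run_all <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- rlang::hash(config[setdiff(names(config), "output_dir")])
  log_lines <- c(sprintf("config_hash: %s", hash),
                 sprintf("seed: %d", config$seed))
  truth <- NULL
  if (is.null(config$input)) {
    cohort <- gen_cohort(seed = config$seed)
    tracks <- cohort$tracks
    truth <- cohort$truth
    log_lines <- c(log_lines, sprintf("stage synth: %d tracks generated", length(tracks)))
  } else {
    tracks <- read_tracks(config$input, metadata = config$metadata,
                          column_map = config$column_map)
    log_lines <- c(log_lines, sprintf("stage read: %d tracks from %s",
                                      length(tracks), config$input))
  }
  if (length(tracks) == 0L) abort("Stage read: no tracks available.")

  n_raw <- sum(vapply(tracks, n_positions, integer(1)))
  reduced <- lapply(tracks, function(trk) {
    select_duty_cycle_positions(filter_quality(trk), config$duty_cycle_hours)
  })
  n_kept <- sum(vapply(reduced, n_positions, integer(1)))
  log_lines <- c(log_lines, sprintf("stage filter+duty: %d fixes in, %d retained",
                                    n_raw, n_kept))

  metrics <- track_metrics(reduced, thresholds_km = config$thresholds_km,
                           duty_cycle_hours = NULL, onset = config$onset)
  log_lines <- c(log_lines, sprintf("stage metrics: %d birds, %d started migration",
                                    nrow(metrics), sum(metrics$started_migration)))

  comparisons <- list(
    endpoint_bearings = tryCatch(compare_endpoint_bearings(metrics, age = "juvenile"),
                                 warning = function(w) NULL),
    lon_displacement = tryCatch(compare_lon_displacement(metrics, age = "juvenile"),
                                warning = function(w) NULL),
    timing_500 = tryCatch(compare_timing(metrics, "doy_500", age = "juvenile"),
                          warning = function(w) NULL),
    timing_1000 = tryCatch(compare_timing(metrics, "doy_1000", age = "juvenile"),
                           warning = function(w) NULL),
    timing_endpoint = tryCatch(compare_timing(metrics, "endpoint_doy", age = "juvenile"),
                               warning = function(w) NULL),
    two_way = tryCatch(two_way_screen(metrics), error = function(e) NULL)
  )
  log_lines <- c(log_lines, sprintf("stage compare: %d comparisons computed",
                                    sum(!vapply(comparisons, is.null, logical(1)))))

  young <- reduced[vapply(reduced, function(t) identical(t$age, "juvenile"), logical(1))]
  if (length(young) == 0L) young <- reduced
  steps <- extract_steps(young, min_step_km = config$min_step_km)
  cloud <- simulate_endpoints(steps,
                              k_min = config$simulation$k_min,
                              k_max = config$simulation$k_max,
                              tracks_per_k = config$simulation$tracks_per_k,
                              seed = config$seed)
  log_lines <- c(log_lines, sprintf("stage nullsim: %d steps -> %d endpoints",
                                    nrow(steps), nrow(cloud)))

  displaced <- metrics[metrics$group %in% "displaced" & !is.na(metrics$lon_displacement), ]
  calls <- NULL
  if (nrow(displaced) > 0L) {
    observed <- tibble::tibble(
      bird_id = displaced$bird_id,
      dlon = displaced$lon_displacement,
      dlat = displaced$endpoint_lat -
        vapply(displaced$bird_id, function(id) reduced[[id]]$release_site$lat, numeric(1))
    )
    calls <- classify_compensation(cloud, observed,
                                   compensation_sign = config$classification$sign,
                                   lat_band_deg = config$classification$lat_band_deg)
    log_lines <- c(log_lines, sprintf("stage classify: %d displaced birds, %d compensating",
                                      nrow(calls), sum(calls$compensating)))
  } else {
    log_lines <- c(log_lines, "stage classify: skipped (no displaced birds with metrics)")
  }

  report <- list(metrics = metrics, comparisons = comparisons, steps = steps,
                 cloud = cloud, calls = calls, truth = truth,
                 config = config, config_hash = hash)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(metrics, file.path(config$output_dir, "metrics.csv"), progress = FALSE)
    readr::write_csv(tibble::as_tibble(cloud), file.path(config$output_dir, "cloud.csv"),
                     progress = FALSE)
    if (!is.null(calls)) {
      readr::write_csv(calls, file.path(config$output_dir, "compensation_calls.csv"),
                       progress = FALSE)
    }
    jsonlite::write_json(serialise_comparisons(comparisons, hash),
                         file.path(config$output_dir, "comparisons.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(log_lines, file.path(config$output_dir, "log.txt"))
  }
  invisible(report)
}

serialise_comparisons <- function(comparisons, hash) {
  flat <- lapply(comparisons, function(cmp) {
    if (is.null(cmp)) return(NULL)
    if (is.data.frame(cmp)) return(as.list(cmp))
    res <- cmp$result
    list(metric = cmp$metric, test = cmp$test,
         statistic = res$t %||% res$F %||% NA,
         df = res$df, p = res$p,
         groups = cmp$group_summaries)
  })
  c(list(config_hash = hash), flat)
}
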