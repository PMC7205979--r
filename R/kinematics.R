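#' Detect migration onset
#'
#' Displacement-released birds often wander near the release site before
#' departing. Onset is declared at the first retained position from which
#' `k_consecutive` successive displacements (consecutive-fix movements) are
#' all at least `min_step_km` long and all head within
#' `sector_center_deg +/- sector_halfwidth_deg`. The returned index is the
#' departure fix, i.e. the position the first qualifying movement leaves
#' from.
#'
#' @param trk A [track()] with retained (filtered) positions.
#' @param sector_center_deg Centre of the accepted bearing sector (default
#'   180, due south).
#' @param sector_halfwidth_deg Half-width of the sector in degrees
#'   (default 90).
#' @param k_consecutive Number of consecutive qualifying movements required
#'   (default 2).
#' @param min_step_km Minimum movement length in km (default 50).
#' @return Integer position index, or `NA_integer_` if no qualifying run
#'   exists.
#' @export
detect_migration_onset <- function(trk, sector_center_deg = 180,
                                   sector_halfwidth_deg = 90,
                                   k_consecutive = 2, min_step_km = 50) {
  stopifnot(inherits(trk, "track"), k_consecutive >= 1)
  pos <- trk$positions
  n <- nrow(pos)
  if (n < k_consecutive + 1L) return(NA_integer_)
  from <- pos[-n, c("lat", "lon")]
  to <- pos[-1, c("lat", "lon")]
  len <- gc_distance(from, to)
  brg <- rep(NA_real_, n - 1L)
  moved <- len > 1e-9
  if (any(moved)) {
    brg[moved] <- wrap_bearing(geosphere::bearing(as_lonlat(from), as_lonlat(to),
                                                  a = EARTH_RADIUS_KM * 1000, f = 0)[moved])
  }
  dev <- abs(wrap_lon(brg - sector_center_deg))
  ok <- len >= min_step_km & !is.na(dev) & dev <= sector_halfwidth_deg
  run <- 0L
  for (i in seq_along(ok)) {
    run <- if (ok[i]) run + 1L else 0L
    if (run == k_consecutive) return(i - k_consecutive + 1L)
  }
  NA_integer_
}

#' Has a bird started migration?
#'
#' Inclusion rule for the analysis cohort: a bird is considered to have
#' started migration once it has been tracked more than 500 km from the
#' release site or has crossed south of 50 degrees N.
#'
#' @param trk A [track()].
#' @param dist_km Distance criterion in km (default 500).
#' @param lat_deg Latitude criterion in degrees N (default 50).
#' @return Logical.
#' @export
started_migration <- function(trk, dist_km = 500, lat_deg = 50) {
  stopifnot(inherits(trk, "track"))
  pos <- trk$positions
  if (nrow(pos) == 0L) return(FALSE)
  d <- gc_distance(trk$release_site, pos[c("lat", "lon")])
  max(d) > dist_km || min(pos$lat) < lat_deg
}

#' First crossing of a distance threshold
#'
#' Finds the first retained position (at or after the onset index) whose
#' great-circle distance from the release site exceeds `threshold_km`; with
#' duty-cycled sampling this is deliberately the first observed fix beyond
#' the threshold, not an interpolated crossing point. The crossing bearing
#' is the initial great-circle bearing from the release site to that fix.
#'
#' @param trk A [track()].
#' @param threshold_km Distance threshold in km (e.g. 500 or 1000).
#' @param onset_index Index of the onset position; earlier fixes are
#'   ignored. Default 1 (whole track).
#' @return A list of class `crossing_event` with `threshold_km`, `position`
#'   ([geo_point()]), `bearing_deg`, `day_of_year`, `timestamp` and `index`
#'   (into the track's positions), or `NULL` if the threshold is never
#'   exceeded.
#' @export
crossing_event <- function(trk, threshold_km, onset_index = 1L) {
  stopifnot(inherits(trk, "track"), threshold_km > 0)
  pos <- trk$positions
  if (is.na(onset_index)) return(NULL)
  if (nrow(pos) < onset_index) return(NULL)
  idx <- seq(onset_index, nrow(pos))
  d <- gc_distance(trk$release_site, pos[idx, c("lat", "lon")])
  hit <- which(d > threshold_km)
  if (length(hit) == 0L) return(NULL)
  i <- idx[hit[1]]
  p <- geo_point(pos$lat[i], pos$lon[i])
  structure(list(
    threshold_km = threshold_km,
    position = p,
    bearing_deg = initial_bearing(trk$release_site, p),
    day_of_year = as.integer(format(pos$timestamp[i], "%j", tz = "UTC")),
    timestamp = pos$timestamp[i],
    index = i
  ), class = "crossing_event")
}

#' Endpoint metrics of a track
#'
#' The endpoint is the temporally last retained position -- the best
#' available proxy for progress towards the wintering grounds when
#' transmission ends early. Longitudinal displacement is the wrapped
#' difference endpoint longitude minus release longitude, west negative.
#'
#' @param trk A [track()] with at least one retained position.
#' @return A list with `endpoint` ([geo_point()]), `bearing_to_endpoint_deg`
#'   (`NA` if the endpoint coincides with the release site),
#'   `lon_displacement_deg` and `endpoint_day_of_year`.
#' @export
endpoint_metrics <- function(trk) {
  stopifnot(inherits(trk, "track"))
  pos <- trk$positions
  if (nrow(pos) == 0L) abort("Track has no retained positions.")
  i <- nrow(pos)
  ep <- geo_point(pos$lat[i], pos$lon[i])
  brg <- if (gc_distance(trk$release_site, ep) < 1e-9) NA_real_ else
    initial_bearing(trk$release_site, ep)
  list(
    endpoint = ep,
    bearing_to_endpoint_deg = brg,
    lon_displacement_deg = wrap_lon(ep$lon - trk$release_site$lon),
    endpoint_day_of_year = as.integer(format(pos$timestamp[i], "%j", tz = "UTC"))
  )
}

#' Standardise track longitudes to the release site
#'
#' Shifts every track so that its release longitude becomes 0: position
#' longitudes are replaced by their wrapped offset from the release
#' longitude. Latitudes are unchanged. Used to overlay control and
#' displaced tracks in a common longitude frame.
#'
#' @param tracks A list of [track()] objects (or a single track).
#' @return The tracks, re-referenced (same structure as the input).
#' @export
standardize_longitude <- function(tracks) {
  single <- inherits(tracks, "track")
  if (single) tracks <- list(tracks)
  out <- lapply(tracks, function(trk) {
    off <- trk$release_site$lon
    trk$positions$lon <- wrap_lon(trk$positions$lon - off)
    trk$release_site <- geo_point(trk$release_site$lat, 0)
    trk
  })
  if (single) out[[1]] else out
}

#' Per-bird track metrics table
#'
#' Runs quality filtering, duty-cycle selection, onset detection, threshold
#' crossings and endpoint metrics over a set of tracks and returns the tidy
#' per-bird table that the group-comparison stage consumes. Milestones a
#' bird never reached are `NA`.
#'
#' @param tracks List of [track()] objects.
#' @param thresholds_km Ascending distance thresholds (default `c(500, 1000)`).
#' @param duty_cycle_hours Duty-cycle length for [select_duty_cycle_positions()];
#'   `NULL` skips the reduction (for already-reduced tracks).
#' @param onset Named list of arguments for [detect_migration_onset()].
#' @return A tibble with one row per bird: ids and cohort labels, retained
#'   fix count, `started_migration`, `onset_index`, then per threshold
#'   `bearing_<t>` / `doy_<t>`, and endpoint columns `endpoint_lat`,
#'   `endpoint_lon`, `endpoint_bearing`, `lon_displacement`, `endpoint_doy`.
#' @export
track_metrics <- function(tracks, thresholds_km = c(500, 1000),
                          duty_cycle_hours = 58, onset = list()) {
  stopifnot(length(tracks) > 0L)
  if (is.unsorted(thresholds_km, strictly = TRUE)) {
    abort("`thresholds_km` must be strictly ascending.")
  }
  rows <- purrr::map(tracks, function(trk) {
    trk <- filter_quality(trk)
    if (!is.null(duty_cycle_hours)) {
      trk <- select_duty_cycle_positions(trk, duty_cycle_hours)
    }
    n_kept <- n_positions(trk)
    base <- tibble::tibble(
      bird_id = trk$bird_id, age = trk$age, group = trk$group, year = trk$year,
      n_fixes = n_kept,
      started_migration = if (n_kept > 0) started_migration(trk) else FALSE
    )
    if (n_kept == 0L) {
      base$onset_index <- NA_integer_
      for (t in thresholds_km) {
        base[[paste0("bearing_", t)]] <- NA_real_
        base[[paste0("doy_", t)]] <- NA_integer_
      }
      base$endpoint_lat <- NA_real_; base$endpoint_lon <- NA_real_
      base$endpoint_bearing <- NA_real_; base$lon_displacement <- NA_real_
      base$endpoint_doy <- NA_integer_
      return(base)
    }
    onset_idx <- do.call(detect_migration_onset, c(list(trk), onset))
    base$onset_index <- onset_idx
    for (t in thresholds_km) {
      ev <- if (is.na(onset_idx)) NULL else crossing_event(trk, t, onset_idx)
      base[[paste0("bearing_", t)]] <- if (is.null(ev)) NA_real_ else ev$bearing_deg
      base[[paste0("doy_", t)]] <- if (is.null(ev)) NA_integer_ else ev$day_of_year
    }
    em <- endpoint_metrics(trk)
    base$endpoint_lat <- em$endpoint$lat
    base$endpoint_lon <- em$endpoint$lon
    base$endpoint_bearing <- em$bearing_to_endpoint_deg
    base$lon_displacement <- em$lon_displacement_deg
    base$endpoint_doy <- em$endpoint_day_of_year
    base
  })
  dplyr::bind_rows(rows)
}
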