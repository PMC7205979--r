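#' Construct a telemetry track
#'
#' A track bundles the time-ordered position fixes of one bird with its
#' cohort metadata (age class, experimental group, deployment year) and the
#' release site that anchors all distance and bearing computations.
#'
#' @param bird_id Character scalar identifier.
#' @param positions A data frame with columns `timestamp` (POSIXct, UTC),
#'   `lat`, `lon` (decimal degrees), `quality` (one of `"3" "2" "1" "0" "A"
#'   "B" "Z" "GPS"`) and `sensor` (`"doppler"` or `"gps"`). Rows are sorted
#'   by time on construction.
#' @param release_site A [geo_point()]; defaults to the first fix.
#' @param age `"juvenile"` or `"adult"` (or `NA`).
#' @param group `"control"` or `"displaced"` (or `NA`).
#' @param year Deployment year (or `NA`).
#'
#' @return An object of class `track`.
#' @export
track <- function(bird_id, positions, release_site = NULL,
                  age = NA_character_, group = NA_character_,
                  year = NA_integer_) {
  stopifnot(is.character(bird_id), length(bird_id) == 1L)
  positions <- validate_positions(positions)
  positions <- positions[order(positions$timestamp), , drop = FALSE]
  if (anyDuplicated(positions$timestamp)) {
    # Strictly increasing timestamps: keep the first fix at a duplicated time.
    positions <- positions[!duplicated(positions$timestamp), , drop = FALSE]
  }
  if (is.null(release_site)) {
    if (nrow(positions) == 0L) abort("Empty track needs an explicit `release_site`.")
    release_site <- geo_point(positions$lat[1], positions$lon[1])
  }
  stopifnot(inherits(release_site, "geo_point"))
  if (!is.na(age)) age <- match.arg(age, c("juvenile", "adult"))
  if (!is.na(group)) group <- match.arg(group, c("control", "displaced"))
  structure(
    list(bird_id = bird_id, age = age, group = group,
         year = as.integer(year), release_site = release_site,
         positions = tibble::as_tibble(positions)),
    class = "track"
  )
}

validate_positions <- function(positions) {
  positions <- tibble::as_tibble(positions)
  required <- c("timestamp", "lat", "lon", "quality", "sensor")
  missing <- setdiff(required, names(positions))
  if (length(missing)) {
    abort(paste0("Positions are missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!inherits(positions$timestamp, "POSIXct")) {
    abort("`timestamp` must be POSIXct (UTC).")
  }
  attr(positions$timestamp, "tzone") <- "UTC"
  if (any(is.na(positions$timestamp))) abort("Timestamps must not be NA.")
  if (any(is.na(positions$lat)) || any(positions$lat < -90 | positions$lat > 90)) {
    abort("Latitudes must be non-missing and within [-90, 90].")
  }
  positions$lon <- wrap_lon(positions$lon)
  if (any(is.na(positions$lon))) abort("Longitudes must not be NA.")
  positions$quality <- as.character(positions$quality)
  bad <- setdiff(unique(positions$quality), QUALITY_LEVELS)
  if (length(bad)) {
    abort(paste0("Unknown location class(es): ", paste(bad, collapse = ", ")))
  }
  positions$quality <- factor(positions$quality, levels = QUALITY_LEVELS, ordered = TRUE)
  positions$sensor <- as.character(positions$sensor)
  bad <- setdiff(unique(positions$sensor), c("doppler", "gps"))
  if (length(bad)) abort(paste0("Unknown sensor type(s): ", paste(bad, collapse = ", ")))
  positions[c("timestamp", "lat", "lon", "quality", "sensor")]
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track> %s  (%s, %s, year %s)\n", x$bird_id,
              x$age %||% NA, x$group %||% NA, x$year))
  cat(sprintf("  release: %.4f, %.4f   fixes: %d", x$release_site$lat,
              x$release_site$lon, nrow(x$positions)))
  if (nrow(x$positions) > 0L) {
    cat(sprintf("   span: %s -> %s",
                format(min(x$positions$timestamp), "%Y-%m-%d"),
                format(max(x$positions$timestamp), "%Y-%m-%d")))
  }
  cat("\n")
  invisible(x)
}

#' Number of position fixes in a track
#' @param x A [track()].
#' @return Integer fix count.
#' @export
n_positions <- function(x) nrow(x$positions)

with_positions <- function(trk, positions) {
  trk$positions <- tibble::as_tibble(positions)
  trk
}

#' Remove invalid (class Z) location estimates
#'
#' Argos class Z marks a failed position estimate; these fixes are rejected
#' before any analysis. All other classes, including the unbounded-error
#' classes A and B, are retained. Idempotent; order preserving.
#'
#' @param trk A [track()].
#' @return The track without class-Z fixes. If every fix is class Z the
#'   returned track is empty and a warning is raised.
#' @export
filter_quality <- function(trk) {
  stopifnot(inherits(trk, "track"))
  keep <- trk$positions$quality != "Z"
  out <- with_positions(trk, trk$positions[keep, , drop = FALSE])
  if (nrow(out$positions) == 0L && nrow(trk$positions) > 0L) {
    warn(sprintf("Track %s: all fixes were class Z; track is now empty.", trk$bird_id))
  }
  out
}

#' Reduce a track to one position per transmission duty cycle
#'
#' Solar-powered Argos tags transmit on a fixed duty cycle (here 10 h on /
#' 48 h off, i.e. a 58-h cycle). Within each cycle window -- anchored at the
#' track's first retained fix -- the single analysis position is the fix of
#' highest location class (GPS > 3 > 2 > 1 > 0 > A > B), with ties broken by
#' proximity of the timestamp to 12:00 UTC. Class-Z fixes, if still present,
#' never win a window over a valid class.
#'
#' @param trk A [track()].
#' @param cycle_hours Duty-cycle length in hours (> 0), default 58.
#' @return A track with at most one fix per cycle window, time order
#'   preserved.
#' @export
select_duty_cycle_positions <- function(trk, cycle_hours = 58) {
  stopifnot(inherits(trk, "track"), is.numeric(cycle_hours), cycle_hours > 0)
  pos <- trk$positions
  if (nrow(pos) <= 1L) return(trk)
  hours <- as.numeric(difftime(pos$timestamp, pos$timestamp[1], units = "hours"))
  window <- floor(hours / cycle_hours)
  noon <- as.POSIXct(paste0(format(pos$timestamp, "%Y-%m-%d"), " 12:00:00"), tz = "UTC")
  noon_gap <- abs(as.numeric(difftime(pos$timestamp, noon, units = "hours")))
  keep <- vapply(split(seq_len(nrow(pos)), window), function(idx) {
    q <- pos$quality[idx]
    best <- idx[q == max(q)]
    best[which.min(noon_gap[best])]
  }, integer(1))
  with_positions(trk, pos[sort(unname(keep)), , drop = FALSE])
}
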