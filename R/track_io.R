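#' Default Movebank-dialect column mapping
#'
#' Maps the internal position fields onto the column names used by
#' Movebank CSV exports. Pass a modified copy to [read_tracks()] /
#' [write_tracks()] for files with other headers.
#'
#' @return Named character vector: internal field -> CSV column name.
#' @export
movebank_columns <- function() {
  c(bird_id   = "individual-local-identifier",
    timestamp = "timestamp",
    lat       = "location-lat",
    lon       = "location-long",
    quality   = "argos:lc",
    sensor    = "sensor-type")
}

# Optional per-bird metadata columns understood in the same file.
meta_columns <- function() {
  c(age = "age", group = "group", year = "year",
    release_lat = "release-lat", release_lon = "release-lon")
}

normalise_sensor <- function(x) {
  x <- tolower(as.character(x))
  out <- ifelse(grepl("gps", x), "gps", "doppler")
  out[is.na(x) | x == ""] <- "doppler"
  out
}

#' Read telemetry tracks from a Movebank-dialect CSV
#'
#' One [track()] is built per bird id; positions are sorted by time. Rows
#' whose coordinates or timestamps cannot be parsed are dropped with an
#' informative message. Location classes are kept as-is (including class Z:
#' filtering is a separate, explicit step, [filter_quality()]); GPS-sensor
#' rows with no Argos class are assigned class `"GPS"`.
#'
#' @param path CSV file path.
#' @param metadata Optional per-bird table with columns `bird_id` and any of
#'   `age`, `group`, `year`, `release_lat`, `release_lon`. Overrides metadata
#'   columns embedded in the CSV. When no release site is given anywhere the
#'   first fix is used.
#' @param column_map Named character vector as returned by
#'   [movebank_columns()].
#' @param quiet Suppress row-drop messages.
#' @return A named list of [track()] objects (possibly empty, with a
#'   warning, for an empty file).
#' @export
read_tracks <- function(path, metadata = NULL, column_map = movebank_columns(),
                        quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    warn("Input file contains no data rows; returning an empty track list.")
    return(list())
  }
  missing <- setdiff(unname(column_map), names(raw))
  if (length(missing)) {
    abort(paste0("Required column(s) not found in ", path, ": ",
                 paste(missing, collapse = ", "),
                 ". Adjust `column_map` to match the file."))
  }
  df <- tibble::tibble(
    bird_id = raw[[column_map[["bird_id"]]]],
    timestamp = parse_utc(raw[[column_map[["timestamp"]]]]),
    lat = suppressWarnings(as.numeric(raw[[column_map[["lat"]]]])),
    lon = suppressWarnings(as.numeric(raw[[column_map[["lon"]]]])),
    quality = raw[[column_map[["quality"]]]],
    sensor = normalise_sensor(raw[[column_map[["sensor"]]]])
  )
  df$quality[(is.na(df$quality) | df$quality == "") & df$sensor == "gps"] <- "GPS"
  ok <- !is.na(df$timestamp) & !is.na(df$lat) & !is.na(df$lon) &
    df$lat >= -90 & df$lat <= 90 & df$quality %in% QUALITY_LEVELS
  if (!quiet && any(!ok)) {
    inform(sprintf("read_tracks: dropped %d of %d rows with unparsable or invalid fields.",
                   sum(!ok), nrow(df)))
  }
  df <- df[ok, , drop = FALSE]

  embedded <- extract_embedded_metadata(raw, column_map)
  meta <- resolve_metadata(metadata, embedded)

  tracks <- lapply(split(df, df$bird_id), function(d) {
    id <- d$bird_id[1]
    m <- meta[meta$bird_id == id, , drop = FALSE]
    release <- NULL
    if (nrow(m) == 1L && !is.na(m$release_lat) && !is.na(m$release_lon)) {
      release <- geo_point(m$release_lat, m$release_lon)
    }
    track(id, d[c("timestamp", "lat", "lon", "quality", "sensor")],
          release_site = release,
          age = if (nrow(m) == 1L) m$age else NA_character_,
          group = if (nrow(m) == 1L) m$group else NA_character_,
          year = if (nrow(m) == 1L) m$year else NA_integer_)
  })
  tracks[order(names(tracks))]
}

parse_utc <- function(x) {
  # ISO-8601 with or without the "T"; unparsable entries become NA.
  suppressWarnings(readr::parse_datetime(gsub(" ", "T", x), locale = readr::locale(tz = "UTC")))
}

extract_embedded_metadata <- function(raw, column_map) {
  mc <- meta_columns()
  present <- mc[mc %in% names(raw)]
  ids <- raw[[column_map[["bird_id"]]]]
  out <- tibble::tibble(bird_id = unique(ids))
  for (field in names(mc)) {
    col <- mc[[field]]
    if (col %in% names(raw)) {
      vals <- vapply(out$bird_id, function(id) raw[[col]][match(id, ids)], character(1))
      out[[field]] <- vals
    } else {
      out[[field]] <- NA_character_
    }
  }
  out
}

resolve_metadata <- function(metadata, embedded) {
  out <- embedded
  if (!is.null(metadata)) {
    metadata <- tibble::as_tibble(metadata)
    if (!"bird_id" %in% names(metadata)) abort("`metadata` must have a `bird_id` column.")
    for (field in c("age", "group", "year", "release_lat", "release_lon")) {
      if (field %in% names(metadata)) {
        idx <- match(out$bird_id, metadata$bird_id)
        repl <- as.character(metadata[[field]])[idx]
        out[[field]] <- ifelse(is.na(repl), out[[field]], repl)
      }
    }
    extra <- setdiff(metadata$bird_id, out$bird_id)
    if (length(extra)) {
      add <- tibble::tibble(bird_id = extra)
      for (field in c("age", "group", "year", "release_lat", "release_lon")) {
        add[[field]] <- if (field %in% names(metadata)) {
          as.character(metadata[[field]])[match(extra, metadata$bird_id)]
        } else NA_character_
      }
      out <- dplyr::bind_rows(out, add)
    }
  }
  out$year <- suppressWarnings(as.integer(out$year))
  out$release_lat <- suppressWarnings(as.numeric(out$release_lat))
  out$release_lon <- suppressWarnings(as.numeric(out$release_lon))
  out
}

#' Write tracks to CSV or GeoJSON
#'
#' CSV output uses the same Movebank-dialect columns that [read_tracks()]
#' reads, plus metadata columns (`age`, `group`, `year`, `release-lat`,
#' `release-lon`), so that a write/read cycle preserves every retained
#' field. GeoJSON output emits one `LineString` feature per bird with the
#' cohort metadata as feature properties and coordinates ordered
#' `[lon, lat]`.
#'
#' @param tracks Non-empty list of [track()] objects.
#' @param path Output file path.
#' @param format `"csv"` or `"geojson"`.
#' @param column_map Column mapping for CSV output, see [movebank_columns()].
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, format = c("csv", "geojson"),
                         column_map = movebank_columns()) {
  format <- match.arg(format)
  if (length(tracks) == 0L) abort("`tracks` is empty; nothing to write.")
  stopifnot(all(vapply(tracks, inherits, logical(1), "track")))
  if (format == "csv") {
    rows <- purrr::map(tracks, function(trk) {
      p <- trk$positions
      tibble::tibble(
        !!column_map[["bird_id"]] := trk$bird_id,
        !!column_map[["timestamp"]] := format(p$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
        !!column_map[["lat"]] := p$lat,
        !!column_map[["lon"]] := p$lon,
        !!column_map[["quality"]] := as.character(p$quality),
        !!column_map[["sensor"]] := ifelse(p$sensor == "gps", "gps", "argos-doppler-shift"),
        age = trk$age, group = trk$group, year = trk$year,
        `release-lat` = trk$release_site$lat, `release-lon` = trk$release_site$lon
      )
    })
    readr::write_csv(dplyr::bind_rows(rows), path, progress = FALSE)
  } else {
    features <- purrr::map(unname(tracks), function(trk) {
      coords <- mapply(function(lon, lat) c(lon, lat),
                       trk$positions$lon, trk$positions$lat,
                       SIMPLIFY = FALSE, USE.NAMES = FALSE)
      list(
        type = "Feature",
        properties = list(bird_id = trk$bird_id, age = trk$age,
                          group = trk$group, year = trk$year,
                          release = c(trk$release_site$lon, trk$release_site$lat)),
        geometry = list(type = "LineString", coordinates = coords)
      )
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
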