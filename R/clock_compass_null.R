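#' Extract movement steps for the clock-and-compass null
#'
#' A clock-and-compass migrant strings together innately oriented flights;
#' the null model therefore treats each observed long movement between
#' consecutive retained fixes as one "step" and resamples them. A step is
#' retained when its great-circle length strictly exceeds `min_step_km`
#' (default 100 km); it is recorded as the signed longitude and latitude
#' differences it traversed (longitude difference wrapped).
#'
#' @param tracks List of [track()] objects (typically the quality-filtered,
#'   duty-cycle-reduced young cohort).
#' @param min_step_km Minimum step length in km, strict (default 100).
#' @return A `step_set`: tibble with columns `source_bird`, `dlon`, `dlat`,
#'   `gc_length_km` and a `provenance` attribute listing contributing
#'   birds. Errors if no step qualifies.
#' @export
extract_steps <- function(tracks, min_step_km = 100) {
  if (inherits(tracks, "track")) tracks <- list(tracks)
  stopifnot(length(tracks) > 0L)
  rows <- purrr::map(tracks, function(trk) {
    pos <- trk$positions
    if (nrow(pos) < 2L) return(NULL)
    from <- pos[-nrow(pos), c("lat", "lon")]
    to <- pos[-1, c("lat", "lon")]
    len <- gc_distance(from, to)
    keep <- len > min_step_km
    if (!any(keep)) return(NULL)
    tibble::tibble(
      source_bird = trk$bird_id,
      dlon = wrap_lon(to$lon[keep] - from$lon[keep]),
      dlat = to$lat[keep] - from$lat[keep],
      gc_length_km = len[keep]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    abort(paste0("No movement longer than ", min_step_km,
                 " km found; cannot build a step set."))
  }
  structure(out, provenance = unique(out$source_bird),
            class = c("step_set", class(out)))
}

#' Simulate clock-and-compass endpoints by step resampling
#'
#' Builds the null endpoint distribution of a vector-orientation migrant:
#' for each total step count k in `k_min:k_max`, `tracks_per_k` simulated
#' tracks are formed by summing k steps drawn uniformly with replacement
#' from the observed step set, starting from the origin (0, 0). Steps are
#' drawn as joint (dlon, dlat) pairs by default, preserving the directional
#' correlation of real flights; `pair_axes = FALSE` resamples the two axes
#' independently as a sensitivity variant. The summation is planar in
#' (longitude, latitude) space, deliberately matching the simple null the
#' classification is defined against.
#'
#' @param steps A `step_set` from [extract_steps()] (or any data frame with
#'   `dlon` and `dlat` columns).
#' @param k_min,k_max Range of total step counts (defaults 1 and 15).
#' @param tracks_per_k Simulated tracks per step count (default 1000, i.e.
#'   15,000 endpoints under the defaults).
#' @param seed Optional integer seed; a fixed seed makes the cloud
#'   bit-reproducible.
#' @param pair_axes Resample (dlon, dlat) jointly (default `TRUE`).
#' @return An `endpoint_cloud`: tibble with columns `k`, `dlon`, `dlat`
#'   (one row per simulated endpoint) and a `config` attribute recording
#'   `k_min`, `k_max`, `tracks_per_k`, `seed`, `pair_axes` and the step
#'   count.
#' @export
simulate_endpoints <- function(steps, k_min = 1, k_max = 15,
                               tracks_per_k = 1000, seed = NULL,
                               pair_axes = TRUE) {
  stopifnot(is.data.frame(steps), nrow(steps) > 0L,
            all(c("dlon", "dlat") %in% names(steps)),
            k_min >= 1, k_max >= k_min, tracks_per_k >= 1)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    set.seed(seed)
  }
  n_steps <- nrow(steps)
  per_k <- purrr::map(k_min:k_max, function(k) {
    idx <- matrix(sample.int(n_steps, k * tracks_per_k, replace = TRUE),
                  nrow = k)
    dlon <- colSums(matrix(steps$dlon[idx], nrow = k))
    if (pair_axes) {
      dlat <- colSums(matrix(steps$dlat[idx], nrow = k))
    } else {
      idx2 <- matrix(sample.int(n_steps, k * tracks_per_k, replace = TRUE),
                     nrow = k)
      dlat <- colSums(matrix(steps$dlat[idx2], nrow = k))
    }
    tibble::tibble(k = k, dlon = dlon, dlat = dlat)
  })
  out <- dplyr::bind_rows(per_k)
  structure(out,
            config = list(k_min = k_min, k_max = k_max,
                          tracks_per_k = tracks_per_k, seed = seed,
                          pair_axes = pair_axes, n_source_steps = n_steps),
            class = c("endpoint_cloud", class(out)))
}

# Two-sided empirical p for one observation against a reference sample,
# plus the lower-tail quantile it is based on.
empirical_two_sided <- function(obs, ref) {
  q <- (sum(ref < obs) + 0.5 * sum(ref == obs)) / length(ref)
  list(q = q, p = min(2 * min(q, 1 - q), 1))
}

#' Classify displaced birds as compensating outliers
#'
#' Compares each bird's observed release-relative endpoint against the
#' clock-and-compass null cloud: the two-sided empirical quantile of the
#' observed longitudinal displacement among the null endpoints gives a
#' per-bird significance level (at 0.05 and 0.001), and a significant bird
#' is called compensating only when its deviation lies in the direction of
#' compensation (westward after an eastward displacement, or vice versa).
#'
#' @param cloud An `endpoint_cloud` from [simulate_endpoints()].
#' @param observed Data frame with columns `bird_id`, `dlon`, `dlat` --
#'   endpoints relative to each bird's release site, in the same frame as
#'   the cloud (see [endpoint_metrics()]; `dlon` is `lon_displacement`).
#' @param compensation_sign Direction that counts as compensation:
#'   `"westward"` (default; eastward displacement) or `"eastward"`.
#' @param lat_band_deg Optional half-width (degrees) of a latitude band:
#'   each bird is then compared only against null endpoints with
#'   `|dlat - dlat_obs| <= lat_band_deg`. If the band contains no
#'   endpoints the comparison falls back to the full cloud with a warning.
#'   `NULL` (default) uses the pooled cloud.
#' @return A tibble with one row per bird: `bird_id`, `dlon`, `dlat`,
#'   `lon_quantile`, `p`, `level` (`"ns"`, `"p<0.05"`, `"p<0.001"`),
#'   `direction` (`"toward_control_route"` / `"away"`), `compensating`
#'   and `n_reference`.
#' @export
classify_compensation <- function(cloud, observed,
                                  compensation_sign = c("westward", "eastward"),
                                  lat_band_deg = NULL) {
  compensation_sign <- match.arg(compensation_sign)
  stopifnot(is.data.frame(cloud), all(c("dlon", "dlat") %in% names(cloud)),
            is.data.frame(observed),
            all(c("bird_id", "dlon", "dlat") %in% names(observed)))
  rows <- purrr::pmap(observed[c("bird_id", "dlon", "dlat")],
                      function(bird_id, dlon, dlat) {
    ref <- cloud$dlon
    n_ref <- length(ref)
    if (!is.null(lat_band_deg)) {
      in_band <- abs(cloud$dlat - dlat) <= lat_band_deg
      if (any(in_band)) {
        ref <- cloud$dlon[in_band]
        n_ref <- sum(in_band)
      } else {
        warn(sprintf("Bird %s: latitude band holds no null endpoints; using the full cloud.",
                     bird_id))
      }
    }
    e <- empirical_two_sided(dlon, ref)
    level <- if (e$p < 0.001) "p<0.001" else if (e$p < 0.05) "p<0.05" else "ns"
    westward_side <- e$q <= 0.5
    toward <- (compensation_sign == "westward") == westward_side
    tibble::tibble(
      bird_id = bird_id, dlon = dlon, dlat = dlat,
      lon_quantile = e$q, p = e$p, level = level,
      direction = if (toward) "toward_control_route" else "away",
      compensating = level != "ns" && toward,
      n_reference = n_ref
    )
  })
  dplyr::bind_rows(rows)
}

#' Longitudinal quantile envelopes of the null cloud
#'
#' Per-latitude-band empirical envelopes of the null longitudinal
#' displacement, for drawing confidence contours over an endpoint scatter.
#' For each `lat_bin_deg`-wide band of `dlat` and each significance level
#' alpha, the (alpha/2, 1 - alpha/2) empirical quantiles of `dlon` are
#' reported.
#'
#' @param cloud An `endpoint_cloud` from [simulate_endpoints()].
#' @param levels Significance levels (default `c(0.05, 0.001)`).
#' @param lat_bin_deg Latitude bin width in degrees (default 2).
#' @return A tibble with `lat_mid`, `level`, `lower`, `upper`, `n` and
#'   `reliable` (`FALSE` for bins with fewer than 20 endpoints).
#' @export
null_contours <- function(cloud, levels = c(0.05, 0.001), lat_bin_deg = 2) {
  stopifnot(is.data.frame(cloud), nrow(cloud) > 0L, lat_bin_deg > 0)
  bin <- floor(cloud$dlat / lat_bin_deg)
  per_bin <- split(cloud$dlon, bin)
  rows <- purrr::imap(per_bin, function(v, b) {
    b <- as.numeric(b)
    purrr::map(levels, function(a) tibble::tibble(
      lat_mid = (b + 0.5) * lat_bin_deg,
      level = a,
      lower = unname(quantile(v, a / 2, type = 7)),
      upper = unname(quantile(v, 1 - a / 2, type = 7)),
      n = length(v),
      reliable = length(v) >= 20L
    )) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$level, .data$lat_mid)
}

#' Plot the null endpoint cloud with observed endpoints
#'
#' Scatter of simulated clock-and-compass endpoints in release-relative
#' (longitude, latitude) space, with per-latitude-band confidence
#' envelopes and, optionally, the observed bird endpoints overlaid.
#'
#' @param cloud An `endpoint_cloud`.
#' @param observed Optional data frame with `dlon`, `dlat` and (optionally)
#'   `group` columns.
#' @param levels Envelope significance levels (default `c(0.05, 0.001)`).
#' @param lat_bin_deg Envelope bin width (default 2).
#' @param subsample Optional number of cloud points to draw (plotting
#'   only); `NULL` draws all.
#' @return A ggplot object.
#' @export
plot_endpoint_cloud <- function(cloud, observed = NULL,
                                levels = c(0.05, 0.001), lat_bin_deg = 2,
                                subsample = NULL) {
  pts <- tibble::as_tibble(cloud)
  if (!is.null(subsample) && subsample < nrow(pts)) {
    pts <- pts[sample.int(nrow(pts), subsample), ]
  }
  env <- null_contours(cloud, levels = levels, lat_bin_deg = lat_bin_deg)
  env <- env[env$reliable, , drop = FALSE]
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$dlon, y = .data$dlat)) +
    ggplot2::geom_point(colour = "grey70", size = 0.4, alpha = 0.5) +
    ggplot2::geom_path(data = env,
                       ggplot2::aes(x = .data$lower, y = .data$lat_mid,
                                    linetype = factor(.data$level)),
                       colour = "grey30") +
    ggplot2::geom_path(data = env,
                       ggplot2::aes(x = .data$upper, y = .data$lat_mid,
                                    linetype = factor(.data$level)),
                       colour = "grey30") +
    ggplot2::labs(x = "Longitude relative to release (deg)",
                  y = "Latitude relative to release (deg)",
                  linetype = "Envelope level") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    obs <- tibble::as_tibble(observed)
    if (!"group" %in% names(obs)) obs$group <- "observed"
    p <- p + ggplot2::geom_point(data = obs,
                                 ggplot2::aes(colour = .data$group), size = 2)
  }
  p
}
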