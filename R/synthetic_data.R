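#' Navigation-strategy parameters for the track generator
#'
#' Describes how a synthetic bird chooses its daily displacement
#' directions:
#' \describe{
#'   \item{`clock_compass`}{every day's direction is drawn von
#'     Mises-distributed around a fixed innate heading -- vector
#'     orientation, the null strategy. Predicts no correction after
#'     displacement.}
#'   \item{`goal_navigation`}{directions are drawn around the current
#'     great-circle bearing to a goal point -- full compensation.}
#'   \item{`partial`}{each day the bird orients to the goal with
#'     probability `mix_c` and follows the innate heading otherwise (a
#'     von Mises mixture); `mix_c = 0` reduces to `clock_compass`,
#'     `mix_c = 1` to `goal_navigation`.}
#' }
#'
#' @param strategy One of `"clock_compass"`, `"goal_navigation"`,
#'   `"partial"`.
#' @param heading_mu_deg Innate mean heading in degrees (default 195,
#'   south-southwest).
#' @param kappa von Mises concentration of daily directions (> 0; default
#'   15, i.e. a circular SD of roughly 15 degrees).
#' @param step_shape,step_scale_km Gamma parameters of the per-step
#'   displacement length (defaults shape 2.5, scale 100 km: mean 250 km
#'   per movement step).
#' @param n_steps Integer range `c(min, max)` of migration movement steps
#'   (default `c(8, 15)`, aligned with the 1..15 step counts the
#'   resampling null simulates).
#' @param goal A [geo_point()]; only used by `goal_navigation`/`partial`.
#'   The default (30 N, 13 E) is the waypoint of the uncompensated control
#'   route at the cohort's expected migration distance (about 2,900 km
#'   along the innate heading from the trapping site): a navigating bird
#'   on a truncated track heads for where the species route is at its
#'   current progress, not straight for the distant winter grounds.
#' @param mix_c Compensation weight in \[0, 1\] for `partial` (default 0.5).
#' @param wander_days Integer range of pre-departure days of short (< 50
#'   km) undirected movements around the release site (default `c(0, 5)`).
#' @return A list of class `strategy_params`.
#' @export
strategy_params <- function(strategy = c("clock_compass", "goal_navigation", "partial"),
                            heading_mu_deg = 195, kappa = 15,
                            step_shape = 2.5, step_scale_km = 100,
                            n_steps = c(8, 15), goal = geo_point(30, 13),
                            mix_c = 0.5, wander_days = c(0, 5)) {
  strategy <- match.arg(strategy)
  stopifnot(kappa > 0, mix_c >= 0, mix_c <= 1,
            length(n_steps) == 2L, n_steps[1] >= 1, n_steps[2] >= n_steps[1],
            step_shape > 0, step_scale_km > 0,
            length(wander_days) == 2L, wander_days[1] >= 0)
  if (strategy == "clock_compass") mix_c <- 0
  if (strategy == "goal_navigation") mix_c <- 1
  structure(list(strategy = strategy, heading_mu_deg = wrap_bearing(heading_mu_deg),
                 kappa = kappa, step_shape = step_shape,
                 step_scale_km = step_scale_km, n_steps = as.integer(n_steps),
                 goal = goal, mix_c = mix_c, wander_days = as.integer(wander_days)),
            class = "strategy_params")
}

#' Observation-noise and duty-cycle parameters
#'
#' Emulates Argos satellite telemetry: fixes arrive only during the
#' transmitter's on-windows, carry a location class drawn from `class_mix`,
#' and are displaced from the true position by isotropic Gaussian noise
#' with a class-dependent standard deviation. The default class sigmas
#' follow the nominal Argos error classes (3: < 250 m, 2: 250-500 m, 1:
#' 0.5-1.5 km, 0: > 1.5 km); the unbounded classes A/B and the invalid
#' class Z are given large nominal sigmas, and GPS fixes ~30 m.
#'
#' @param class_mix Named probabilities over location classes (must sum
#'   to 1). The default includes 2\% class-Z fixes so that the rejection
#'   step is exercised.
#' @param class_sigma_km Named per-class noise SD in km.
#' @param duty_cycle_hours Full duty-cycle length (default 58 = 10 h on +
#'   48 h off).
#' @param on_hours Transmission-window length in hours (default 10).
#' @param fixes_per_window Integer range of fixes per on-window (default
#'   `c(1, 3)`).
#' @param sensor `"doppler"` (default) or `"gps"`; GPS tags yield class
#'   `"GPS"` fixes with GPS noise regardless of `class_mix`.
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(class_mix = c("3" = 0.15, "2" = 0.20, "1" = 0.25,
                                       "0" = 0.20, "A" = 0.10, "B" = 0.08,
                                       "Z" = 0.02),
                         class_sigma_km = c("3" = 0.25, "2" = 0.5, "1" = 1.5,
                                            "0" = 3, "A" = 5, "B" = 10,
                                            "Z" = 50, "GPS" = 0.03),
                         duty_cycle_hours = 58, on_hours = 10,
                         fixes_per_window = c(1, 3),
                         sensor = c("doppler", "gps")) {
  sensor <- match.arg(sensor)
  stopifnot(abs(sum(class_mix) - 1) < 1e-8, all(class_mix >= 0),
            all(class_sigma_km >= 0), duty_cycle_hours > 0,
            on_hours > 0, on_hours <= duty_cycle_hours)
  if (!all(names(class_mix) %in% QUALITY_LEVELS)) abort("Unknown class in `class_mix`.")
  if (!all(names(class_mix) %in% names(class_sigma_km))) {
    abort("Every class in `class_mix` needs a sigma in `class_sigma_km`.")
  }
  structure(list(class_mix = class_mix, class_sigma_km = class_sigma_km,
                 duty_cycle_hours = duty_cycle_hours, on_hours = on_hours,
                 fixes_per_window = as.integer(fixes_per_window), sensor = sensor),
            class = "noise_params")
}

#' Draw von Mises random angles
#'
#' Best-Fisher rejection sampler for the von Mises distribution; nearly
#' uniform draws are returned for very small concentrations.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction in degrees.
#' @param kappa Concentration (>= 0).
#' @return Angles in degrees in \[0, 360).
#' @export
rvonmises <- function(n, mu_deg, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * runif(1))
    f <- (1 + rr * z) / (rr + z)
    cc <- kappa * (rr - f)
    u2 <- runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      theta <- sign(runif(1) - 0.5) * acos(pmin(pmax(f, -1), 1))
      out[i] <- theta + mu_deg * pi / 180
    }
  }
  wrap_bearing(out * 180 / pi)
}

#' Generate one synthetic telemetry track
#'
#' Simulates a migrating bird on the sphere: an optional pre-departure
#' wandering phase (one short undirected move per day) followed by
#' `n_steps` migration movement steps whose directions follow the bird's
#' navigation strategy ([strategy_params()]) and whose lengths are
#' gamma-distributed. One movement step spans one transmitter duty cycle,
#' so the movement unit the generator emits is the same unit the
#' between-fix step extraction and the resampling null operate on. The
#' path is then observed through the Argos-style duty cycle with
#' class-dependent position noise ([noise_params()]); fix positions are
#' interpolated linearly in time between waypoints before noise is added.
#'
#' @param bird_id Identifier.
#' @param release A [geo_point()] release site.
#' @param params A [strategy_params()].
#' @param noise A [noise_params()].
#' @param seed Optional integer seed (per-bird reproducibility).
#' @param start Release time (POSIXct UTC or something coercible); default
#'   2016-08-01 12:00 UTC.
#' @param age,group,year Cohort metadata stored on the track.
#' @return A list with `track` (a [track()]) and `truth` (one-row tibble
#'   with the generating strategy, the true -- noise-free -- endpoint and
#'   its release-relative longitude).
#' @export
gen_track <- function(bird_id, release, params = strategy_params(),
                      noise = noise_params(), seed = NULL,
                      start = as.POSIXct("2016-08-01 12:00:00", tz = "UTC"),
                      age = "juvenile", group = "control", year = 2016L) {
  stopifnot(inherits(release, "geo_point"), inherits(params, "strategy_params"),
            inherits(noise, "noise_params"))
  if (!is.null(seed)) set.seed(seed)
  start <- as.POSIXct(start, tz = "UTC")

  wander <- if (params$wander_days[2] > params$wander_days[1]) {
    sample(params$wander_days[1]:params$wander_days[2], 1L)
  } else params$wander_days[1]
  n_mig <- if (params$n_steps[2] > params$n_steps[1]) {
    sample(params$n_steps[1]:params$n_steps[2], 1L)
  } else params$n_steps[1]

  cycle_secs <- noise$duty_cycle_hours * 3600
  lat <- release$lat
  lon <- release$lon
  way_t <- 0
  headings <- numeric(0)
  for (d in seq_len(wander)) {
    cur <- geo_point(lat[length(lat)], lon[length(lon)])
    nxt <- destination_point(cur, runif(1, 0, 360), runif(1, 5, 30))
    lat <- c(lat, nxt$lat); lon <- c(lon, nxt$lon)
    way_t <- c(way_t, way_t[length(way_t)] + 86400)
  }
  for (d in seq_len(n_mig)) {
    cur <- geo_point(lat[length(lat)], lon[length(lon)])
    use_goal <- params$mix_c > 0 && runif(1) < params$mix_c
    mu <- if (use_goal) initial_bearing(cur, params$goal) else params$heading_mu_deg
    dir <- rvonmises(1, mu, params$kappa)
    len <- rgamma(1, shape = params$step_shape, scale = params$step_scale_km)
    nxt <- destination_point(cur, dir, len)
    lat <- c(lat, nxt$lat); lon <- c(lon, nxt$lon)
    way_t <- c(way_t, way_t[length(way_t)] + cycle_secs)
    headings <- c(headings, dir)
  }
  day_times <- start + way_t
  total_secs <- way_t[length(way_t)]

  # Observe through the duty cycle.
  win_starts <- seq(0, total_secs, by = noise$duty_cycle_hours * 3600)
  fw <- noise$fixes_per_window
  fix_times <- purrr::map(win_starts, function(ws) {
    m <- if (fw[2] > fw[1]) sample(fw[1]:fw[2], 1L) else fw[1]
    ft <- ws + runif(m, 0, noise$on_hours * 3600)
    ft[ft <= total_secs]
  })
  fix_times <- sort(unique(c(0, unlist(fix_times))))
  t_num <- as.numeric(day_times) - as.numeric(start)
  true_lat <- stats::approx(t_num, lat, xout = fix_times, rule = 2)$y
  true_lon <- stats::approx(t_num, lon, xout = fix_times, rule = 2)$y
  nf <- length(fix_times)
  if (noise$sensor == "gps") {
    cls <- rep("GPS", nf)
  } else {
    cls <- sample(names(noise$class_mix), nf, replace = TRUE, prob = noise$class_mix)
  }
  sig <- unname(noise$class_sigma_km[cls])
  km_per_deg <- 2 * pi * EARTH_RADIUS_KM / 360
  obs_lat <- true_lat + rnorm(nf) * sig / km_per_deg
  obs_lat <- pmin(pmax(obs_lat, -90), 90)
  obs_lon <- wrap_lon(true_lon + rnorm(nf) * sig / (km_per_deg * cos(true_lat * pi / 180)))

  pos <- tibble::tibble(
    timestamp = start + fix_times,
    lat = obs_lat, lon = obs_lon, quality = cls,
    sensor = noise$sensor
  )
  trk <- track(bird_id, pos, release_site = release, age = age, group = group,
               year = year)
  truth <- tibble::tibble(
    bird_id = bird_id, age = age, group = group, year = as.integer(year),
    strategy = params$strategy, mix_c = params$mix_c,
    heading_mu_deg = params$heading_mu_deg, kappa = params$kappa,
    n_steps = n_mig, wander_days = wander,
    release_lat = release$lat, release_lon = release$lon,
    true_end_lat = lat[length(lat)], true_end_lon = lon[length(lon)],
    true_dlon = wrap_lon(lon[length(lon)] - release$lon)
  )
  list(track = trk, truth = truth)
}

#' Default cohort design
#'
#' The juvenile design of the displacement experiment the generator
#' emulates: 4 control young released at the trapping site (all
#' clock-and-compass) and 8 young displaced ~1,750 km east, of which 2 are
#' goal-navigators (true compensators) and 6 follow the uncorrected
#' clock-and-compass programme.
#'
#' @return A tibble with columns `age`, `group`, `n`, `strategy`, `mix_c`.
#' @export
cohort_design <- function() {
  tibble::tibble(
    age = "juvenile",
    group = c("control", "displaced", "displaced"),
    n = c(4L, 6L, 2L),
    strategy = c("clock_compass", "clock_compass", "goal_navigation"),
    mix_c = c(0, 0, 1)
  )
}

#' Generate a synthetic displacement-experiment cohort
#'
#' Builds one [gen_track()] bird per design row/count, releasing control
#' birds at `control_release` and displaced birds at `displaced_release`
#' (defaults: the two study sites, ~1,750 km apart). Optional design
#' columns `heading_mu_deg`, `kappa` and `mix_c` override the strategy
#' defaults per row.
#'
#' @param design Design tibble as in [cohort_design()].
#' @param control_release,displaced_release [geo_point()] release sites.
#' @param noise A [noise_params()].
#' @param seed Optional integer seed for the whole cohort.
#' @param start Release time passed to [gen_track()].
#' @param goal Goal for navigating birds (see [strategy_params()]).
#' @return A list of class `synthetic_cohort`: `tracks` (named list of
#'   [track()]), `truth` (tibble, one row per bird), `design`, `seed`.
#' @export
gen_cohort <- function(design = cohort_design(),
                       control_release = release_sites()$rybachy,
                       displaced_release = release_sites()$kazan,
                       noise = noise_params(), seed = NULL,
                       start = as.POSIXct("2016-08-01 12:00:00", tz = "UTC"),
                       goal = geo_point(30, 13)) {
  design <- tibble::as_tibble(design)
  stopifnot(all(c("age", "group", "n", "strategy") %in% names(design)),
            all(design$n >= 0))
  if (!is.null(seed)) set.seed(seed)
  tracks <- list()
  truth <- list()
  counter <- integer(0)
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    for (j in seq_len(row$n)) {
      key <- paste(row$group, row$age, sep = "_")
      counter[key] <- (if (key %in% names(counter)) counter[[key]] else 0L) + 1L
      id <- sprintf("%s_%s_%02d", row$group, row$age, counter[key])
      params <- strategy_params(
        strategy = row$strategy,
        heading_mu_deg = if ("heading_mu_deg" %in% names(row) && !is.na(row$heading_mu_deg))
          row$heading_mu_deg else 195,
        kappa = if ("kappa" %in% names(row) && !is.na(row$kappa)) row$kappa else 15,
        goal = goal,
        mix_c = if ("mix_c" %in% names(row) && !is.na(row$mix_c)) row$mix_c else 0.5
      )
      release <- if (row$group == "displaced") displaced_release else control_release
      res <- gen_track(id, release, params, noise,
                       start = start, age = row$age, group = row$group)
      tracks[[id]] <- res$track
      truth[[id]] <- res$truth
    }
  }
  structure(list(tracks = tracks, truth = dplyr::bind_rows(truth),
                 design = design, seed = seed),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits the Movebank-dialect positions CSV (readable by [read_tracks()]),
#' the ground-truth CSV and a YAML snapshot of the design and seed.
#'
#' @param cohort A `synthetic_cohort` from [gen_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (length(cohort$tracks) == 0L) {
    warn("Empty cohort; nothing written.")
    return(invisible(character(0)))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tracks = file.path(dir, "tracks.csv"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "cohort.yaml"))
  write_tracks(cohort$tracks, paths[["tracks"]], format = "csv")
  readr::write_csv(cohort$truth, paths[["truth"]], progress = FALSE)
  yaml::write_yaml(list(seed = cohort$seed,
                        design = lapply(seq_len(nrow(cohort$design)), function(i)
                          as.list(cohort$design[i, ]))),
                   paths[["config"]])
  invisible(paths)
}
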