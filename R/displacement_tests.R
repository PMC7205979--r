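#' @name cohort_comparisons
#' @title Group comparisons for displacement experiments
#'
#' @description
#' These stage functions consume the per-bird metrics table produced by
#' [track_metrics()] and assemble the standard group comparisons of a
#' displacement experiment: endpoint bearings (circular), endpoint
#' longitudinal displacement (linear), milestone bearings and timing. Each
#' returns a self-auditing `cohort_comparison` record that carries the
#' per-group summaries alongside the test result.
NULL

new_comparison <- function(metric, test, result, group_summaries, extra = list()) {
  structure(c(list(metric = metric, test = test, result = result,
                   group_summaries = group_summaries), extra),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> metric: %s, test: %s\n", x$metric, x$test))
  print(x$group_summaries)
  if (!is.null(x$result$p)) cat(sprintf("p = %.4g\n", x$result$p))
  invisible(x)
}

split_groups <- function(metrics, value_col, age = NULL, min_n = 2L) {
  stopifnot(value_col %in% names(metrics))
  if (!is.null(age)) metrics <- metrics[metrics$age %in% age, , drop = FALSE]
  metrics <- metrics[!is.na(metrics[[value_col]]), , drop = FALSE]
  groups <- split(metrics[[value_col]], metrics$group)
  small <- names(groups)[vapply(groups, length, integer(1)) < min_n]
  if (length(small)) {
    warn(paste0("Group(s) with fewer than ", min_n, " birds skipped: ",
                paste(small, collapse = ", ")))
    groups <- groups[!names(groups) %in% small]
  }
  groups
}

#' @rdname cohort_comparisons
#'
#' @param metrics Per-bird metrics tibble from [track_metrics()].
#' @param age Optional age filter (e.g. `"juvenile"`); `NULL` uses all birds.
#' @param bearing_col Column holding the bearing to compare (default
#'   `"endpoint_bearing"`; use e.g. `"bearing_500"` for initial bearings).
#' @return `compare_endpoint_bearings()`: a `cohort_comparison` with a
#'   per-group [circular_summary()] and [rayleigh_test()] plus the
#'   two-group [watson_williams()] result, or `NULL` (with a warning) when
#'   fewer than two groups have >= 2 birds.
#' @export
compare_endpoint_bearings <- function(metrics, age = NULL,
                                      bearing_col = "endpoint_bearing") {
  groups <- split_groups(metrics, bearing_col, age = age)
  if (length(groups) < 2L) {
    warn("Fewer than two usable groups; comparison skipped.")
    return(NULL)
  }
  summaries <- purrr::imap(groups, function(v, nm) {
    s <- circular_summary(v, conf_level = if (length(v) >= 3) 0.95 else NULL)
    list(group = nm, summary = s, rayleigh = rayleigh_test(s$n, s$r))
  })
  ww <- watson_williams(groups[[1]], groups[[2]])
  tab <- dplyr::bind_rows(purrr::map(summaries, function(s) tibble::tibble(
    group = s$group, n = s$summary$n, mu_deg = s$summary$mu_deg,
    r = s$summary$r, circ_sd_deg = s$summary$circ_sd_deg,
    rayleigh_p = s$rayleigh$p
  )))
  new_comparison(bearing_col, "watson_williams", ww, tab,
                 extra = list(per_group = summaries))
}

#' @rdname cohort_comparisons
#'
#' @return `compare_lon_displacement()`: a `cohort_comparison` whose
#'   primary result is the pooled two-sample t-test on endpoint
#'   longitudinal displacement (degrees, west negative) treated as linear,
#'   with the longitude-as-angle Watson-Williams test attached as
#'   `ww_crosscheck` (the two agree whenever only a small fraction of the
#'   circle of longitudes is traversed).
#' @export
compare_lon_displacement <- function(metrics, age = NULL) {
  groups <- split_groups(metrics, "lon_displacement", age = age)
  if (length(groups) < 2L) {
    warn("Fewer than two usable groups; comparison skipped.")
    return(NULL)
  }
  g1 <- groups[[1]]; g2 <- groups[[2]]
  tt <- summary_ttest(mean(g1), stats::sd(g1), length(g1),
                      mean(g2), stats::sd(g2), length(g2))
  ww <- tryCatch(watson_williams(g1, g2), error = function(e) NULL)
  tab <- tibble::tibble(
    group = names(groups),
    n = c(length(g1), length(g2)),
    mean = c(mean(g1), mean(g2)),
    sd = c(stats::sd(g1), stats::sd(g2))
  )
  new_comparison("lon_displacement", "summary_ttest", tt, tab,
                 extra = list(ww_crosscheck = ww))
}

#' @rdname cohort_comparisons
#'
#' @param milestone Timing column to compare: `"doy_500"`, `"doy_1000"` or
#'   `"endpoint_doy"` (day-of-year values).
#' @return `compare_timing()`: a `cohort_comparison` with the pooled
#'   two-sample t-test on the milestone day-of-year. Birds missing the
#'   milestone are excluded and their count reported in `n_excluded`.
#' @export
compare_timing <- function(metrics, milestone = c("doy_500", "doy_1000", "endpoint_doy"),
                           age = NULL) {
  milestone <- match.arg(milestone)
  n_missing <- sum(is.na(metrics[[milestone]]) &
                     (is.null(age) | metrics$age %in% age))
  groups <- split_groups(metrics, milestone, age = age)
  if (length(groups) < 2L) {
    warn("Fewer than two usable groups; comparison skipped.")
    return(NULL)
  }
  g1 <- as.numeric(groups[[1]]); g2 <- as.numeric(groups[[2]])
  tt <- summary_ttest(mean(g1), stats::sd(g1), length(g1),
                      mean(g2), stats::sd(g2), length(g2))
  tab <- tibble::tibble(
    group = names(groups),
    n = c(length(g1), length(g2)),
    mean = c(mean(g1), mean(g2)),
    sd = c(stats::sd(g1), stats::sd(g2))
  )
  new_comparison(milestone, "summary_ttest", tt, tab,
                 extra = list(n_excluded = n_missing))
}

#' Two-factor screen of age and displacement effects
#'
#' Additive (no-interaction) linear-model ANOVA of a per-bird response on
#' age class and experimental group, reporting a per-factor F and p. Used
#' as a small-sample screen for whether displacement, age, or both drive
#' the endpoint response.
#'
#' @param metrics Per-bird metrics tibble from [track_metrics()].
#' @param response Response column, default `"lon_displacement"`.
#' @return A tibble with one row per factor: `term`, `df`, `F`, `p`.
#'   Errors if either factor has fewer than two levels with >= 2 birds,
#'   naming the offending cell.
#' @export
two_way_screen <- function(metrics, response = "lon_displacement") {
  stopifnot(response %in% names(metrics))
  d <- metrics[!is.na(metrics[[response]]) & !is.na(metrics$age) &
                 !is.na(metrics$group), , drop = FALSE]
  for (f in c("age", "group")) {
    counts <- table(d[[f]])
    if (length(counts) < 2L || any(counts < 2L)) {
      bad <- if (length(counts) < 2L) paste0("only level(s) ", paste(names(counts), collapse = ", "))
        else paste0("level ", names(counts)[which.min(counts)], " has ", min(counts), " bird(s)")
      abort(paste0("Factor `", f, "` is not testable: ", bad, "."))
    }
  }
  d$age <- factor(d$age); d$group <- factor(d$group)
  if (stats::var(d[[response]]) == 0) {
    # No variation at all: nothing to attribute to either factor.
    return(tibble::tibble(term = c("age", "group"), df = c(1L, 1L),
                          F = c(0, 0), p = c(1, 1)))
  }
  fit <- stats::lm(stats::reformulate(c("age", "group"), response = response), data = d)
  if (fit$rank < 3L) abort("Design is rank deficient; check for an empty age x group cell.")
  an <- stats::anova(fit)
  terms <- rownames(an)[rownames(an) != "Residuals"]
  tibble::tibble(
    term = terms,
    df = an$Df[seq_along(terms)],
    F = an$`F value`[seq_along(terms)],
    p = an$`Pr(>F)`[seq_along(terms)]
  )
}
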