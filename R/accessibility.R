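#' Cumulative-opportunity coverage at a travel-time threshold
#'
#' A TAZ is covered iff its shortest travel time to a service at the given
#' congestion level is `<=` the threshold (inclusive — "within 20 minutes"
#' counts the boundary). Coverage is whole-TAZ: the covered population is
#' the sum of covered TAZs' populations, and the percent is rounded half
#' away from zero to one decimal.
#'
#' @param nearest Tibble from [nearest_service_times()].
#' @param zones Zones tibble (`taz_id`, `total_population`).
#' @param level Congestion level to evaluate.
#' @param threshold Travel-time threshold in minutes (default 20).
#' @param scenario Optional label carried into the result.
#' @return A `coverage_result` list: `scenario`, `level`, `threshold`,
#'   `covered_taz`, `covered_population`, `total_population`, `percent`.
#' @export
#' @examples
#' # 1,017,011 covered of 2,258,823 -> 45.0%
coverage <- function(nearest, zones, level, threshold = 20,
                     scenario = NULL) {
  if (threshold <= 0) abort_config("threshold must be positive")
  sub <- nearest[nearest$level == level, , drop = FALSE]
  if (nrow(sub) == 0) abort_config(sprintf("unknown level %s", level))
  covered_taz <- sub$origin_taz[sub$shortest_minutes <= threshold]
  pop <- zones$total_population[match(covered_taz, zones$taz_id)]
  structure(list(
    scenario = scenario, level = level, threshold = threshold,
    covered_taz = covered_taz,
    covered_population = sum(pop),
    total_population = sum(zones$total_population),
    percent = pct1(sum(pop), sum(zones$total_population))
  ), class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf(
    "<coverage> %s level %s, <=%g min: %s of %s persons (%.1f%%)\n",
    x$scenario %||% "", x$level, x$threshold,
    format(x$covered_population, big.mark = ","),
    format(x$total_population, big.mark = ","), x$percent))
  invisible(x)
}

check_marginals <- function(marginals, zones) {
  tot <- marginals |>
    dplyr::summarise(count = sum(.data$count),
                     .by = c("taz_id", "attribute"))
  exp <- zones$total_population[match(tot$taz_id, zones$taz_id)]
  if (any(tot$count != exp))
    abort_config("attribute totals inconsistent with TAZ populations")
}

#' Sociodemographic equity table across scenarios
#'
#' Disaggregates covered population by attribute category for each scenario
#' and reports the between-scenario variation. Category percentages use the
#' category's own citywide total as denominator; the variation column is
#' the difference of unrounded percents, rounded to one decimal (this is
#' how published variation columns reproduce). Categories with zero
#' population get `NA` percents with a warning.
#'
#' @param nearest_by_scenario Named list of [nearest_service_times()]
#'   tibbles, one per scenario, in comparison order (variation = last
#'   minus first).
#' @param zones Zones tibble.
#' @param marginals Marginals tibble (`taz_id`, `attribute`, `category`,
#'   `count`); must be consistent with `zones` totals.
#' @param level Congestion level.
#' @param threshold Threshold minutes (default 20).
#' @return Tibble with one row per (attribute, category) plus an overall
#'   row: `total`, `share_of_total`, `covered_<scenario>` and
#'   `pct_<scenario>` per scenario, `variation_count`, `pct_variation`.
#' @export
equity_table <- function(nearest_by_scenario, zones, marginals, level,
                         threshold = 20) {
  stopifnot(is.list(nearest_by_scenario),
            length(nearest_by_scenario) >= 1)
  if (is.null(names(nearest_by_scenario)))
    names(nearest_by_scenario) <- paste0("s", seq_along(nearest_by_scenario))
  check_marginals(marginals, zones)

  total_pop <- sum(zones$total_population)
  base <- marginals |>
    dplyr::summarise(total = sum(.data$count),
                     .by = c("attribute", "category"))
  base <- dplyr::bind_rows(
    tibble::tibble(attribute = "overall", category = "all",
                   total = total_pop),
    base)
  base$share_of_total <- pct1(base$total, total_pop)
  if (any(base$total == 0))
    warning("categories with zero population: percents undefined",
            call. = FALSE)

  pct_raw <- list()
  for (s in names(nearest_by_scenario)) {
    cov <- coverage(nearest_by_scenario[[s]], zones, level, threshold,
                    scenario = s)
    cat_cov <- marginals |>
      dplyr::filter(.data$taz_id %in% cov$covered_taz) |>
      dplyr::summarise(covered = sum(.data$count),
                       .by = c("attribute", "category"))
    m <- match(paste(base$attribute, base$category),
               paste(cat_cov$attribute, cat_cov$category))
    covered <- ifelse(is.na(m), 0L, cat_cov$covered[m])
    covered[1] <- cov$covered_population
    base[[paste0("covered_", s)]] <- covered
    pct_raw[[s]] <- 100 * covered / base$total
    base[[paste0("pct_", s)]] <- pct1(covered, base$total)
  }
  s1 <- names(nearest_by_scenario)[1]
  s2 <- names(nearest_by_scenario)[length(nearest_by_scenario)]
  base$variation_count <- base[[paste0("covered_", s2)]] -
    base[[paste0("covered_", s1)]]
  v <- round_half_up(pct_raw[[s2]] - pct_raw[[s1]], 1)
  v[!is.finite(v)] <- NA_real_
  base$pct_variation <- v
  base
}

#' Cumulative-opportunity curve over travel-time thresholds
#'
#' Covered population and percent at regular threshold intervals (10-minute
#' steps by default), overall and optionally per socioeconomic stratum
#' group. Non-decreasing in the threshold by construction.
#'
#' @param nearest Tibble from [nearest_service_times()].
#' @param zones Zones tibble.
#' @param level Congestion level.
#' @param marginals Optional marginals; when given and containing a
#'   `stratum_group` attribute (see [group_stratum_marginals()]), per-group
#'   curves are included.
#' @param max_threshold Largest threshold, minutes.
#' @param step Threshold step, minutes (default 10).
#' @return Tibble `threshold`, `group`, `covered`, `total`, `percent`.
#' @export
opportunity_curve <- function(nearest, zones, level, marginals = NULL,
                              max_threshold = 60, step = 10) {
  if (step <= 0) abort_config("step must be positive")
  thresholds <- seq(step, max_threshold, by = step)
  rows <- lapply(thresholds, function(th) {
    cov <- coverage(nearest, zones, level, th)
    out <- tibble::tibble(threshold = th, group = "overall",
                          covered = cov$covered_population,
                          total = cov$total_population,
                          percent = cov$percent)
    if (!is.null(marginals) &&
        "stratum_group" %in% marginals$attribute) {
      g <- marginals |>
        dplyr::filter(.data$attribute == "stratum_group") |>
        dplyr::mutate(covered_taz = .data$taz_id %in% cov$covered_taz) |>
        dplyr::summarise(
          covered = sum(.data$count[.data$covered_taz]),
          total = sum(.data$count), .by = "category")
      out <- dplyr::bind_rows(out, tibble::tibble(
        threshold = th, group = g$category, covered = g$covered,
        total = g$total, percent = pct1(g$covered, g$total)))
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Expected patient demand from prevalence
#'
#' Applies a disease prevalence (cases per 100,000 population) to a covered
#' population, rounding half up to whole patients: e.g. 700,472 persons at
#' a haemodialysis prevalence of 128/100,000 is 897 expected patients.
#'
#' @param covered_population Persons covered (vectorised).
#' @param prevalence_per_100k Cases per 100,000 persons (default 128).
#' @return Tibble `covered_population`, `prevalence_per_100k`, `patients`.
#' @export
estimate_patients <- function(covered_population,
                              prevalence_per_100k = 128) {
  if (any(covered_population < 0) || any(prevalence_per_100k < 0))
    abort_config("inputs must be nonnegative")
  tibble::tibble(
    covered_population = covered_population,
    prevalence_per_100k = prevalence_per_100k,
    patients = as.integer(round_half_up(
      covered_population * prevalence_per_100k / 1e5)))
}
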