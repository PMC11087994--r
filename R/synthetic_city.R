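#' Default hour-of-week congestion regime labels
#'
#' Weekly profile of ordered congestion regimes (1 = free-flow night traffic,
#' 9 = peak). Hours are indexed 0..167 starting Monday 00:00. The default
#' emulates a large, persistently congested city: weekday morning and evening
#' rush at the top regime, broad daytime congestion one step below (regime 8
#' holds 40 of 168 hours), and weekends that stay busy through the day.
#'
#' @return Integer vector of length 168 with values in 1..9.
#' @export
default_hour_levels <- function() {
  weekday <- c(1, 1, 1, 2, 3, 5, 7, 9, 9, 8, 8, 8,
               8, 8, 7, 8, 8, 9, 9, 8, 7, 6, 4, 2)
  weekend <- c(1, 1, 1, 1, 1, 2, 3, 4, 5, 6, 7, 7,
               7, 7, 7, 7, 7, 7, 6, 6, 5, 4, 3, 2)
  as.integer(c(rep(weekday, 5), rep(weekend, 2)))
}

#' Default per-regime travel-time multipliers
#'
#' Multiplicative slow-down of each congestion regime relative to the
#' free-flow (distance/speed) time. The lowest regime sits slightly above 1
#' so that overnight traffic still pays signal and intersection delay; this
#' also keeps the free-flow floor from censoring the generator's noise, which
#' would otherwise bias the lowest regime's mean upward.
#'
#' @return Named numeric vector of length 9, strictly increasing.
#' @export
default_level_multipliers <- function() {
  setNames(c(1.05, 1.12, 1.20, 1.32, 1.45, 1.62, 1.82, 2.05, 2.50),
           as.character(1:9))
}

# citywide category shares for the non-stratum attributes (census-like
# marginals for a large Colombian city, 2018-adjusted)
city_attribute_shares <- function() {
  list(
    ethnicity = c(
      "Afrodescendent" = 325865, "Rrom (nomadic)" = 102,
      "Indigenous" = 11112, "Islander/Raizal" = 382,
      "Other (Caucasian Mestizo)" = 1890491, "Palenque" = 245,
      "N.D." = 30626),
    education = c(
      "Graduate degree" = 72441, "Bachelor's Degree" = 295319,
      "Technical" = 244160, "Middle" = 608429, "High School" = 337065,
      "Primary" = 468206, "Pre-school" = 36294, "No data" = 196909),
    literacy = c(
      "Literate" = 2043041, "No literacy" = 66383,
      "N.A." = 121140, "N.D." = 28259),
    sex = c("Fem" = 1208617, "Masc" = 1050206),
    civil_status = c(
      "Single" = 821536, "Married or cohabitation" = 896958,
      "Divorced or separated" = 163980, "Widow" = 95611,
      "N.A." = 254492, "N.D." = 26246),
    age_band = c(
      "0-14" = 400527, "15-24" = 363311, "25-59" = 1118758, "60+" = 376227)
  )
}

# citywide socioeconomic stratum shares, levels 1..6 plus undetermined;
# low (1-2) ~49%, middle (3-4) ~41%, high (5-6) ~9%
city_stratum_shares <- function() {
  c("1" = 0.200, "2" = 0.291, "3" = 0.260, "4" = 0.154,
    "5" = 0.055, "6" = 0.036, "N.D." = 0.004)
}

#' Configuration for the synthetic-city generator
#'
#' Bundles every tunable of the generator with validated defaults that
#' emulate a large congested city of ~2.26 million people in 507 traffic
#' analysis zones (TAZs), with haemodialysis-type services concentrated in a
#' few central TAZs and low-income population densifying toward the
#' periphery.
#'
#' @param n_taz Number of traffic analysis zones.
#' @param total_population Citywide population to allocate across TAZs.
#' @param n_service_taz Number of central TAZs hosting services.
#' @param n_services Number of individual services spread over the host TAZs.
#' @param city_radius_km Radius of the (planar, km) city disc.
#' @param speed_kmh Free-flow door-to-door speed used for travel times.
#' @param access_minutes Fixed access/egress constant added to each
#'   inter-zonal free-flow time.
#' @param hour_levels Integer vector of length 168 assigning each
#'   hour-of-week to a congestion regime (the generator's ground truth).
#' @param level_multipliers Named numeric vector of per-regime travel-time
#'   multipliers, all `>= 1`, increasing.
#' @param noise_sd Standard deviation (log scale) of the lognormal
#'   multiplicative noise on hourly travel times.
#' @param income_gradient Strength of the centre-to-periphery low-stratum
#'   gradient (0 = spatially uniform strata).
#' @param seed Mandatory integer seed; all generation is deterministic
#'   given `seed` and the other fields.
#' @return A `city_config` list.
#' @export
city_config <- function(n_taz = 507,
                        total_population = 2258823,
                        n_service_taz = 6,
                        n_services = 11,
                        city_radius_km = 9,
                        speed_kmh = 30,
                        access_minutes = 2,
                        hour_levels = default_hour_levels(),
                        level_multipliers = default_level_multipliers(),
                        noise_sd = 0.05,
                        income_gradient = 0.35,
                        seed = NULL) {
  if (is.null(seed)) abort_config("a seed is mandatory for city generation")
  if (n_taz < 1 || total_population < 1 || n_service_taz < 1 ||
      n_services < 1 || city_radius_km <= 0 || speed_kmh <= 0)
    abort_config("all counts and scales in a city_config must be positive")
  if (access_minutes < 0 || noise_sd < 0)
    abort_config("access_minutes and noise_sd must be nonnegative")
  if (length(hour_levels) != 168)
    abort_config("hour_levels must assign all 168 hours of the week")
  if (!all(hour_levels %in% seq_along(level_multipliers)))
    abort_config("hour_levels refers to regimes without a multiplier")
  if (any(level_multipliers < 1))
    abort_config("congestion multipliers must be >= 1")
  structure(list(
    n_taz = as.integer(n_taz),
    total_population = as.integer(total_population),
    n_service_taz = as.integer(min(n_service_taz, n_taz)),
    n_services = as.integer(n_services),
    city_radius_km = city_radius_km,
    speed_kmh = speed_kmh,
    access_minutes = access_minutes,
    hour_levels = as.integer(hour_levels),
    level_multipliers = level_multipliers,
    noise_sd = noise_sd,
    income_gradient = income_gradient,
    seed = as.integer(seed)
  ), class = "city_config")
}

#' Generate a synthetic city
#'
#' Builds a seeded synthetic city with the structure the accessibility
#' analysis assumes: TAZ centroids on a planar disc (km), population
#' periphery-weighted, services clustered in the most central TAZs (one host
#' concentrating several services), and per-TAZ sociodemographic marginals
#' whose categories sum exactly to each TAZ's population. The share of
#' low-stratum households increases with distance from the service cluster.
#'
#' @param config A [city_config()].
#' @return A `synthetic_city` list with elements `zones` (tibble: `taz_id`,
#'   `x`, `y`, `total_population`, plus a `polygon` list-column of square
#'   rings), `marginals` (tibble: `taz_id`, `attribute`, `category`,
#'   `count`), `services` (tibble: `service_id`, `taz_id`, `chairs`) and the
#'   `config`.
#' @export
#' @examples
#' city <- generate_city(city_config(n_taz = 20, total_population = 5e4,
#'                                   seed = 1))
#' sum(city$zones$total_population)
generate_city <- function(config) {
  stopifnot(inherits(config, "city_config"))
  set.seed(config$seed)
  n <- config$n_taz
  R <- config$city_radius_km

  # centroids: uniform over the disc, centre-first so TAZ ids are stable
  r <- R * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  ord <- order(r)
  x <- (r * cos(th))[ord]
  y <- (r * sin(th))[ord]
  if (n == 1) { x <- 0; y <- 0 }
  taz_id <- sprintf("TAZ%04d", seq_len(n))
  dist_centre <- sqrt(x^2 + y^2)

  # population: denser toward the periphery, with lognormal heterogeneity
  w <- (0.35 + dist_centre / max(R, dist_centre)) * exp(rnorm(n, 0, 0.4))
  pop <- largest_remainder(w, config$total_population)

  # polygons: square rings around each centroid (centroid strictly inside)
  half <- sqrt(pi * R^2 / n) / 2
  polygon <- lapply(seq_len(n), function(i) {
    cbind(x = x[i] + half * c(-1, 1, 1, -1, -1),
          y = y[i] + half * c(-1, -1, 1, 1, -1))
  })

  zones <- tibble::tibble(taz_id = taz_id, x = x, y = y,
                          total_population = pop, polygon = polygon)

  # services in the most central TAZs; extra services pile onto the two
  # most central hosts (one TAZ hosting several services)
  hosts <- taz_id[order(dist_centre)][seq_len(config$n_service_taz)]
  host_of <- hosts[1 + (seq_len(config$n_services) - 1) %% length(hosts)]
  extra <- config$n_services - length(hosts)
  if (extra > 0) {
    host_of <- c(rep(hosts[1], ceiling(extra / 2)),
                 rep(hosts[2 - (length(hosts) == 1)], floor(extra / 2)),
                 hosts)
    host_of <- host_of[seq_len(config$n_services)]
  }
  services <- tibble::tibble(
    service_id = sprintf("SVC%02d", seq_len(config$n_services)),
    taz_id = sort(host_of),
    chairs = sample(12:24, config$n_services, replace = TRUE))

  marginals <- build_marginals(zones, hosts, config)

  structure(list(zones = zones, marginals = marginals, services = services,
                 config = config),
            class = "synthetic_city")
}

# per-TAZ attribute marginals; stratum gets a centre-periphery gradient,
# other attributes follow citywide shares; every attribute sums to the
# TAZ population exactly (largest-remainder within TAZ)
build_marginals <- function(zones, host_tazs, config) {
  n <- nrow(zones)
  pop <- zones$total_population

  hx <- mean(zones$x[zones$taz_id %in% host_tazs])
  hy <- mean(zones$y[zones$taz_id %in% host_tazs])
  d <- sqrt((zones$x - hx)^2 + (zones$y - hy)^2)
  d_norm <- if (max(d) > 0) d / max(d) else rep(0, n)
  d_bar <- sum(d_norm * pop) / sum(pop)

  strat <- city_stratum_shares()
  low0 <- strat[["1"]] + strat[["2"]]
  high0 <- strat[["5"]] + strat[["6"]]
  nd0 <- strat[["N.D."]]

  rows <- vector("list", n)
  shares_fixed <- city_attribute_shares()
  for (i in seq_len(n)) {
    # low share rises with distance from the service cluster; the
    # population-weighted city aggregate stays at the configured share
    low_i <- min(max(low0 + config$income_gradient * (d_norm[i] - d_bar),
                     0.02), 0.95)
    high_i <- min(max(high0 - 0.6 * config$income_gradient *
                        (d_norm[i] - d_bar), 0.005), 0.6)
    mid_i <- max(1 - nd0 - low_i - high_i, 0.02)
    s <- c("1" = low_i * strat[["1"]] / low0,
           "2" = low_i * strat[["2"]] / low0,
           "3" = mid_i * strat[["3"]] / (strat[["3"]] + strat[["4"]]),
           "4" = mid_i * strat[["4"]] / (strat[["3"]] + strat[["4"]]),
           "5" = high_i * strat[["5"]] / high0,
           "6" = high_i * strat[["6"]] / high0,
           "N.D." = nd0)
    tabs <- c(list(stratum = s), shares_fixed)
    rows[[i]] <- dplyr::bind_rows(lapply(names(tabs), function(a) {
      tibble::tibble(taz_id = zones$taz_id[i], attribute = a,
                     category = names(tabs[[a]]),
                     count = largest_remainder(unname(tabs[[a]]), pop[i]))
    }))
  }
  dplyr::bind_rows(rows)
}

#' Collapse stratum marginals into Low/Middle/High groups
#'
#' Colombian household strata 1-6 are reported grouped: Low (1 and 2),
#' Middle (3 and 4), High (5 and 6); undetermined stays `"N.D."`. Adds the
#' grouped rows as a new attribute `stratum_group`.
#'
#' @param marginals Marginals tibble as produced by [generate_city()].
#' @return The marginals with `stratum_group` rows appended.
#' @export
group_stratum_marginals <- function(marginals) {
  s <- dplyr::filter(marginals, .data$attribute == "stratum")
  map <- c("1" = "Low", "2" = "Low", "3" = "Middle", "4" = "Middle",
           "5" = "High", "6" = "High", "N.D." = "N.D.")
  g <- s |>
    dplyr::mutate(category = map[.data$category],
                  attribute = "stratum_group") |>
    dplyr::summarise(count = sum(.data$count),
                     .by = c("taz_id", "attribute", "category"))
  dplyr::bind_rows(marginals, g)
}

#' Analytic free-flow travel-time matrix of a city
#'
#' Euclidean centroid distance over the free-flow speed plus the fixed
#' access constant, in minutes; 0 on the diagonal. Row/column names are
#' TAZ ids.
#'
#' @param zones Zones tibble.
#' @param speed_kmh Free-flow speed.
#' @param access_minutes Fixed access/egress constant.
#' @return Square numeric matrix, minutes.
#' @export
free_flow_matrix <- function(zones, speed_kmh = 30, access_minutes = 2) {
  dx <- outer(zones$x, zones$x, "-")
  dy <- outer(zones$y, zones$y, "-")
  ff <- sqrt(dx^2 + dy^2) / speed_kmh * 60 + access_minutes
  diag(ff) <- 0
  dimnames(ff) <- list(zones$taz_id, zones$taz_id)
  ff
}

#' Generate the hourly travel-time tensor of a synthetic city
#'
#' Hourly door-to-door car travel times for all 168 hours of the week:
#' free-flow time is Euclidean centroid distance over the configured speed
#' plus a fixed access constant; each hour multiplies it by its congestion
#' regime's multiplier and lognormal noise, clamped to the free-flow floor.
#' Within-TAZ (diagonal) times are 0 by convention — the TAZ is the unit of
#' analysis. The true regime labels and multipliers are carried along so
#' clustering and estimation can be scored for recovery.
#'
#' Restricting `dest_taz` mirrors the sampling design used at city scale
#' (times are only downloaded toward service-hosting TAZs) and keeps the
#' tensor small: the full 507-zone week would hold 43.1 million entries.
#'
#' @param city A `synthetic_city`.
#' @param dest_taz Destination TAZ ids (default: all zones).
#' @return An `hourly_travel` list: `minutes` array
#'   `[origin, dest, hour]` (hours 0..167), `free_flow` matrix, `origin_taz`,
#'   `dest_taz`, `hour_level` (true regimes), `level_multipliers` (truth).
#' @export
generate_hourly_travel <- function(city, dest_taz = NULL) {
  stopifnot(inherits(city, "synthetic_city"))
  config <- city$config
  zones <- city$zones
  if (nrow(zones) == 0) abort_config("city has no zones")
  dest_taz <- sort(dest_taz %||% zones$taz_id)
  if (!all(dest_taz %in% zones$taz_id))
    abort_config("dest_taz not present in the city")

  di <- match(dest_taz, zones$taz_id)
  dx <- outer(zones$x, zones$x[di], "-")
  dy <- outer(zones$y, zones$y[di], "-")
  ff <- sqrt(dx^2 + dy^2) / config$speed_kmh * 60 + config$access_minutes
  diag_cells <- outer(zones$taz_id, dest_taz, "==")
  ff[diag_cells] <- 0
  dimnames(ff) <- list(zones$taz_id, dest_taz)

  set.seed(config$seed + 104729L)  # independent stream from generate_city
  mult <- config$level_multipliers[config$hour_levels]
  no <- nrow(zones); nd <- length(dest_taz)
  eps <- if (config$noise_sd > 0) {
    exp(rnorm(no * nd * 168, 0, config$noise_sd))
  } else rep(1, no * nd * 168)
  minutes <- array(as.vector(ff) *
                     rep(mult, each = no * nd) * eps,
                   dim = c(no, nd, 168),
                   dimnames = list(zones$taz_id, dest_taz,
                                   as.character(0:167)))
  # congestion floor: no hour is faster than free flow
  floor_arr <- array(as.vector(ff), dim = dim(minutes))
  minutes <- pmax(minutes, floor_arr)
  minutes[array(as.vector(diag_cells), dim = dim(minutes))] <- 0

  structure(list(minutes = minutes, free_flow = ff,
                 origin_taz = zones$taz_id, dest_taz = dest_taz,
                 hour_level = config$hour_levels,
                 level_multipliers = config$level_multipliers,
                 config = config),
            class = "hourly_travel")
}
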