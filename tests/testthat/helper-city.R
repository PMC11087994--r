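# Shared fixtures: all built in code, seeded.

small_city <- function(seed = 7, n_taz = 20, total = 50000,
                       n_service_taz = 2, n_services = 3, ...) {
  generate_city(city_config(n_taz = n_taz, total_population = total,
                            n_service_taz = n_service_taz,
                            n_services = n_services, seed = seed, ...))
}

# city with hand-placed centroids, for closed-form travel-time checks
manual_city <- function(xy, hour_levels = rep(1L, 168),
                        level_multipliers = c("1" = 1),
                        noise_sd = 0, seed = 1, speed_kmh = 30,
                        access_minutes = 2) {
  n <- nrow(xy)
  cfg <- city_config(n_taz = n, total_population = n * 100,
                     n_service_taz = 1, n_services = 1,
                     hour_levels = hour_levels,
                     level_multipliers = level_multipliers,
                     noise_sd = noise_sd, speed_kmh = speed_kmh,
                     access_minutes = access_minutes, seed = seed)
  zones <- tibble::tibble(taz_id = sprintf("TAZ%04d", seq_len(n)),
                          x = xy[, 1], y = xy[, 2],
                          total_population = 100L,
                          polygon = vector("list", n))
  structure(list(zones = zones,
                 marginals = NULL,
                 services = tibble::tibble(service_id = "SVC01",
                                           taz_id = zones$taz_id[1],
                                           chairs = 12L),
                 config = cfg),
            class = "synthetic_city")
}

# full analysis chain on a city: hourly (all dests) -> cluster -> sample
# over all dests -> tensor without regression (estimation bypassed)
direct_analysis <- function(city, K = 9, seed = 1) {
  hourly <- generate_hourly_travel(city)
  cl <- cluster_hours(hourly, K = K, seed = seed)
  plan <- build_sampling_plan(
    city$zones, city$services, K = cl$K,
    extra_dest_taz = setdiff(city$zones$taz_id, city$services$taz_id))
  sampled <- sample_travel_times(hourly, cl, plan)
  list(hourly = hourly, clustering = cl, plan = plan, sampled = sampled,
       tensor = sampled_tensor(sampled, plan))
}

# clustering built from the generator's true regime labels (bypasses
# k-means, which can merge adjacent regimes in small noisy cities)
truth_clustering <- function(city) {
  lv <- city$config$hour_levels
  structure(list(level_of_hour = lv, K = as.integer(max(lv)),
                 level_mean_minutes = as.numeric(
                   city$config$level_multipliers),
                 hours_per_level = as.integer(table(lv))),
            class = "congestion_clustering")
}

# independent oracle: per-level aggregate of the hourly tensor by plain
# loops, then min over service TAZs
oracle_nearest <- function(hourly, clustering, services, level) {
  svc <- sort(unique(services$taz_id))
  hrs <- which(clustering$level_of_hour == level)
  sapply(seq_along(hourly$origin_taz), function(o) {
    min(sapply(svc, function(s) {
      d <- match(s, hourly$dest_taz)
      mean(hourly$minutes[o, d, hrs])
    }))
  })
}
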