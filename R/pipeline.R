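#' Run the full accessibility pipeline on a synthetic city
#'
#' Orchestrates simulate -> cluster -> sample -> estimate -> nearest ->
#' coverage/equity -> siting, and writes every report artifact to
#' `out_dir`. Two congestion scenarios are analysed (a heavy-traffic
#' baseline week and a lighter week whose multipliers are shrunk toward
#' free flow), mirroring a before/after travel-time comparison. All stages
#' are deterministic given the config seed; re-running reproduces
#' byte-identical tables.
#'
#' @param config Named list (or path to a JSON file) with any of:
#'   `n_taz`, `total_population`, `n_service_taz`, `n_services`, `seed`
#'   (mandatory), `K`, `threshold`, `step`, `max_threshold`,
#'   `prevalence_per_100k`, `n_new`, `solver` (`"exhaustive"` or `"ga"`),
#'   `scenario_scales` (named numeric, congestion shrinkage per scenario,
#'   default `c(heavy = 1, light = 0.6)`), `extra_dest_taz`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results: `city`,
#'   `clusterings`, `nearest`, `equity`, `curve`, `solutions`, `gains`,
#'   `demand`, `paths`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(list(
    n_taz = 50, total_population = 200000, n_service_taz = 3,
    n_services = 5, K = 9, threshold = 20, step = 10, max_threshold = 60,
    prevalence_per_100k = 128, n_new = 2, solver = "exhaustive",
    scenario_scales = c(heavy = 1, light = 0.6),
    extra_dest_taz = NULL, seed = NULL), config)
  if (is.null(cfg$seed)) abort_config("run config must carry a seed")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  unlink(log_path)
  log_stage <- function(stage, ...) {
    rec <- list(stage = stage, ...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE)
  }

  stage <- "simulate"
  res <- tryCatch({
    base_cfg <- city_config(
      n_taz = cfg$n_taz, total_population = cfg$total_population,
      n_service_taz = cfg$n_service_taz, n_services = cfg$n_services,
      seed = cfg$seed)
    city <- generate_city(base_cfg)
    marg <- group_stratum_marginals(city$marginals)
    write_zones_geojson(city$zones, file.path(out_dir, "zones.geojson"))
    readr::write_csv(city$marginals, file.path(out_dir, "population.csv"))
    readr::write_csv(city$services, file.path(out_dir, "services.csv"))
    log_stage("simulate", seed = cfg$seed, n_taz = cfg$n_taz,
              total_population = sum(city$zones$total_population))

    ff <- free_flow_matrix(city$zones, base_cfg$speed_kmh,
                           base_cfg$access_minutes)
    plan <- build_sampling_plan(city$zones, city$services, K = cfg$K,
                                extra_dest_taz = cfg$extra_dest_taz)
    log_stage("plan", destinations = length(plan$dest_taz),
              sample_size = plan$sample_size)

    scen_names <- names(cfg$scenario_scales)
    clusterings <- list(); nearest <- list(); tensors <- list()
    for (s in scen_names) {
      stage <- paste0("scenario:", s)
      sc <- cfg$scenario_scales[[s]]
      mult <- 1 + sc * (default_level_multipliers() - 1)
      scen_cfg <- city_config(
        n_taz = cfg$n_taz, total_population = cfg$total_population,
        n_service_taz = cfg$n_service_taz, n_services = cfg$n_services,
        level_multipliers = mult, seed = cfg$seed)
      scen_city <- city
      scen_city$config <- scen_cfg
      hourly <- generate_hourly_travel(scen_city, dest_taz = plan$dest_taz)
      cl <- cluster_hours(hourly, K = cfg$K, seed = cfg$seed)
      sampled <- sample_travel_times(hourly, cl, plan)
      readr::write_csv(sampled,
                       file.path(out_dir, sprintf("sampled_%s.csv", s)))
      readr::write_csv(
        tibble::tibble(hour_of_week = 0:167, level = cl$level_of_hour),
        file.path(out_dir, sprintf("clustering_%s.csv", s)))
      tensor <- estimate_full_tensor(sampled, ff, K = cl$K)
      nst <- nearest_service_times(tensor, city$services)
      readr::write_csv(nst, file.path(out_dir, sprintf("nearest_%s.csv", s)))
      write_choropleth_geojson(
        city$zones, nst, level = cl$K,
        file.path(out_dir, sprintf("choropleth_%s.geojson", s)),
        threshold = cfg$threshold, bin = cfg$step)
      clusterings[[s]] <- cl; nearest[[s]] <- nst; tensors[[s]] <- tensor
      log_stage("estimate", scenario = s, K = cl$K,
                sampled_rows = nrow(sampled),
                estimated_cells = tensor$n_estimated_cells)
    }

    stage <- "access"
    peak <- clusterings[[1]]$K
    equity <- equity_table(nearest, city$zones, marg, level = peak,
                           threshold = cfg$threshold)
    readr::write_csv(equity, file.path(out_dir, "equity_table.csv"))
    curve <- opportunity_curve(nearest[[1]], city$zones, level = peak,
                               marginals = marg,
                               max_threshold = cfg$max_threshold,
                               step = cfg$step)
    readr::write_csv(curve, file.path(out_dir, "opportunity_curve.csv"))
    log_stage("access", level = peak, threshold = cfg$threshold)

    stage <- "optimize"
    solutions <- list(); gains <- NULL
    prob1 <- siting_problem(tensors[[1]], city$zones, city$services,
                            n_new = 1, level = peak,
                            threshold = cfg$threshold)
    solutions$one <- if (cfg$solver == "ga")
      solve_ga(prob1, ga_config(seed = cfg$seed)) else
        solve_exhaustive(prob1)
    if (cfg$n_new >= 2) {
      prob2 <- siting_problem(tensors[[1]], city$zones, city$services,
                              n_new = 2, level = peak,
                              threshold = cfg$threshold)
      solutions$two <- if (cfg$solver == "ga")
        solve_ga(prob2, ga_config(seed = cfg$seed)) else
          solve_exhaustive(prob2)
      gains <- predict_gains(prob1, solutions$one, marg,
                             solution2 = solutions$two)
    } else {
      gains <- predict_gains(prob1, solutions$one, marg)
    }
    best <- solutions[[length(solutions)]]
    write_solution_json(best, file.path(out_dir, "solution.json"),
                        gains = gains)
    log_stage("optimize", solver = cfg$solver,
              chosen = paste(best$taz_ids, collapse = ","),
              objective = best$objective)

    stage <- "demand"
    demand <- estimate_patients(
      c(baseline = best$baseline, with_new_sites = best$objective),
      cfg$prevalence_per_100k)
    readr::write_csv(demand, file.path(out_dir, "demand.csv"))
    log_stage("demand", prevalence_per_100k = cfg$prevalence_per_100k)

    list(city = city, clusterings = clusterings, nearest = nearest,
         equity = equity, curve = curve, solutions = solutions,
         gains = gains, demand = demand,
         paths = list.files(out_dir, full.names = TRUE))
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

#' Compare two accessibility scenarios
#'
#' Per-subgroup variation between two single-scenario equity tables of the
#' same city (later minus earlier): count difference, and percent
#' difference computed on unrounded percents then rounded to one decimal.
#'
#' @param result_a,result_b Equity tables from [equity_table()] with one
#'   scenario each, sharing the subgroup schema.
#' @return Tibble `attribute`, `category`, `total`, covered/pct columns
#'   for both scenarios, `variation_count`, `pct_variation`.
#' @export
compare_scenarios <- function(result_a, result_b) {
  key_a <- paste(result_a$attribute, result_a$category)
  key_b <- paste(result_b$attribute, result_b$category)
  if (!identical(sort(key_a), sort(key_b)) ||
      !identical(result_a$total[order(key_a)],
                 result_b$total[order(key_b)]))
    abort_config("scenario results do not share city and subgroup schema")
  ca <- grep("^covered_", names(result_a), value = TRUE)[1]
  cb <- grep("^covered_", names(result_b), value = TRUE)[1]
  b <- result_b[match(key_a, key_b), ]
  tibble::tibble(
    attribute = result_a$attribute, category = result_a$category,
    total = result_a$total,
    covered_a = result_a[[ca]], covered_b = b[[cb]],
    pct_a = pct1(result_a[[ca]], result_a$total),
    pct_b = pct1(b[[cb]], b$total),
    variation_count = b[[cb]] - result_a[[ca]],
    pct_variation = {
      v <- round_half_up(100 * b[[cb]] / b$total -
                           100 * result_a[[ca]] / result_a$total, 1)
      v[!is.finite(v)] <- NA_real_
      v
    })
}

#' Published 20-minute accessibility counts for Cali (2020)
#'
#' Reported covered/total population counts for 20-minute car accessibility
#' to haemodialysis in Cali, Colombia, for a heavy-traffic week (6-12 July
#' 2020) and a lighter week (23-29 November 2020), by sociodemographic
#' subgroup; plus the predicted citywide counts after adding one or two
#' services, and the catchment populations of the proposed new services.
#' These printed counts feed the arithmetic layer directly, bypassing any
#' simulation (count-injection mode).
#'
#' @param which One of `"accessibility"` (subgroup counts),
#'   `"predicted"` (citywide counts with 0/1/2 added services) or
#'   `"catchment"` (population within threshold of the new services).
#' @return Tibble of counts.
#' @export
reported_counts <- function(which = c("accessibility", "predicted",
                                      "catchment")) {
  which <- match.arg(which)
  f <- c(accessibility = "cali_accessibility_counts.csv",
         predicted = "cali_predicted_counts.csv",
         catchment = "cali_new_service_catchment.csv")[[which]]
  path <- system.file("extdata", f, package = "dstam", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Recompute the equity table from injected counts
#'
#' Applies the package's percentage and variation rules to a table of
#' covered/total counts (e.g. [reported_counts()]), reproducing every
#' derived column of a published subgroup accessibility table from its
#' count columns alone.
#'
#' @param counts Tibble with `attribute`, `category`, `total` and two or
#'   more `covered_*` columns.
#' @return The table with `share_of_total`, per-scenario `pct_*`,
#'   `variation_count` and `pct_variation` added (last scenario minus
#'   first).
#' @export
equity_from_counts <- function(counts) {
  cov_cols <- grep("^covered_", names(counts), value = TRUE)
  stopifnot(length(cov_cols) >= 1, all(c("total") %in% names(counts)))
  ov <- counts$total[counts$attribute == "overall"]
  total_city <- if (length(ov) >= 1) ov[1] else max(counts$total)
  out <- counts
  out$share_of_total <- pct1(out$total, total_city)
  for (cc in cov_cols)
    out[[sub("^covered_", "pct_", cc)]] <- pct1(out[[cc]], out$total)
  c1 <- cov_cols[1]; c2 <- cov_cols[length(cov_cols)]
  out$variation_count <- out[[c2]] - out[[c1]]
  v <- round_half_up(100 * out[[c2]] / out$total -
                       100 * out[[c1]] / out$total, 1)
  v[!is.finite(v)] <- NA_real_
  out$pct_variation <- v
  out
}

#' Recompute predicted siting percentages from injected counts
#'
#' From citywide covered counts at 0, 1 and 2 added services per scenario,
#' derives the percent accessible, the gain over baseline and the benefit
#' of the second service.
#'
#' @param counts Tibble with `scenario`, `n_added`, `covered`, `total`
#'   (e.g. `reported_counts("predicted")`).
#' @return Tibble with `percent`, `gain`, `benefit_of_second` added.
#' @export
predicted_from_counts <- function(counts) {
  counts |>
    dplyr::mutate(percent = pct1(.data$covered, .data$total)) |>
    dplyr::mutate(
      gain = .data$covered - .data$covered[.data$n_added == 0],
      benefit_of_second = ifelse(
        .data$n_added == 2,
        .data$covered - .data$covered[.data$n_added == 1], NA_real_),
      .by = "scenario")
}
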