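test_that("sampling-plan arithmetic matches the design identities", {
  zones <- tibble::tibble(taz_id = sprintf("Z%03d", 1:507))
  svc <- tibble::tibble(service_id = "S1", taz_id = "Z001")
  fifteen <- sprintf("Z%03d", 1:15)
  plan15 <- build_sampling_plan(zones, svc, K = 9,
                                extra_dest_taz = fifteen)
  expect_identical(plan15$sample_size, 507L * 15L * 9L)
  expect_identical(plan15$sample_size, 68445L)
  six <- tibble::tibble(service_id = paste0("S", 1:11),
                        taz_id = rep(sprintf("Z%03d", 1:6), c(4, 3, 1, 1, 1, 1)))
  expect_identical(build_sampling_plan(zones, six, K = 9)$sample_size, 27378L)
  one <- tibble::tibble(taz_id = "Z001")
  expect_identical(
    build_sampling_plan(one, svc, K = 1)$sample_size, 1L)
  expect_error(build_sampling_plan(zones, svc[0, ], K = 9), "service")
})

test_that("reduction factor reports the fold compression", {
  r <- reduction_factor(43099056, 68445)
  expect_equal(r$fold, 629.69, tolerance = 1e-4)
  expect_identical(r$fold_reported, 630)
  expect_identical(reduction_factor(10, 10)$fold_reported, 1)
  expect_identical(reduction_factor(100, 4)$fold_reported, 25)
  expect_error(reduction_factor(10, 0), "positive")
})

test_that("per-level sampling aggregates the level's hours", {
  an <- direct_analysis(small_city(seed = 13, n_taz = 10))
  expect_identical(nrow(an$sampled), an$plan$sample_size)
  # spot-check one cell against a direct mean
  cell <- an$sampled[an$sampled$origin_taz == "TAZ0003" &
                       an$sampled$dest_taz == "TAZ0007" &
                       an$sampled$level == 4, ]
  hrs <- which(an$clustering$level_of_hour == 4)
  expect_equal(cell$minutes,
               mean(an$hourly$minutes["TAZ0003", "TAZ0007", hrs]))
  # noise-free generator: sampled value is exactly multiplier x free-flow
  city0 <- manual_city(rbind(c(0, 0), c(10, 0)),
                       hour_levels = c(rep(1L, 100), rep(2L, 68)),
                       level_multipliers = c("1" = 1, "2" = 2))
  an0 <- direct_analysis(city0, K = 2)
  expect_equal(
    an0$sampled$minutes[an0$sampled$origin_taz == "TAZ0001" &
                          an0$sampled$dest_taz == "TAZ0002" &
                          an0$sampled$level == 2],
    44)
})

test_that("noise-free linear cities are recovered exactly by estimation", {
  city <- manual_city(cbind(runif(12, -8, 8), runif(12, -8, 8)),
                      hour_levels = default_hour_levels(),
                      level_multipliers = default_level_multipliers(),
                      access_minutes = 0)
  an <- direct_analysis(city, K = 9)
  ff <- free_flow_matrix(city$zones, access_minutes = 0)
  # restrict the sample to 3 destinations, then reconstruct everything
  plan <- build_sampling_plan(city$zones, city$services, K = 9,
                              extra_dest_taz = city$zones$taz_id[2:3])
  sampled <- sample_travel_times(an$hourly, an$clustering, plan)
  tensor <- estimate_full_tensor(sampled, ff, K = 9)
  m <- unname(default_level_multipliers())
  expect_equal(tensor$params$slope, m, tolerance = 1e-9)
  expect_equal(tensor$params$intercept, rep(0, 9), tolerance = 1e-7)
  off <- ff > 0
  for (l in c(1, 5, 9))
    expect_equal(tensor$minutes[, , l][off], (ff * m[l])[off],
                 tolerance = 1e-8)
  expect_identical(tensor$n_estimated_cells, 12L * 11L * 9L)
})

test_that("regression recovers noisy multipliers; extrapolation holds up", {
  city <- small_city(seed = 21, n_taz = 60, total = 2e5,
                     n_service_taz = 3, n_services = 5)
  hourly <- generate_hourly_travel(city)
  cl <- truth_clustering(city)  # score the regression, not the clustering
  plan <- build_sampling_plan(city$zones, city$services, K = 9)
  sampled <- sample_travel_times(hourly, cl, plan)
  ff <- free_flow_matrix(city$zones)
  tensor <- estimate_full_tensor(sampled, ff, K = 9)

  truth <- unname(default_level_multipliers())
  expect_true(all(abs(tensor$params$slope - truth) / truth < 0.02))
  expect_true(all(abs(tensor$params$intercept) < 1))

  # held-out error: predictions vs the direct per-level aggregation of the
  # full hourly tensor; out-of-sample RMSE within 1.5x the fit's residual
  full_plan <- build_sampling_plan(
    city$zones, city$services, K = 9,
    extra_dest_taz = city$zones$taz_id)
  full <- sample_travel_times(hourly, cl, full_plan)
  oi <- match(full$origin_taz, tensor$origin_taz)
  di <- match(full$dest_taz, tensor$dest_taz)
  in_samp <- tensor$provenance_sampled[cbind(oi, di, full$level)]
  offd <- full$origin_taz != full$dest_taz
  fit_pred <- tensor$params$intercept[full$level] +
    tensor$params$slope[full$level] * ff[cbind(oi, di)]
  resid <- fit_pred - full$minutes
  rmse_in <- sqrt(mean(resid[offd & in_samp]^2))
  rmse_out <- sqrt(mean(resid[offd & !in_samp]^2))
  expect_lt(rmse_out, 1.5 * rmse_in)
})

test_that("sampled cells survive estimation verbatim", {
  city <- small_city(seed = 14, n_taz = 15)
  hourly <- generate_hourly_travel(city)
  cl <- truth_clustering(city)
  plan <- build_sampling_plan(
    city$zones, city$services, K = 9,
    extra_dest_taz = city$zones$taz_id)
  sampled <- sample_travel_times(hourly, cl, plan)
  ff <- free_flow_matrix(city$zones)
  tensor <- estimate_full_tensor(sampled, ff, K = 9)
  oi <- match(sampled$origin_taz, tensor$origin_taz)
  di <- match(sampled$dest_taz, tensor$dest_taz)
  got <- tensor$minutes[cbind(oi, di, sampled$level)]
  keep <- sampled$origin_taz != sampled$dest_taz
  # monotone repair may touch a cell only when the sampled profile itself
  # violates monotonicity; with separated regimes that is rare
  expect_gt(mean(abs(got[keep] - sampled$minutes[keep]) < 1e-9), 0.95)
  expect_true(all(tensor$provenance_sampled[cbind(oi, di, sampled$level)]))
})

test_that("estimated tensors respect the floor and level monotonicity", {
  city <- small_city(seed = 15, n_taz = 25)
  an <- direct_analysis(city)
  ff <- free_flow_matrix(city$zones)
  plan <- build_sampling_plan(city$zones, city$services, K = 9)
  sampled <- sample_travel_times(an$hourly, an$clustering, plan)
  tensor <- estimate_full_tensor(sampled, ff, K = 9)
  off <- ff > 0
  for (l in 1:9)
    expect_true(all(tensor$minutes[, , l][off] >= ff[off] - 1e-9))
  flat <- matrix(tensor$minutes, ncol = 9)
  expect_true(all(flat[, -1] - flat[, -9] >= -1e-9))
})

test_that("degenerate free-flow samples fail loudly, naming the level", {
  sampled <- tibble::tibble(
    origin_taz = c("A", "B"), dest_taz = c("B", "A"),
    level = 1L, minutes = c(10, 10))
  ff <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(estimate_full_tensor(sampled, ff, K = 1), "level 1")
})

test_that("nearest-service times equal a brute-force minimum", {
  city <- small_city(seed = 16, n_taz = 20, n_service_taz = 3,
                     n_services = 4)
  an <- direct_analysis(city)
  nst <- nearest_service_times(an$tensor, city$services)
  expect_identical(nrow(nst), 20L * 9L)
  for (l in c(1, 9)) {
    oracle <- oracle_nearest(an$hourly, an$clustering, city$services, l)
    got <- nst$shortest_minutes[nst$level == l][
      match(city$zones$taz_id, nst$origin_taz[nst$level == l])]
    expect_equal(got, oracle, tolerance = 1e-9)
  }
  # service-hosting origins are always at 0
  hosts <- unique(city$services$taz_id)
  expect_true(all(nst$shortest_minutes[nst$origin_taz %in% hosts] == 0))
  expect_error(
    nearest_service_times(an$tensor,
                          tibble::tibble(taz_id = "nope")), "cover")
})
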