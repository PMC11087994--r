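#' Build the travel-time sampling plan
#'
#' The data-reduction design: instead of downloading times from every origin
#' to every destination for all 168 hours, times are sampled from every
#' origin TAZ to the (few) service-hosting TAZs only, once per congestion
#' level. `sample_size = |origins| x |destinations| x K`.
#'
#' @param zones Zones tibble (all TAZs are origins).
#' @param services Services tibble with a `taz_id` column.
#' @param K Number of congestion levels.
#' @param extra_dest_taz Optional additional destination TAZ ids (e.g. hosts
#'   of other service types measured in the same download).
#' @return A `sampling_plan` list: `origin_taz`, `dest_taz`, `K`,
#'   `sample_size`.
#' @export
#' @examples
#' # 507 origins x 15 destinations x 9 levels = 68,445 sampled cells
build_sampling_plan <- function(zones, services, K = 9,
                                extra_dest_taz = NULL) {
  if (is.null(services) || nrow(services) == 0)
    abort_config("at least one service is required to build a plan")
  dest <- sort(unique(c(services$taz_id, extra_dest_taz)))
  if (!all(dest %in% zones$taz_id))
    abort_config("plan destinations must be existing TAZs")
  structure(list(origin_taz = zones$taz_id, dest_taz = dest,
                 K = as.integer(K),
                 sample_size = length(zones$taz_id) * length(dest) *
                   as.integer(K)),
            class = "sampling_plan")
}

#' Fold reduction of the sampling design
#'
#' How many times fewer cells the sampling plan downloads than the full
#' hourly grid. The headline figure is reported to three significant digits
#' (e.g. 43,099,056 / 68,445 = 629.7, reported as 630).
#'
#' @param full_count Cell count of the full hourly grid.
#' @param sample_size Cell count of the sampling plan.
#' @return List with `fold` (exact ratio) and `fold_reported`.
#' @export
reduction_factor <- function(full_count, sample_size) {
  if (sample_size <= 0) abort_config("sample_size must be positive")
  fold <- full_count / sample_size
  list(fold = fold, fold_reported = signif(fold, 3))
}

#' Sample per-level travel times from the hourly tensor
#'
#' For each (origin, destination, level) cell of the plan, aggregates the
#' hourly minutes over the hours assigned to that level (mean by default,
#' median by flag). Diagonal cells stay 0. The result has exactly
#' `sample_size` rows.
#'
#' @param hourly An `hourly_travel` tensor covering the plan's destinations.
#' @param clustering A `congestion_clustering` of the same tensor.
#' @param plan A `sampling_plan`.
#' @param aggregator `"mean"` (default) or `"median"`.
#' @return Tibble `origin_taz`, `dest_taz`, `level`, `minutes`.
#' @export
sample_travel_times <- function(hourly, clustering, plan,
                                aggregator = c("mean", "median")) {
  stopifnot(inherits(hourly, "hourly_travel"),
            inherits(clustering, "congestion_clustering"),
            inherits(plan, "sampling_plan"))
  aggregator <- match.arg(aggregator)
  if (!all(plan$dest_taz %in% hourly$dest_taz))
    abort_config("plan destinations missing from the hourly tensor")
  if (plan$K != clustering$K)
    abort_config("plan and clustering disagree on K")
  di <- match(plan$dest_taz, hourly$dest_taz)
  agg <- if (aggregator == "mean") rowMeans else
    function(m) apply(m, 1, stats::median)

  out <- lapply(seq_len(plan$K), function(l) {
    hrs <- which(clustering$level_of_hour == l)
    if (length(hrs) == 0)
      abort_config(sprintf("congestion level %d holds no hours", l))
    sub <- hourly$minutes[, di, hrs, drop = FALSE]
    m <- agg(matrix(sub, nrow = length(hourly$origin_taz) * length(di)))
    tibble::tibble(
      origin_taz = rep(hourly$origin_taz, times = length(di)),
      dest_taz = rep(plan$dest_taz, each = length(hourly$origin_taz)),
      level = l, minutes = m)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$origin_taz, .data$dest_taz,
                 .data$level)
}

#' Estimate the full per-level travel-time tensor from the sample
#'
#' Reconstructs travel times from every origin to every destination TAZ per
#' congestion level. Per level, sampled off-diagonal minutes are regressed
#' on free-flow time by ordinary least squares
#' (`minutes ~ alpha_level + beta_level * free_flow`) and the fit predicts
#' every unsampled cell. Sampled cells keep their sampled values
#' (`provenance` distinguishes the two). Predictions are clamped to the
#' free-flow floor and each pair's level profile is made non-decreasing by
#' pool-adjacent-violators.
#'
#' @param sampled Long tibble from [sample_travel_times()].
#' @param free_flow Square free-flow minutes matrix with TAZ-id dimnames
#'   (0 diagonal); for generated cities this is the analytic matrix, for
#'   observational inputs the level-1 aggregated times can stand in.
#' @param K Number of congestion levels.
#' @return A `travel_tensor` list: `minutes` array `[origin, dest, level]`,
#'   logical `provenance_sampled` array, `params` tibble (`level`,
#'   `intercept`, `slope`), `origin_taz`, `dest_taz`, `free_flow`,
#'   `n_estimated_cells` (off-diagonal cell count `n(n-1)K`).
#' @export
estimate_full_tensor <- function(sampled, free_flow, K) {
  K <- as.integer(K)
  ids <- rownames(free_flow)
  if (is.null(ids) || !identical(ids, colnames(free_flow)))
    abort_config("free_flow must be a square matrix with TAZ-id dimnames")
  if (!all(sampled$origin_taz %in% ids) ||
      !all(sampled$dest_taz %in% ids))
    abort_config("sampled pairs outside the free_flow matrix")
  n <- length(ids)

  minutes <- array(NA_real_, dim = c(n, n, K),
                   dimnames = list(ids, ids, as.character(seq_len(K))))
  prov <- array(FALSE, dim = dim(minutes), dimnames = dimnames(minutes))

  oi <- match(sampled$origin_taz, ids)
  di <- match(sampled$dest_taz, ids)
  params <- vector("list", K)
  for (l in seq_len(K)) {
    sel <- sampled$level == l & oi != di
    ffs <- free_flow[cbind(oi[sel], di[sel])]
    if (length(unique(ffs)) < 2)
      abort_config(sprintf(
        "level %d: free-flow times in the sample are constant; fit is degenerate", l))
    fit <- lm(sampled$minutes[sel] ~ ffs)
    a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
    pred <- a + b * free_flow
    minutes[, , l] <- pmax(pred, free_flow)   # congestion floor
    params[[l]] <- tibble::tibble(level = l, intercept = a, slope = b)
  }
  # sampled cells are kept verbatim
  idx <- cbind(oi, di, sampled$level)
  minutes[idx] <- sampled$minutes
  prov[idx] <- TRUE
  for (l in seq_len(K)) minutes[, , l][free_flow == 0] <- 0

  # across-level monotonicity per pair (pool-adjacent-violators)
  flat <- matrix(minutes, ncol = K)
  offd <- as.vector(free_flow > 0)
  flat[offd, ] <- pava_rows(flat[offd, , drop = FALSE])
  minutes <- array(flat, dim = dim(minutes), dimnames = dimnames(minutes))

  structure(list(minutes = minutes, provenance_sampled = prov,
                 params = dplyr::bind_rows(params),
                 origin_taz = ids, dest_taz = ids, free_flow = free_flow,
                 n_estimated_cells = as.integer(n * (n - 1) * K)),
            class = "travel_tensor")
}

#' Assemble a tensor directly from sampled cells (estimation bypassed)
#'
#' When the plan's destinations already cover every TAZ of interest, no
#' regression is needed; this packs the sampled long table into the same
#' `travel_tensor` container (destinations restricted to the plan's).
#'
#' @param sampled Long tibble from [sample_travel_times()].
#' @param plan The `sampling_plan` that produced it.
#' @param K Number of levels.
#' @return A `travel_tensor` whose cells are all sampled.
#' @export
sampled_tensor <- function(sampled, plan, K = plan$K) {
  o <- plan$origin_taz; d <- plan$dest_taz
  minutes <- array(NA_real_, dim = c(length(o), length(d), K),
                   dimnames = list(o, d, as.character(seq_len(K))))
  idx <- cbind(match(sampled$origin_taz, o), match(sampled$dest_taz, d),
               sampled$level)
  minutes[idx] <- sampled$minutes
  prov <- array(TRUE, dim = dim(minutes), dimnames = dimnames(minutes))
  structure(list(minutes = minutes, provenance_sampled = prov,
                 params = NULL, origin_taz = o, dest_taz = d,
                 free_flow = NULL,
                 n_estimated_cells = 0L),
            class = "travel_tensor")
}

#' Shortest travel time to any service, per origin and level
#'
#' For every origin TAZ and congestion level, the minimum travel time over
#' all service-hosting TAZs, with the host's id. Origins hosting a service
#' get 0 at every level (within-TAZ convention). Ties go to the smallest
#' destination TAZ id.
#'
#' @param tensor A `travel_tensor` whose destinations include every
#'   service-hosting TAZ.
#' @param services Services tibble with `taz_id`.
#' @return Tibble `origin_taz`, `level`, `shortest_minutes`,
#'   `nearest_service_taz`.
#' @export
nearest_service_times <- function(tensor, services) {
  stopifnot(inherits(tensor, "travel_tensor"))
  svc <- sort(unique(services$taz_id))
  if (!all(svc %in% tensor$dest_taz))
    abort_config("tensor does not cover every service-hosting TAZ")
  K <- dim(tensor$minutes)[3]
  si <- match(svc, tensor$dest_taz)
  out <- lapply(seq_len(K), function(l) {
    m <- matrix(tensor$minutes[, si, l, drop = FALSE], ncol = length(si))
    j <- max.col(-m, ties.method = "first")
    tibble::tibble(origin_taz = tensor$origin_taz, level = l,
                   shortest_minutes = m[cbind(seq_len(nrow(m)), j)],
                   nearest_service_taz = svc[j])
  })
  dplyr::bind_rows(out)
}
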