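#' Define a maximal-covering siting problem
#'
#' Where should 1 or 2 new services go so that the population within the
#' travel-time threshold is maximised? Coverage is evaluated at one
#' congestion level (default: peak, level K) against the existing services;
#' a candidate TAZ covers every TAZ whose travel time to it is within the
#' threshold, plus itself (within-TAZ time 0). New services are open to all
#' patients; capacity is not modelled.
#'
#' The constructor precomputes the baseline covered set and the
#' candidate-incidence matrix so both solvers evaluate the same exact
#' objective cheaply.
#'
#' @param tensor Full `travel_tensor` (destinations = all TAZs).
#' @param zones Zones tibble.
#' @param services Existing services tibble.
#' @param n_new Number of new sites, 1 or 2.
#' @param level Congestion level (default `K`, peak).
#' @param threshold Threshold minutes (default 20).
#' @param candidates Candidate TAZ ids (default: all TAZs).
#' @return A `siting_problem` list.
#' @export
siting_problem <- function(tensor, zones, services, n_new,
                           level = NULL, threshold = 20,
                           candidates = NULL) {
  stopifnot(inherits(tensor, "travel_tensor"))
  if (!n_new %in% 1:2) abort_config("n_new must be 1 or 2")
  K <- dim(tensor$minutes)[3]
  level <- level %||% K
  candidates <- sort(candidates %||% zones$taz_id)
  if (length(candidates) == 0) abort_config("candidates must be nonempty")
  if (!all(candidates %in% tensor$dest_taz))
    abort_config("candidates must be tensor destinations")

  nearest <- nearest_service_times(tensor, services)
  base <- coverage(nearest, zones, level, threshold)
  oi <- match(zones$taz_id, tensor$origin_taz)
  ci <- match(candidates, tensor$dest_taz)
  # incidence: TAZ o is covered by candidate c (includes c covering itself)
  Tmat <- matrix(tensor$minutes[oi, ci, level], ncol = length(ci))
  C <- (Tmat <= threshold) | outer(zones$taz_id, candidates, "==")
  base_cov <- zones$taz_id %in% base$covered_taz

  structure(list(
    zones = zones, services = services, n_new = as.integer(n_new),
    level = level, threshold = threshold, candidates = candidates,
    nearest = nearest, baseline = base$covered_population,
    base_cov = base_cov, C = C,
    pop = zones$total_population,
    total_population = sum(zones$total_population)
  ), class = "siting_problem")
}

#' Population covered after adding new sites
#'
#' @param problem A `siting_problem`.
#' @param new_sites Character vector of `n_new` candidate TAZ ids.
#' @return Covered population (existing plus new services).
#' @export
coverage_with_sites <- function(problem, new_sites) {
  stopifnot(inherits(problem, "siting_problem"))
  j <- match(new_sites, problem$candidates)
  if (anyNA(j)) abort_config(sprintf(
    "unknown site id(s): %s",
    paste(new_sites[is.na(j)], collapse = ", ")))
  cov <- problem$base_cov |
    rowSums(problem$C[, j, drop = FALSE]) > 0
  sum(problem$pop[cov])
}

# per-candidate added population (over base) and, for pairs, the matrix of
# weighted intersections among uncovered TAZs; shared by both solvers
siting_precompute <- function(problem) {
  unc <- !problem$base_cov
  Cu <- problem$C[unc, , drop = FALSE]
  wu <- problem$pop[unc]
  s <- as.numeric(crossprod(Cu, wu))
  M <- if (problem$n_new == 2) crossprod(Cu * wu, Cu) else NULL
  list(s = s, M = M)
}

new_solution <- function(problem, ids, objective, method, log = NULL) {
  objective <- as.integer(round(objective))
  structure(list(
    taz_ids = sort(ids), objective = objective,
    baseline = problem$baseline, gain = objective - problem$baseline,
    n_new = problem$n_new, level = problem$level,
    threshold = problem$threshold, method = method,
    percent = pct1(objective, problem$total_population),
    generation_log = log
  ), class = "siting_solution")
}

#' @export
print.siting_solution <- function(x, ...) {
  cat(sprintf(
    "<siting> %s: sites {%s}, covered %s (%.1f%%), gain %s over baseline %s\n",
    x$method, paste(x$taz_ids, collapse = ", "),
    format(x$objective, big.mark = ","), x$percent,
    format(x$gain, big.mark = ","), format(x$baseline, big.mark = ",")))
  invisible(x)
}

#' Exhaustive maximal-covering solver
#'
#' Enumerates every candidate (or candidate pair) and returns the global
#' optimum. Ties are broken by the lexicographically smallest TAZ-id set.
#' Refuses instances beyond `cap` enumerations (use [solve_ga()] there);
#' a 507-zone city needs only 128,271 pairs, well within the default cap.
#'
#' @param problem A `siting_problem`.
#' @param cap Maximum number of enumerations (default 2e5).
#' @return A `siting_solution`.
#' @export
solve_exhaustive <- function(problem, cap = 2e5) {
  stopifnot(inherits(problem, "siting_problem"))
  m <- length(problem$candidates)
  n_comb <- if (problem$n_new == 1) m else choose(m, 2)
  if (n_comb > cap)
    abort_config(sprintf(
      "%s combinations exceed the cap (%g); use solve_ga()", n_comb, cap))
  pre <- siting_precompute(problem)
  if (problem$n_new == 1) {
    best <- which.max(pre$s)   # first max = smallest id (candidates sorted)
    return(new_solution(problem, problem$candidates[best],
                        problem$baseline + pre$s[best], "exhaustive"))
  }
  obj <- outer(pre$s, pre$s, "+") - pre$M
  obj[lower.tri(obj, diag = TRUE)] <- -Inf
  hit <- which(obj == max(obj), arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
  new_solution(problem, problem$candidates[hit],
               problem$baseline + obj[hit[1], hit[2]], "exhaustive")
}

#' Genetic-algorithm configuration
#'
#' @param population_size Chromosomes per generation (default 100).
#' @param generations Number of generations (default 200).
#' @param tournament_size Tournament selection size (default 3).
#' @param mutation_rate Per-gene mutation probability (default 0.1).
#' @param elitism Number of elites carried over unchanged (default 1).
#' @param seed Mandatory seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 100, generations = 200,
                      tournament_size = 3, mutation_rate = 0.1,
                      elitism = 1, seed = NULL) {
  if (is.null(seed)) abort_config("a seed is mandatory for the GA")
  if (population_size < 2 || generations < 1 || tournament_size < 1 ||
      mutation_rate < 0 || mutation_rate > 1 || elitism < 0)
    abort_config("invalid GA configuration")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 tournament_size = as.integer(tournament_size),
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Genetic-algorithm maximal-covering solver
#'
#' Heuristic solver for the same objective as [solve_exhaustive()], kept
#' for larger instances and validated against the exhaustive optimum on
#' small ones. A chromosome is a set of `n_new` distinct candidate TAZs;
#' fitness is the covered population; operators are tournament selection,
#' uniform site-swap crossover, per-gene replacement mutation and elitism.
#' For pairs, half the initial population couples the strongest single
#' sites with random partners, and the final answer receives a
#' steepest-swap local-search polish (memetic step) — complementary pairs
#' whose members are individually weak are otherwise hard to discover.
#' Deterministic given the config seed; tie-break matches the exhaustive
#' solver (lexicographically smallest id set).
#'
#' @param problem A `siting_problem`.
#' @param config A [ga_config()].
#' @return A `siting_solution` with a per-generation best-fitness log.
#' @export
solve_ga <- function(problem, config) {
  stopifnot(inherits(problem, "siting_problem"),
            inherits(config, "ga_config"))
  m <- length(problem$candidates)
  k <- problem$n_new
  if (m < k) abort_config("fewer candidates than sites to place")
  pre <- siting_precompute(problem)
  fitness <- function(chrom) {  # chrom: matrix pop_size x k of indices
    if (k == 1) problem$baseline + pre$s[chrom[, 1]]
    else problem$baseline + pre$s[chrom[, 1]] + pre$s[chrom[, 2]] -
      pre$M[chrom]
  }
  set.seed(config$seed)
  np <- config$population_size
  chrom <- t(replicate(np, sample.int(m, k)))
  if (k == 1) chrom <- matrix(chrom, ncol = 1)
  # seed half the initial population with strong single sites paired with
  # random partners: complementary pairs are otherwise hard to discover
  if (k == 2 && m > 2) {
    top <- order(pre$s, decreasing = TRUE)[seq_len(min(m, ceiling(np / 2)))]
    for (i in seq_along(top)) {
      partner <- sample.int(m, 1)
      if (partner == top[i]) partner <- if (top[i] == 1) 2L else top[i] - 1L
      chrom[i, ] <- c(top[i], partner)
    }
  }

  better <- function(ids_a, fa, ids_b, fb) {
    # is a better than b (higher fitness, ties to smaller id set)?
    if (fa != fb) return(fa > fb)
    a <- sort(ids_a); b <- sort(ids_b)
    for (i in seq_along(a)) {
      if (a[i] != b[i]) return(a[i] < b[i])
    }
    FALSE
  }

  fit <- fitness(chrom)
  i0 <- which.max(fit)
  best <- list(idx = sort(chrom[i0, ]), fit = fit[i0])
  log <- numeric(config$generations + 1)
  log[1] <- best$fit

  tournament <- function() {
    cand <- matrix(sample.int(np, np * config$tournament_size,
                              replace = TRUE), np)
    cand[cbind(seq_len(np),
               max.col(matrix(fit[cand], np), ties.method = "first"))]
  }
  repair <- function(children) {
    # resample one gene of any chromosome holding duplicate sites
    if (k == 1) return(children)
    repeat {
      dup <- children[, 1] == children[, 2]
      if (!any(dup)) return(children)
      children[dup, 2] <- sample.int(m, sum(dup), replace = TRUE)
    }
  }
  for (g in seq_len(config$generations)) {
    p1 <- chrom[tournament(), , drop = FALSE]
    p2 <- chrom[tournament(), , drop = FALSE]
    take <- matrix(runif(np * k) < 0.5, np, k)
    children <- repair(ifelse(take, p1, p2))
    mut <- matrix(runif(np * k) < config$mutation_rate, np, k)
    children[mut] <- sample.int(m, sum(mut), replace = TRUE)
    children <- repair(children)
    if (config$elitism > 0) children[1, ] <- best$idx
    chrom <- children
    fit <- fitness(chrom)
    rows <- which(fit == max(fit))
    srt <- matrix(chrom[rows, , drop = FALSE], ncol = k)
    if (k > 1) srt <- t(apply(srt, 1, sort))
    top <- do.call(order, as.data.frame(srt))[1]
    if (better(srt[top, ], max(fit), best$idx, best$fit))
      best <- list(idx = srt[top, ], fit = max(fit))
    log[g + 1] <- best$fit
  }
  # memetic polish: steepest single-site swaps until no move improves
  repeat {
    improved <- FALSE
    for (pos in seq_len(k)) {
      others <- best$idx[-pos]
      cand_fit <- problem$baseline + pre$s
      if (k == 2) {
        cand_fit <- cand_fit + pre$s[others] - pre$M[, others]
        cand_fit[others] <- -Inf   # keep sites distinct
      }
      j <- which.max(cand_fit)
      if (better(sort(c(others, j)), cand_fit[j], best$idx, best$fit)) {
        best <- list(idx = sort(c(others, j)), fit = cand_fit[j])
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  new_solution(problem, problem$candidates[best$idx], best$fit, "ga",
               log = tibble::tibble(generation = 0:config$generations,
                                    best_objective = log))
}

#' Per-subgroup accessibility gains of a siting solution
#'
#' For each sociodemographic category: covered population with the new
#' site(s) versus baseline, the gain, and percents on the category's own
#' total. When both a one-site and a two-site solution are supplied, the
#' benefit of the second service (two-site gain minus one-site gain) is
#' added.
#'
#' @param problem A `siting_problem`.
#' @param solution A `siting_solution` for this problem.
#' @param marginals Marginals tibble.
#' @param solution2 Optional two-site `siting_solution`.
#' @return Tibble with overall and per-category rows.
#' @export
predict_gains <- function(problem, solution, marginals,
                          solution2 = NULL) {
  stopifnot(inherits(solution, "siting_solution"))
  covered_set <- function(sites) {
    j <- match(sites, problem$candidates)
    problem$zones$taz_id[
      problem$base_cov | rowSums(problem$C[, j, drop = FALSE]) > 0]
  }
  per_cat <- function(taz_set) {
    cc <- marginals |>
      dplyr::filter(.data$taz_id %in% taz_set) |>
      dplyr::summarise(covered = sum(.data$count),
                       .by = c("attribute", "category"))
    cc
  }
  base_set <- problem$zones$taz_id[problem$base_cov]
  tot <- marginals |>
    dplyr::summarise(total = sum(.data$count),
                     .by = c("attribute", "category"))
  out <- tibble::tibble(attribute = "overall", category = "all",
                        total = problem$total_population) |>
    dplyr::bind_rows(tot)

  add_scenario <- function(out, taz_set, tag, overall) {
    cc <- per_cat(taz_set)
    m <- match(paste(out$attribute, out$category),
               paste(cc$attribute, cc$category))
    v <- ifelse(is.na(m), 0L, cc$covered[m])
    v[1] <- overall
    out[[paste0("covered_", tag)]] <- v
    out[[paste0("pct_", tag)]] <- pct1(v, out$total)
    out
  }
  out <- add_scenario(out, base_set, "baseline", problem$baseline)
  out <- add_scenario(out, covered_set(solution$taz_ids), "new",
                      solution$objective)
  out$gain <- out$covered_new - out$covered_baseline
  if (!is.null(solution2)) {
    out <- add_scenario(out, covered_set(solution2$taz_ids), "two",
                        solution2$objective)
    out$gain_two <- out$covered_two - out$covered_baseline
    out$benefit_of_second <- out$gain_two - out$gain
  }
  out
}
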