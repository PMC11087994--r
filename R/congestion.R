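#' Cluster hours of the week into ordered congestion levels
#'
#' Partitions the 168 hour-of-week slots into `K` congestion levels by
#' k-means on the citywide mean travel time of each hour, with clusters
#' labelled in ascending order of mean travel time so that level 1 is
#' free-flow and level `K` is peak. Because the feature is one-dimensional,
#' the k-means objective is solved exactly by dynamic programming over the
#' sorted hourly means (optimal contiguous partition), rather than by
#' random-restart Lloyd iterations — the hourly profile is heavily skewed
#' and restarts routinely stall in local optima that merge small regimes.
#' The result is fully deterministic; `seed` is accepted for interface
#' stability but does not influence it. The hourly feature is the mean over
#' all off-diagonal origin-destination pairs, matching the single citywide
#' level labels used throughout the analysis; per-TAZ deviations are the
#' business of [audit_taz_ordering()].
#'
#' A constant hourly profile collapses to a single level (with a warning
#' when `K > 1`); more clusters than distinct hourly means likewise reduces
#' `K` with a warning.
#'
#' @param hourly An `hourly_travel` tensor.
#' @param K Number of congestion levels (default 9).
#' @param seed Unused; retained so callers can treat the clusterer like any
#'   other seeded stage.
#' @return A `congestion_clustering` list: `level_of_hour` (integer 168,
#'   values 1..K), `K`, `level_mean_minutes`, `hours_per_level`.
#' @export
cluster_hours <- function(hourly, K = 9, seed = 1L) {
  stopifnot(inherits(hourly, "hourly_travel"))
  if (K < 1) abort_config("K must be >= 1")
  if (K > 168) abort_config("K cannot exceed the 168 hours of the week")

  off <- hourly$free_flow > 0
  if (!any(off)) abort_config("tensor has no off-diagonal pairs")
  city_mean <- apply(hourly$minutes, 3, function(m) mean(m[off]))

  n_distinct <- length(unique(signif(city_mean, 12)))
  K_eff <- min(K, n_distinct)
  if (K_eff < K)
    warning(sprintf(
      "only %d distinct hourly means: K collapsed from %d to %d",
      n_distinct, K, K_eff), call. = FALSE)

  if (K_eff == 1) {
    labels <- rep(1L, 168)
  } else {
    ord <- order(city_mean)
    blocks <- kmeans_1d(city_mean[ord], K_eff)
    labels <- integer(168)
    labels[ord] <- rep(seq_len(K_eff), times = blocks)
  }

  structure(list(
    level_of_hour = as.integer(labels),
    K = as.integer(K_eff),
    level_mean_minutes = as.numeric(tapply(city_mean, labels, mean)),
    hours_per_level = as.integer(table(factor(labels, seq_len(K_eff))))
  ), class = "congestion_clustering")
}

# exact 1-D k-means on sorted data: dynamic programme over contiguous
# blocks minimising within-cluster sum of squares; returns block lengths
kmeans_1d <- function(x, K) {
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  block_ss <- function(i, j) {
    # SS of x[i..j] for vector i, scalar j
    s <- cs[j] - c(0, cs)[i]
    s2 <- cs2[j] - c(0, cs2)[i]
    pmax(s2 - s^2 / (j - i + 1), 0)
  }
  D <- matrix(Inf, K, n)
  B <- matrix(1L, K, n)
  for (j in 1:n) D[1, j] <- block_ss(1L, j)
  if (K > 1) {
    for (k in 2:K) {
      for (j in k:n) {
        i <- k:j
        cand <- D[k - 1, i - 1] + block_ss(i, j)
        pick <- which.min(cand)
        D[k, j] <- cand[pick]
        B[k, j] <- i[pick]
      }
    }
  }
  # backtrack block lengths
  lens <- integer(K); j <- n
  for (k in K:1) {
    i <- if (k == 1) 1L else B[k, j]
    lens[k] <- j - i + 1L
    j <- i - 1L
  }
  lens
}

#' Share of the week spent at a congestion level
#'
#' @param clustering A `congestion_clustering`.
#' @param level Level in `1..K`.
#' @return Fraction of the 168 weekly hours assigned to `level`.
#' @export
#' @examples
#' \dontrun{hours_share(clustering, 8)  # e.g. 40/168 = 0.238}
hours_share <- function(clustering, level) {
  stopifnot(inherits(clustering, "congestion_clustering"))
  if (!level %in% seq_len(clustering$K))
    abort_config(sprintf("unknown congestion level %s", level))
  sum(clustering$level_of_hour == level) / 168
}

#' Audit per-TAZ consistency of the citywide level ordering
#'
#' The citywide levels are ordered by citywide mean travel time, but an
#' individual TAZ's own mean outgoing time per level need not respect that
#' order (local commuting patterns can swap contiguous clusters). For each
#' origin TAZ this ranks levels by the TAZ's mean outgoing time and counts
#' adjacent transpositions against the global order 1..K.
#'
#' @param hourly The `hourly_travel` tensor the clustering was computed from.
#' @param clustering A `congestion_clustering`.
#' @return An `ordering_audit` list: `per_taz` tibble (`origin_taz`,
#'   `inversions`), `n_taz_with_inversion`, `total_inversions`.
#' @export
audit_taz_ordering <- function(hourly, clustering) {
  stopifnot(inherits(hourly, "hourly_travel"),
            inherits(clustering, "congestion_clustering"))
  K <- clustering$K
  lv <- clustering$level_of_hour
  no <- length(hourly$origin_taz)
  off <- hourly$free_flow > 0

  # mean outgoing minutes per origin and level, off-diagonal pairs only
  taz_level_mean <- sapply(seq_len(K), function(l) {
    sub <- hourly$minutes[, , lv == l, drop = FALSE]
    n_h <- sum(lv == l)
    tot <- apply(sub, 1, sum)          # diagonal cells are 0, add nothing
    cnt <- rowSums(off) * n_h          # ... but are excluded from the count
    ifelse(cnt > 0, tot / cnt, NA_real_)
  })
  if (no == 1) taz_level_mean <- matrix(taz_level_mean, nrow = 1)

  inversions <- if (K < 2) rep(0L, no) else
    rowSums(taz_level_mean[, -1, drop = FALSE] <
              taz_level_mean[, -K, drop = FALSE], na.rm = TRUE)

  per_taz <- tibble::tibble(origin_taz = hourly$origin_taz,
                            inversions = as.integer(inversions))
  structure(list(per_taz = per_taz,
                 n_taz_with_inversion = sum(per_taz$inversions > 0),
                 total_inversions = sum(per_taz$inversions)),
            class = "ordering_audit")
}
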