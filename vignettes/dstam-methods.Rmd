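---
title: "Dynamic spatial-temporal accessibility to scarce urban health services: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic spatial-temporal accessibility: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dstam)
```

## The problem

Patients who need frequent, time-critical care — haemodialysis is the
archetype, with three trips a week for life — experience a city through its
traffic. A service that is 15 minutes away at 5 a.m. can be 40 minutes away
at rush hour, and the households that can least afford the trip are often
the ones living farthest from the service corridor. `dstam` measures this
*dynamic spatial-temporal accessibility*: the share of a city's population
that can reach the nearest service within a travel-time threshold, as a
function of traffic congestion, disaggregated by sociodemographic group,
and projected forward under the addition of one or two optimally sited new
services.

The unit of analysis is the traffic analysis zone (TAZ), the standard
geographic unit of transportation planning. Each TAZ has a representative
centroid, a population, and per-attribute category counts (socioeconomic
stratum 1–6 plus undetermined, ethnicity, education, literacy, sex, civil
status, age band). Travel within a TAZ is taken as negligible: within-TAZ
travel time is fixed at 0, so a TAZ hosting a service is always covered.

## The pipeline

1. **Congestion clustering** (`cluster_hours`). The 168 hour-of-week slots
   are partitioned into $K$ ordered congestion levels (default $K = 9$;
   level 1 free-flow, level 9 peak) by k-means on the citywide mean travel
   time of each hour. Because the feature is one-dimensional, the k-means
   objective is solved *exactly*: the optimal clusters of 1-D data are
   contiguous runs of the sorted values, found by dynamic programming in
   $O(168^2 K)$. We abandoned random-restart Lloyd iterations after
   observing that, on realistic skewed profiles (one level holding 40 of
   168 hours next to levels holding 7–9), ten restarts routinely returned
   local optima that merged small regimes — an error that propagates
   directly into the travel-time regression. The exact solution is
   deterministic and needs no seed. Clusters are labelled in ascending
   order of mean travel time.

2. **Sampling plan** (`build_sampling_plan`). Instead of measuring every
   origin–destination pair for every hour ($n(n-1) \times 168$ cells —
   43.1 million for 507 zones), times are sampled from every origin to the
   few service-hosting TAZs only, once per congestion level:
   $|O| \times |D| \times K$ cells. With 507 origins, 15 destination TAZs
   and 9 levels this is 68,445 — a ~630-fold reduction, which is the
   economic point of the design when travel times are bought from a
   commercial routing API.

3. **Tensor estimation** (`estimate_full_tensor`). The full per-level
   origin–destination tensor is reconstructed from the sample. Per level
   $k$ we fit ordinary least squares
   $t_{odk} \approx \alpha_k + \beta_k \cdot f_{od}$, where $f_{od}$ is
   the free-flow time, and predict every unsampled cell. Sampled cells are
   kept verbatim (a provenance flag distinguishes them). Predictions are
   clamped to the free-flow floor, and each pair's level profile is made
   non-decreasing by pool-adjacent-violators (an Rcpp kernel, since the
   repair runs over $n(n-1)$ pairs). The estimated cell count for 507
   zones is $507 \times 506 \times 9 = 2{,}308{,}878$. When travel times
   are multiplicative in congestion — the structure the generator plants —
   $\beta_k$ recovers the level-$k$ multiplier and $\alpha_k \approx 0$.

4. **Accessibility** (`coverage`, `equity_table`, `opportunity_curve`,
   `estimate_patients`). A TAZ is covered at level $\ell$ and threshold
   $\tau$ iff its shortest time to any service-hosting TAZ is $\le \tau$
   (inclusive; default $\tau = 20$ min). Coverage is whole-TAZ — no
   partial-area interpolation — because the TAZ is the unit of analysis.
   Equity tables disaggregate the covered population by category, with
   percentages on each category's own total. Patient demand applies a
   prevalence (default 128 per 100,000, the haemodialysis prevalence used
   throughout) to a covered population.

5. **Siting** (`siting_problem`, `solve_exhaustive`, `solve_ga`,
   `predict_gains`). Where should 1–2 new services go? This is the maximal
   covering location problem: choose sites maximising the population whose
   travel time to *some* service (existing or new) is within the
   threshold, evaluated by default at peak congestion. For $n_{new} \le 2$
   exhaustive enumeration is cheap ($\binom{507}{2} = 128{,}271$ pairs,
   evaluated in closed form from a precomputed candidate-incidence matrix
   and its weighted Gram matrix) and is the reference solver. A genetic
   algorithm (tournament selection, uniform site-swap crossover,
   replacement mutation, elitism; population 100, 200 generations) is kept
   for fidelity to heuristic practice and for larger $n_{new}$; it seeds
   half of its initial pair population with strong single sites and
   finishes with a steepest-swap local search, because complementary pairs
   whose members are individually weak are the one structure plain
   operators discover unreliably. Both solvers break ties by the
   lexicographically smallest TAZ-id set, so they are comparable.

## Rounding conventions

Reported percentages are rounded half away from zero to one decimal, and
between-scenario variation columns are computed on the *unrounded*
percents and then rounded — that is the only convention under which
published accessibility tables of this kind reproduce exactly from their
count columns. Patient counts round half up to whole patients. The fold
reduction of the sampling design is reported to three significant figures.

## The synthetic-city generator

No census, service-registry or routing-API data ships with the package;
`generate_city` and `generate_hourly_travel` build seeded synthetic cities
with the statistical structure the analysis assumes:

* **Geometry.** Centroids uniform on a planar disc (km; no geodesy —
  synthetic cities need no projection), default radius 9 km. With the
  default 30 km/h free-flow speed and 2-min access constant, this puts
  nearly all of the population inside the 20-min *free-flow* isochrone of
  the central service cluster — the situational pattern that motivates the
  analysis, where free-flow accessibility is near-universal and congestion
  is what removes it. TAZ polygons are square rings around centroids.
* **Population.** Default total 2,258,823 in 507 TAZs, allocated with a
  periphery-increasing density and lognormal heterogeneity, by largest
  remainder so the total is exact.
* **Marginals.** Within each TAZ, every attribute's category counts are
  allocated by largest remainder, so they sum exactly to the TAZ
  population (the conservation property the equity layer relies on).
  Stratum shares follow a centre-to-periphery gradient: the low-stratum
  (1–2) share rises with distance from the service cluster while the
  population-weighted city aggregate stays at the configured ~49/41/9
  low/middle/high mix. Age bands are disjoint (0–14, 15–24, 25–59, 60+).
* **Services.** Default 11 services concentrated in the 6 most central
  TAZs, one host holding 4 and another 3 — services for rare conditions
  cluster in historic medical corridors.
* **Travel times.** Free-flow time is centroid distance over speed plus
  the access constant. Hour-of-week $h$ multiplies it by the multiplier of
  its planted congestion regime and by lognormal noise
  (sd 0.05 on the log scale), clamped to the free-flow floor. The default
  weekly profile has 9 regimes, with weekday rush at the top regime and 40
  of 168 hours in the second-highest — a city that stays congested through
  the day. The planted regime labels and multipliers are carried in the
  output so clustering and estimation can be scored for recovery.

Two generator defaults deserve justification:

* **Lowest regime multiplier 1.05, not 1.00.** With multiplicative noise
  clamped at the free-flow floor, a multiplier of exactly 1 censors half
  the noise distribution and biases the level-1 mean upward by
  $E[\max(1, \varepsilon)] - 1 \approx 2\%$ at sd 0.05 — enough to corrupt
  multiplier recovery. At 1.05 the floor essentially never binds (bias
  < 0.6%), and the value is physically sensible: overnight urban driving
  still pays signal and intersection delay above pure free flow.
* **Within-TAZ time 0.** Populations in service-hosting TAZs are always
  covered; this is the whole-TAZ convention, applied consistently in
  coverage and in the siting objective (a new site covers its own TAZ).

### What the generator does *not* emulate

Real road networks (times are Euclidean-distance based, so no barriers,
bridges or one-way asymmetries), directional rush-hour asymmetry,
day-of-week demand shifts beyond the hour index, household-level
microdata, service capacity, or insurance-network restrictions on which
provider a patient may use. Peak-level synthetic coverage is lower than in
a real corridor city, because all services sit in one compact central
cluster and the peak multiplier applies uniformly to every pair.
Consequently, passing tests demonstrate that the *method* recovers planted
structure and satisfies its invariants — not that any synthetic city
reproduces a particular real city's accessibility figures. City-scale
published figures are checked through the count-injection mode instead
(`reported_counts`, `equity_from_counts`, `predicted_from_counts`), which
feeds published covered/total counts for Cali, Colombia (July and November
2020) directly into the arithmetic layer.

## Numerical and design choices

* **Inclusive threshold** ($\le$): "within 20 minutes" counts the
  boundary; fixing this is necessary for reproducibility.
* **Level aggregator**: the mean over a level's hours (median available);
  with 7–40 hours per level the mean is stable and keeps the regression
  unbiased under multiplicative noise.
* **Free-flow matrix for estimation**: the analytic matrix for generated
  cities; for observational inputs the level-1 aggregate can stand in,
  at the cost of folding the lowest regime's multiplier into the slopes.
* **Degenerate inputs**: a constant hourly profile collapses clustering to
  one level with a warning; a level whose sampled free-flow times are
  constant makes the fit degenerate and errors, naming the level; empty
  categories yield `NA` percents with a warning rather than silent zeros.
* **Monotone repair**: across-level PAVA guarantees coverage is
  anti-monotone in congestion level, which downstream comparisons assume.
* **Exhaustive-first siting**: the enumeration cap (2e5) comfortably
  admits one- and two-site problems at 507 zones, so the GA is a validated
  alternative, not a necessity.
* **Two-site search is joint**, not sequential; `predict_gains` reports
  the benefit of the second service by differencing the two solutions.

## Problem sizes used in the test suite

Unit tests run on 10–100-TAZ cities. The deeper validation harnesses use:
100 seeded 50-TAZ instances for GA-vs-exhaustive equivalence (both
$n_{new} = 1$ and $2$); a full 507-TAZ city with the 15-destination,
9-level sampling plan (68,445 cells) for multiplier recovery at noise
sd 0.05; and 5 seeded 100-TAZ cities for cross-scenario siting stability.
These sizes keep the default suite around two minutes on one CPU while
exercising the full-scale (507-zone) arithmetic identities exactly.

## Known limitations

* Travel-time estimation is a two-parameter linear model per level; real
  congestion is corridor-specific, and the per-TAZ ordering audit
  (`audit_taz_ordering`) exists precisely to surface zones whose local
  level ordering deviates from the citywide one.
* Cross-scenario stability of optimal sites is a tendency, not a theorem:
  a city with two comparably dense uncovered areas can flip its optimum
  between congestion scenarios. The test suite asserts stability as a
  majority property across seeds.
* The siting objective is uncapacitated; chair counts are carried as
  information only. Adding capacity would change the problem class
  (maximal covering to capacitated location) and is out of scope.
* Percentage conventions are fixed to reproduce published tables; if a
  different rounding rule is needed, recompute from the count columns,
  which every output table carries.
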