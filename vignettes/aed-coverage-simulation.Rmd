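---
title: "Simulating public-access defibrillator coverage against ambulance response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating public-access defibrillator coverage against ambulance response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aedcover)
```

## The question

Survival after out-of-hospital cardiac arrest (OHCA) falls steeply with
every minute before defibrillation, so a natural planning question is
whether strategically sited public automated external defibrillators
(AEDs) can put a defibrillator at the victim's side faster than an
ambulance can arrive. `aedcover` frames that question as a paired spatial
simulation on an urban street network:

* **Ambulance arm.** For each simulated OHCA location, the one-way
  vehicular travel time from the (nearest) ambulance station to the scene.
* **Bystander arm.** For the same location, the time for a second
  bystander to walk to the nearest AED and back while CPR continues — the
  round trip to the nearest of the AED sites selected by a facility-location
  model.

A demand point counts as *covered* when its response time fits a service
standard of 300 s, read inclusively (exactly 300 s is covered). The 300 s
budget corresponds to 2.5 min per walking stretch of the round trip; we
apply it to the round-trip total, which coincides with the per-stretch
reading because walking traversal is symmetric, and generalizes better if
asymmetric modes are ever added.

## The model, piece by piece

### Travel times

A `road_network` is a planar graph in projected meters. Each edge carries
a length, a one-way flag, and optional per-mode speed overrides. Travel
time on an edge is `length / speed` — constant speed per edge, no turn
penalties, signals or congestion, which mirrors the deliberate simplicity
of fixed-speed planning models (an ambulance "average urban speed" rather
than a traffic simulation). Mode semantics are the substantive rule:
pedestrians traverse every edge in both directions, while `car`,
`bicycle` and `ambulance` must respect one-way flags. Default speeds are
10 km/h for the bystander (a standardized brisk pace between walking and
running), 50 km/h for the ambulance (typical urban average), with
bicycle 15 km/h and car 40 km/h as plausible urban values for the modes
the study design leaves unstated; all are configurable per
`travel_mode()` and per edge.

Shortest-path times are computed by Dijkstra's algorithm on the directed
mode graph (via igraph). The test suite checks the full travel-time
matrix against an independently written Floyd–Warshall oracle on
hundreds of random graphs, exactly.

Points are snapped to the *nearest node* rather than the nearest point on
an edge: simpler, deterministic (ties break to the lowest node id), and
exactly testable. On the synthetic scenes below, blocks are at most
200 m, so snapping displaces a point by at most half a block diagonal
(~141 m), i.e. at most ~51 s of walking — bounded and the same for both
arms, since both use the same snapped location.

### The synthetic city

The study area this package emulates is a planned city with a regular
central grid; its real road network, candidate registry and random seeds
are not published, so every scene here is synthetic and generated by
code. `generate_grid_city()` builds a `rows × cols` lattice with block
length `block_m`, small uniform node jitter (so no two scenes are
metrically identical), and a seeded fraction of one-way segments whose
directions alternate along parallel streets — the classic center-city
pattern, which avoids vehicular traps. Strong connectivity under
vehicular rules is verified after generation and the one-way draw is
repeated under a perturbed seed in the rare case it fails.

Demand is sampled uniformly in continuous space over a concentric
central sub-rectangle (`center_fraction` of the bounding box),
reproducing the "random points plotted over the city center" design
rather than network-constrained sampling. Candidate AED sites are a
seeded sample of distinct nodes (an establishment at a street corner);
the ambulance station sits at a configurable position.

The shipped replication scene (`inst/extdata/replication.yaml`) uses a
24 × 24 lattice of 200 m blocks (~4.6 km square), 10 m jitter, 30%
one-way segments, 50 demand points over the central 60%, 80 candidate
sites, and a **corner** station. Geometry rationale: with the station at
the corner and demand in the center, station-to-scene distances are a
few kilometers, so one-way ambulance times straddle the 300 s standard —
the regime where siting AEDs can actually change coverage — while 80
scattered candidates give the optimizer real choices within the ~417 m
walking reach (150 s at 10 km/h) of central demand. These are the
package's own choices where the study design is silent; the stated study
parameters (50 demand points, one station, 300 s, 10 and 50 km/h, 18 AED
sites) are taken as given.

What the generator does **not** emulate: population-density weighting of
demand, land use (candidates are geometrically random, not "pharmacies
and schools"), opening hours, traffic variation, and dispatch/on-scene
intervals in the ambulance arm. Passing tests therefore demonstrate the
*method's* correctness and the qualitative geometry of the comparison,
not a calibrated forecast for any real city.

### AED siting: the maximal covering location problem

With binary coverage `a[i, j]` (candidate `j` within the round-trip
budget of demand `i`), weights `w_i` (all 1 by default — each simulated
occurrence counts equally) and a budget of `p` facilities, the MCLP
maximizes covered weight subject to `sum(x_j) <= p`. Two solvers:

* `solve_mclp_greedy()` — the standard submodular greedy, lowest-index
  tie-breaks, stops early when nothing is gained (so it may open fewer
  than `p` sites; `sum(x_j) <= p`, not `= p`). It carries the classical
  `1 − 1/e` approximation guarantee, asserted against the exact solver
  across the random test suite.
* `solve_mclp_exact()` — bounded enumeration of all subsets of size
  `1..p`, refusing instances beyond `max_combinations` (default 1e6);
  among optima it returns the lexicographically smallest site set, so
  results are fully deterministic. No commercial ILP solver is required
  anywhere.

`min_facilities_for_target()` inverts the question — the smallest budget
reaching a coverage target — because a printed result like "18 sites"
can be read either as a budget imposed a priori or as the minimal budget
for the achieved coverage; the replication config uses `fixed_p` with
`p = 18` and this wrapper covers the other reading.

### Statistics

`wilcoxon_signed_rank()` implements the paired signed-rank test because
both arms are computed on the *same* demand points: differences
`d = ambulance − bystander`, zeros dropped (Wilcoxon's convention;
Pratt's available), midranks for ties. The exact two-sided p-value is
obtained from the permutation null over all `2^n` sign assignments,
evaluated by dynamic programming over subset sums of ranks, whenever the
effective sample is tie-free and `n ≤ exact_limit` (default 25);
otherwise the tie-corrected normal approximation is used, and the
standardized `z` is reported in both regimes because applied papers
print `z`. The continuity correction defaults to off (conventions differ
across packages); the exact-vs-approximation agreement test enables it,
as is standard when the normal curve approximates a lattice
distribution. Exactness is verified against brute-force sign enumeration
and base R's signed-rank distribution, and the exact test's Type-I rate
under a simulated paired null (n = 50, 2000 replicates) is checked to
sit in [0.04, 0.06] at the 5% level.

`shapiro_wilk()` is the normality gatekeeper the study design runs
before choosing the nonparametric comparison; it delegates to R's
implementation of Royston's approximation (AS R94), with explicit
preconditions (3 ≤ n ≤ 5000, non-constant).

`summarize_times()` reports mean, median, sd and a CI of the mean by
Student-t (default) or seeded percentile bootstrap. Both are exposed
because printed CIs in applied reports are often produced by unstated
methods; we deliberately do not reverse-engineer any particular one.

`cronbach_alpha()` computes scale reliability
`k/(k−1) · (1 − Σ item variances / variance of total scores)` with
sample (n−1) variances, for the usability-survey side of such studies. A
30 × 16 synthetic response matrix
(`inst/extdata/synthetic_csuq_responses.csv`) ships for worked examples:
a one-factor Likert simulation whose loadings were chosen a priori for
an inter-item correlation of ~0.42, i.e. expected alpha ≈ 0.92 for 16
items by Spearman–Brown; it is a synthetic stand-in, not survey data.

### The pipeline

`run_experiment()` chains the stages — city, demand, station,
candidates, ambulance times, coverage matrix, MCLP, bystander times,
Shapiro–Wilk per arm, Wilcoxon — with both arms evaluated on the
identical demand set in identical order (the pairing is asserted in
tests and preserved in every export). A master seed derives per-stage
seeds, so a config + seed pair determines every artifact byte for byte;
each written file carries the seed and a config fingerprint. Stage
errors abort with the stage name. `export_violin_data()` emits the
long-format CSV from which a violin plot of the two arms can be drawn
with any plotting tool (plot rendering is out of scope here).

```{r}
report <- run_experiment(replication_config(seed = 1))
report
```

Across seeds, the qualitative finding is stable: bystander round trips
to MCLP-sited AEDs have a lower median than ambulance travel, cover at
least as many points within 300 s, and the paired test is significant —
the acceptance suite asserts this in at least 9 of 10 fixed seeds.

## Numerical choices and degenerate inputs

* Unreachability is `+Inf`, never a sentinel; counts and summaries treat
  it explicitly (non-finite pairs are excluded from the paired test with
  an explicit count in the report).
* The coverage boundary is inclusive (`<= threshold`), pinned by a test
  whose edge length is chosen so the one-way walk time is *exactly*
  150 s in floating point.
* All tie-breaks are deterministic: snapping to the lowest node id,
  greedy to the lowest candidate index, exact MCLP to the
  lexicographically smallest site set.
* Degenerate cases error loudly: empty networks ("no nodes to snap to"),
  all-zero paired differences (degenerate test, p = 1, flagged),
  constant samples for Shapiro–Wilk, zero total-score variance for
  alpha.
* Problem sizes in the shipped tests (grids up to 24 × 24, 100-graph
  routing oracle sweeps at ≤ 50 nodes, 2000-replicate calibration at
  n = 50, exact MCLP at ≤ 12 candidates) were chosen so the whole suite
  and the end-to-end script each run in well under a minute on a single
  core while still exercising every contract.

## Known limitations

Ambulance times exclude call handling, chute and on-scene intervals, and
assume a single fixed station; bystander times assume an instantly
available, functional AED and a bystander who knows where it is (the
app-guided scenario). Demand is unweighted and uniform over the center.
Snapping error, while bounded, slightly discretizes both arms. None of
these affect the package's comparisons between arms *within* a scene,
but absolute coverage numbers should not be read as predictions for a
real city.
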