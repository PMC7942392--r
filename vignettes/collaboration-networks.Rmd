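---
title: "Modelling HCW collaboration networks and staffing intensity from EHR audit logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling HCW collaboration networks and staffing intensity from EHR audit logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carenet)
library(dplyr)
```

## The problem

Intensive-care teams are large, multidisciplinary, and loosely documented:
no staffing roster records who actually collaborated on a patient. EHR
audit logs do. Every action a health care worker (HCW) performs on a
patient's record — assigning a diagnosis, prescribing, writing a note,
ordering a test, charting a measurement, documenting a procedure — leaves a
time-stamped row. carenet turns those rows into:

1. **Collaboration networks**: two HCWs are connected when they act on the
   same patient's record on the same calendar day; the edge weight counts
   such co-access units.
2. **Sociometrics**: eigenvector centrality ("core status": being densely
   connected to other densely connected staff) and betweenness centrality
   ("bridge status": lying on shortest paths between staff who are not
   directly connected).
3. **Daily patient staffing intensity**: for stay $s_i$ and expertise
   category $exp_k$,
   $$I_{i,k} = \frac{\sum_{j=1}^{l_i} N_{s_i,j,exp_k}}{los_i},$$
   where $N_{s_i,j,exp_k}$ is the number of distinct HCWs of that expertise
   acting on day $j$, $l_i$ the number of calendar days the stay touches,
   and $los_i$ the *fractional* length of stay (hours between admission and
   discharge divided by 24).
4. **Two-arm inference**: two-sided Mann–Whitney U tests between a covid
   and a non-covid cohort, assembled into Bonferroni-corrected families.

Because real audit logs are restricted, the package ships a seeded
synthetic generator with planted team structure, so every stage is testable
without a data download.

## Domain conventions and their rationale

**Calendar-day binning.** Collaboration is resolved at day granularity: a
1-day window is the established choice for capturing meaningful
collaborative relationships in audit-log research. We truncate local
timestamps to their calendar date — no rolling 24-hour windows, no timezone
arithmetic (inputs are assumed single-site local clock time). The
alternative rolling-window reading is conceivable but uncommon; calendar
binning is deterministic and matches how audit-log days are usually
reported. `day_bin()` is the single point where the convention lives.

**$l_i$ versus $los_i$.** The day count and the fractional length of stay
genuinely differ: a stay admitted at 06:00 and discharged at 18:00 the next
day lasts 1.5 days but touches 2 calendar days; a 1.5-day stay crossing two
midnights touches 3. The intensity denominator is deliberately the
fractional $los_i$, not $l_i$, so intensities can slightly exceed the plain
per-day average — `mean_daily_intensity(c(2, 1), 1.5)` is exactly `2`, not
`1.5`. Both quantities are materialized on every stay.

**Edge weights count (patient, day) pairs.** When two HCWs co-manage two
patients on one day, the default `edge_unit = "patient-day"` counts two
units of collaboration; `edge_unit = "day"` collapses them to one. The
phrase "number of days two HCWs performed actions on the records of the
same patients" is ambiguous between the two; patient-day counting preserves
per-patient collaboration intensity, and both conventions are implemented
and tested so the choice is auditable.

**Active nodes only.** Network nodes are HCWs with at least one event on
the arm's stays; rostered but inactive staff are not isolated vertices.
Per-arm HCW counts in the roster summaries are therefore activity-based.

**Out-of-window events.** Real audit logs contain pre-admission orders and
post-discharge documentation. The validator retains such events and flags
them (`in_window = FALSE`) with a warning; `strict = TRUE` drops them.
Flag-don't-drop preserves auditability. Duplicate events are retained
everywhere: all day-level computations are distinct-count based and hence
duplicate-insensitive by construction.

**Zero intensities are data.** An expertise category active anywhere in an
arm receives an explicit intensity of 0 on stays it never touched. The
group comparisons need those zeros in-sample (zero medians are a meaningful
outcome), not missing values.

## Sociometrics: numerical choices

**Eigencentrality** is the dominant eigenvector of the weighted adjacency
matrix, computed by power iteration from the uniform start vector and
rescaled so the maximum entry is exactly 1. Two details matter:

- *Shift.* Bipartite-like graphs (a star, for instance) have $\pm\lambda$
  extreme eigenvalue pairs, and plain power iteration oscillates with
  period 2. We iterate on $A + \sigma I$ with $\sigma$ equal to half the
  maximum node strength: the eigenvectors are unchanged, the oscillation
  disappears, and because $\sigma$ scales with the weights, multiplying all
  edge weights by a constant reproduces bit-identical scores.
- *Convergence.* Iterates are max-normalized; convergence is declared when
  successive iterates differ by less than `tol` (default `1e-10`) in max
  norm, and exceeding `max_iter` raises an error reporting the residual
  rather than returning a half-converged vector.

On a connected graph all scores are strictly positive (Perron–Frobenius —
asserted by a property test). On a disconnected graph the scores
concentrate on the component with the largest eigenvalue and other
components come out near zero; a message reports the component count. A
per-component analysis can be had by building per-component networks, but
the whole-graph behaviour is the default because the arm-level network is
the unit of analysis.

**Betweenness** uses Brandes' algorithm over *unweighted* (hop-count)
shortest paths, with fractional credit among multiple shortest paths and
pair-count normalization by $(n-1)(n-2)/2$; fewer than 3 nodes gives zeros.
The edge weights here are collaboration frequencies — similarities, not
distances — and no weight-to-distance transform is part of the model, so
hops are the honest default. `distance = "inverse_weight"` provides the
usual $1/w$ Dijkstra variant as a sensitivity analysis.

Both metrics carry their convention in the `normalization` attribute of the
returned `node_scores`, because centrality conventions differ across tools
and unlabelled scores are uninterpretable.

**Oracles.** The implementations are validated against independent
small-graph oracles that share no code with them:
`brute_force_betweenness()` enumerates all simple paths per pair (pruned at
the current best length, capped at 12 nodes), and
`dense_eigencentrality()` takes the dominant eigenvector from a full
symmetric eigen-decomposition (capped at 50 nodes). The test suite sweeps
hundreds of seeded random graphs through both pairs, and additionally
cross-checks Brandes against igraph.

## The Mann–Whitney layer

`mann_whitney_u()` computes U by rank sums with midranks. With both samples
of size at most 8 and no ties, the two-sided p value is exact by full
enumeration of the $\binom{n_x+n_y}{n_x}$ rank arrangements (cheap: at most
12,870); otherwise the normal approximation with tie correction and
continuity correction is used. The switchover size is an argument, not a
constant. Two boundary rules are explicit: completely identical samples are
*degenerate* (p = 1, direction 0, flagged, no error), and every test is
two-sided with a reported direction — planted or real effects can favour
either arm (residents higher in non-covid care, NPs higher in covid care),
so a one-sided covid-favouring test would be wrong for half the table.

Families mirror the analyses they support and are Bonferroni-corrected
per family, not globally:

- *Centrality by expertise*: one test per expertise with at least 8 HCWs in
  both arms (the network-level test over all scores stands alone at
  unadjusted $\alpha = 0.05$); with 12 surviving categories the threshold
  is $0.05/12 \approx 0.0042$.
- *Staffing intensity*: the union of each arm's top-20 categories by mean
  intensity; a union of 24 gives the familiar $0.05/24 \approx 0.002$
  threshold. With fewer than 20 categories available (as in the default
  simulation), the family is all categories and a warning says so.
- *Overall activity*: per-stay action count, expertise count, and distinct
  HCW count, a 3-test family at $0.05/3$.

Whether published "mean (SD)" columns in this literature are SDs or SEs is
not always decidable; the result rows therefore carry both, labelled
unambiguously (`sd_*`, `se_*`).

## Cohort matching

The study-design stage is reproduced as: one index stay per patient
(uniform under a seed), a logistic propensity model of arm membership on
age, sex, and fractional length of stay, and greedy 1:1 nearest-neighbour
matching without replacement on the logit of the score, processing covid
stays in seeded random order. The literature this follows names
propensity-score matching but not the algorithm; greedy nearest-neighbour
is standard, reproducible, and adequate at $n = 38$ per arm. Exact sex
matching is on by default — an inference from identical per-arm sex margins
in the motivating design (15 F / 23 M), exposed as a toggle. No caliper is
applied by default; when one is given, covid stays without candidates
inside it are reported unmatched rather than erroring. The
quantile-quantile correlation between the matched arms' sorted score
vectors (`score_correlation()`, with a within-pair option) summarizes
balance; complete separation aborts with advice to fall back to exact
matching.

## What the generator emulates — and what it does not

`simulation_scenario()` fixes the study conditions:

| Parameter | Default | Why |
|---|---|---|
| stays per arm | 38 | the matched two-arm ICU cohort size the analysis is designed around |
| length of stay | lognormal, median 13.5 d, sdlog 0.6 | median 13.5 with SD ≈ 10 d, matching the cohort it emulates |
| age | Normal(54, 12), truncated 18–95 | median 54, SD 12–14 |
| P(male) | 23/38 | the cohort's sex ratio |
| roster | 11 expertise categories | the union-of-top-10 expertise mix of a COVID-era medical ICU |
| events per active HCW-day | mean 4, min 1 | day-resolution analysis; within-day detail is irrelevant |

Counts of active HCWs per (stay, day, expertise) are Poisson with the
arm's effective participation rate, truncated at the pool size — the
simplest count model with a single rate parameter matching the intensity
statistic's object of inference. Which pool members act is driven by
patient-affinity weights drawn once per HCW from a Dirichlet whose
concentration encodes the archetype: *core* staff (concentration 0.1)
repeat near-daily on a small patient set, *bridge* staff (25) spread across
many patients, *peripheral* staff (1) are in between but sparse through low
rates, and *trainees* behave like core staff and vanish when their pool is
zeroed. This reproduces the core-versus-bridge
eigencentrality/betweenness contrast structurally, without hand-placing
edges. Non-covid stays are covariate twins of covid stays (same sex, age
±2 y, length of stay ±8% on the log scale), so the matching stage has
signal to recover. Timestamps are uniform within each patient-day, clipped
to the stay window.

`planted_scenario()` adds the two structural effects the acceptance
simulations rely on: a 3× participation multiplier for internal-medicine
nurse practitioners in the covid arm, and removal of trainees (residents)
from the covid arm. `null_scenario()` makes the arms exchangeable —
multipliers cleared, rates averaged, pools equalized — and is idempotent.

The generator does **not** model comorbidity-driven staffing, shift
schedules, within-day ordering of care, multi-site department taxonomies,
or temporal drift in team composition. Passing tests on synthetic data
therefore demonstrate that the *pipeline* recovers structure it is supposed
to recover and controls error when there is nothing to find; they do not
certify any property of a particular hospital's data.

## Problem sizes used by the test and acceptance runs

The validation suite works at sizes chosen to exercise every code path
while remaining desk-runnable: oracle sweeps over 200 random graphs (4–10
nodes for path enumeration, up to 50 for the dense eigen-oracle), 500
random tied samples against the reference Mann–Whitney implementation,
200 simulation replicates for planted-effect power, 500 replicates for the
null family-wise error rate (bounded at 0.07 = α plus Monte-Carlo margin),
and 20 seeds for structural recovery. Event volumes per simulated cohort
(≈ 35–40k actions over 76 stays) are of the order of one-thirtieth of a
real two-cohort ICU audit extract; all statistics scale linearly in events,
so nothing qualitative changes at full volume.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- run_config(
  scenario = planted_scenario(),
  out_dir = "carenet_demo",
  seed = 42
)
bundle <- run_pipeline(cfg)
bundle
glance(bundle$pairs) # pairs + score correlation
tidy(bundle$comparisons$intensity) |>
  filter(significant)
```

The bundle directory contains the three canonical CSVs, `pairs.csv` and
`matching.json`, per-arm GraphML/GEXF/edge-list exports, per-arm centrality
and intensity tables, the four comparison families as CSV + JSON twins, a
`report.json` of roster summaries and medians, and a `manifest.json`
hashing every artifact. Re-running with the same config and seed reproduces
the bundle byte for byte.

## Known limitations

- Single-site local time is assumed; logs spanning timezone changes need
  pre-normalization.
- The co-access assumption identifies collaboration with record co-use;
  spurious connections (e.g. unrelated same-day chart access) are not
  filtered.
- Betweenness on the hop convention treats a weight-1 and a weight-50 tie
  identically; use the inverse-weight mode to probe sensitivity.
- The greedy matcher does not optimize total distance (no Hungarian
  assignment); at two-digit cohort sizes the difference is immaterial.
- Exact Mann–Whitney enumeration is only engaged for tie-free samples of
  size ≤ 8; centrality scores and intensities are continuous enough that
  ties essentially only arise from structural zeros, which route to the
  tie-corrected approximation.
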