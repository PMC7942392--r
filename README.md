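# carenet

Collaboration networks and staffing intensity from EHR audit logs.

Who actually works together on a critically ill patient is poorly captured
by rosters and staffing plans, but it is captured — implicitly — by the
hospital EHR's audit log: every diagnosis assignment, prescription, note,
order, measurement, and procedure leaves a row saying which health care
worker (HCW) touched which patient's record, when. carenet is an R package
for health-services researchers who want to turn those rows into
quantitative statements about team structure, and to compare two matched
cohorts of stays (a `covid` and a `non_covid` arm).

## What it computes

- **Collaboration networks.** Two HCWs are linked when they act on the same
  patient's record on the same calendar day. The edge weight counts
  distinct (patient, day) co-access units (a `"day"` convention is also
  available). Nodes carry the HCW's *expertise*, the composite
  `"specialty: type"` label (e.g. `"respiratory care: respiratory
  therapist"`).
- **Sociometrics.** Native implementations of eigenvector centrality
  (shifted power iteration on the weighted adjacency, max entry scaled
  to 1 — "core status") and betweenness centrality (Brandes' algorithm
  over hop-count shortest paths, pair-count normalized — "bridge status"),
  each validated against an independent brute-force oracle shipped in the
  package.
- **Daily patient staffing intensity.** For stay *i* and expertise *k*:
  sum over the stay's calendar days of the number of distinct HCWs of that
  expertise acting each day, divided by the *fractional* length of stay
  los_i = hours(admit → discharge)/24. The denominator is deliberately not
  the calendar-day count l_i: counts `[2, 1]` over a 1.5-day stay give
  intensity 2.0.
- **Matched two-arm inference.** One index stay per patient, logistic
  propensity scores on age/sex/length-of-stay, greedy 1:1 matching (exact
  on sex by default), then two-sided Mann–Whitney U tests assembled into
  Bonferroni-corrected families: per-expertise centrality (≥ 8 HCWs per
  arm), staffing intensity (union of each arm's top-20 categories), and
  per-stay overall activity. The U test is exact by enumeration for small
  tie-free samples and tie-/continuity-corrected otherwise.
- **Synthetic audit logs.** A seeded generator with planted team structure
  (core physicians, bridging nurse practitioners, removable trainees) so
  the whole pipeline is testable without restricted EHR data.

## A worked example

```r
library(carenet)
library(dplyr)

bundle <- run_pipeline(run_config(
  scenario = planted_scenario(), # 38+38 stays, 3x NP effect, no covid trainees
  out_dir  = tempfile("carenet_demo_"),
  seed     = 42
))

glance(bundle$pairs)
#> # A tibble: 1 × 4
#>   n_pairs n_unmatched score_correlation mean_distance
#>     <int>       <int>             <dbl>         <dbl>
#> 1      38           0             0.995       0.00171

sapply(bundle$scores, function(s) median(s$eigencentrality$score))
#>     covid non_covid
#> 0.1601398 0.1619689

tidy(bundle$comparisons$intensity) |>
  filter(significant) |>
  select(expertise, mean_a, mean_b, p_value)
#> # A tibble: 2 × 4
#>   expertise                                mean_a mean_b  p_value
#>   <chr>                                     <dbl>  <dbl>    <dbl>
#> 1 internal medicine: nurse practitioner      1.65  0.523 6.60e-14
#> 2 medicine house staff: resident physician   0     0.888 1.12e-15
```

Reading the output: the 38 matched pairs balance the arms almost perfectly
(quantile–quantile score correlation 0.995, mean logit distance 0.002),
and the intensity family recovers exactly the two planted effects at the
Bonferroni threshold (0.05/11 here, since the default roster has 11
categories): nurse practitioners staff covid stays about three times more
intensively (1.65 vs 0.52 distinct HCWs per day), and resident physicians
are absent from covid care (0 vs 0.89). The per-arm median
eigencentralities are close — the default generator plants staffing and
role-structure contrasts, not a global network-density difference. The bundle directory also holds GraphML/GEXF network exports,
per-arm centrality and intensity CSVs, JSON twins of every comparison
table, and a `manifest.json` hashing every artifact; the same config and
seed reproduce the bundle byte for byte.

Real data enter through the same door: `run_config(events_path = ...,
roster_path = ..., stays_path = ...)` with the three canonical CSVs
(`events.csv`: hcw_id, patient_id, timestamp, action_category;
`roster.csv`: hcw_id, hcw_type, specialty; `stays.csv`: patient_id, arm,
admit_ts, discharge_ts, age, sex).

## Package tour

| Area | Functions |
|---|---|
| audit-log model | `audit_log()`, `read_audit_log()`, `write_audit_log()`, `day_bin()`, `los_days()`, `stay_day_count()`, `expertise_label()` |
| simulation | `simulation_scenario()`, `planted_scenario()`, `null_scenario()`, `generate_cohort()`, `generate_audit_log()`, `simulate_audit_log()`, `read_scenario()` |
| matching | `select_index_stay()`, `fit_propensity()`, `match_cohorts()`, `score_correlation()`, `covariate_balance()` |
| networks | `build_network()`, `roster_summary()`, `top_expertise_shares()`, `write_network()`, `as_igraph()` |
| sociometrics | `eigencentrality()`, `betweenness()`, `dense_eigencentrality()`, `brute_force_betweenness()`, `node_centrality()`, `random_collab_network()` |
| intensity | `daily_expertise_counts()`, `mean_daily_intensity()`, `staffing_intensity()`, `stay_activity_summary()` |
| inference | `mann_whitney_u()`, `compare_centrality()`, `compare_intensity()`, `compare_overall()` |
| pipeline | `run_config()`, `run_pipeline()` |

Result objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_*`
ggplot2 helpers. The methods vignette
(`vignettes/collaboration-networks.Rmd`) documents the model conventions,
numerical choices, and the generator's scope.
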