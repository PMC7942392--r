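# Fixtures are built in code: a hand-enumerable micro audit log, random
# weighted graphs for the centrality property sweeps, and a scaled-down
# simulation scenario for the stochastic checks.

# Two stays (one per arm), four HCWs, hand-tallied patient-days.
tiny_log <- function() {
  roster <- tibble::tribble(
    ~hcw_id, ~hcw_type, ~specialty,
    "A", "physician", "internal medicine",
    "B", "nurse practitioner", "internal medicine",
    "C", "registered nurse", "medical intensive care unit",
    "D", "respiratory therapist", "respiratory care"
  )
  stays <- tibble::tribble(
    ~patient_id, ~arm, ~admit_ts, ~discharge_ts, ~age, ~sex,
    "P1", "covid", "2020-03-20 08:00:00", "2020-03-23 08:00:00", 60, "male",
    "P2", "covid", "2020-03-20 00:00:00", "2020-03-22 00:00:00", 55, "female",
    "P3", "non_covid", "2020-01-10 10:00:00", "2020-01-12 10:00:00", 58, "male"
  )
  events <- tibble::tribble(
    ~hcw_id, ~patient_id, ~timestamp, ~action_category,
    "A", "P1", "2020-03-20 09:00:00", "note",
    "B", "P1", "2020-03-20 10:00:00", "order",
    "A", "P1", "2020-03-21 09:30:00", "medication",
    "B", "P1", "2020-03-21 11:00:00", "note",
    "A", "P2", "2020-03-20 14:00:00", "condition",
    "C", "P2", "2020-03-20 15:00:00", "measurement",
    "C", "P2", "2020-03-21 15:00:00", "measurement",
    "D", "P3", "2020-01-10 12:00:00", "procedure",
    "A", "P3", "2020-01-10 13:00:00", "note"
  )
  audit_log(events, roster, stays)
}

# Random weighted undirected graph as a collab_network.
random_network <- function(n, p = 0.4, max_weight = 5L, seed = 1L,
                           connected = FALSE) {
  random_collab_network(n, p, max_weight, seed, connected)
}

# Named path / cycle / star / complete test graphs with unit weights.
path_network <- function(ids = c("a", "b", "c")) {
  edges <- tibble::tibble(
    hcw_a = ids[-length(ids)], hcw_b = ids[-1], weight = 1L
  )
  collab_network(ids, edges)
}

cycle_network <- function(n = 4) {
  ids <- letters[seq_len(n)]
  edges <- tibble::tibble(
    hcw_a = ids, hcw_b = ids[c(2:n, 1)], weight = 1L
  )
  collab_network(ids, edges)
}

star_network <- function(n_leaves = 3, weight = 1L) {
  ids <- c("c", sprintf("l%d", seq_len(n_leaves)))
  edges <- tibble::tibble(
    hcw_a = "c", hcw_b = ids[-1], weight = as.integer(weight)
  )
  collab_network(ids, edges)
}

complete_network <- function(n = 4, weight = 1L) {
  ids <- sprintf("k%d", seq_len(n))
  pairs <- t(combn(n, 2))
  edges <- tibble::tibble(
    hcw_a = ids[pairs[, 1]], hcw_b = ids[pairs[, 2]],
    weight = as.integer(weight)
  )
  collab_network(ids, edges)
}

# Scaled-down scenario for fast stochastic tests.
small_scenario <- function(n_stays = 8L, ...) {
  simulation_scenario(
    n_stays_per_arm = n_stays,
    los_meanlog = log(6), los_sdlog = 0.4,
    ...
  )
}

# Independent triple-scan oracle for edge weights: counts co-occurring
# (pair, patient, day) triples by explicit enumeration over all pairs.
brute_force_edges <- function(log, arm, edge_unit = "patient-day") {
  ev <- dplyr::inner_join(
    log$events,
    dplyr::filter(log$stays, arm == !!arm)[, c("patient_id", "stay_id")],
    by = "patient_id"
  )
  ev$day <- day_bin(ev$timestamp)
  hcws <- sort(unique(ev$hcw_id))
  out <- list()
  for (i in seq_along(hcws)) {
    for (j in seq_along(hcws)) {
      if (i >= j) next
      a <- ev[ev$hcw_id == hcws[i], c("patient_id", "day")]
      b <- ev[ev$hcw_id == hcws[j], c("patient_id", "day")]
      shared <- dplyr::intersect(unique(a), unique(b))
      w <- if (edge_unit == "patient-day") {
        nrow(shared)
      } else {
        length(unique(shared$day))
      }
      if (w > 0) {
        out[[length(out) + 1]] <- tibble::tibble(
          hcw_a = hcws[i], hcw_b = hcws[j], weight = as.integer(w)
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(hcw_a = character(), hcw_b = character(), weight = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), hcw_a, hcw_b)
}

expect_scores_equal <- function(a, b, tol) {
  expect_equal(a$hcw_id, b$hcw_id)
  expect_lt(max(abs(a$score - b$score)), tol)
}
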