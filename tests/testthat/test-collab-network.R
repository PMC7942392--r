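test_that("co-access day counting matches the worked example", {
  roster <- tibble::tibble(
    hcw_id = c("A", "B", "C"),
    hcw_type = "physician", specialty = "internal medicine"
  )
  stays <- tibble::tibble(
    patient_id = c("P1", "P2"), arm = "covid",
    admit_ts = "2020-03-01 00:00:00", discharge_ts = "2020-03-05 00:00:00",
    age = 50, sex = "male"
  )
  events <- tibble::tribble(
    ~hcw_id, ~patient_id, ~timestamp, ~action_category,
    "A", "P1", "2020-03-01 08:00:00", "note",
    "B", "P1", "2020-03-01 09:00:00", "note",
    "A", "P1", "2020-03-02 08:00:00", "note",
    "B", "P1", "2020-03-02 09:00:00", "note",
    "A", "P2", "2020-03-01 10:00:00", "note",
    "C", "P2", "2020-03-01 11:00:00", "note"
  )
  net <- build_network(audit_log(events, roster, stays), "covid")
  expect_identical(nrow(net$nodes), 3L)
  expect_equal(
    net$edges,
    tibble::tibble(
      hcw_a = c("A", "A"), hcw_b = c("B", "C"), weight = c(2L, 1L)
    )
  )
})

test_that("patient-day vs day edge units differ on same-day multi-patient co-access", {
  roster <- tibble::tibble(
    hcw_id = c("A", "B"), hcw_type = "physician", specialty = "im"
  )
  stays <- tibble::tibble(
    patient_id = c("P1", "P2"), arm = "covid",
    admit_ts = "2020-03-01 00:00:00", discharge_ts = "2020-03-03 00:00:00",
    age = 50, sex = "male"
  )
  # A and B both act on P1 and P2 on the same day
  events <- tidyr::expand_grid(
    hcw_id = c("A", "B"), patient_id = c("P1", "P2")
  ) |>
    dplyr::mutate(
      timestamp = "2020-03-01 10:00:00",
      action_category = "note"
    )
  log <- audit_log(events, roster, stays)
  expect_identical(build_network(log, "covid", "patient-day")$edges$weight, 2L)
  expect_identical(build_network(log, "covid", "day")$edges$weight, 1L)
})

test_that("lone actors yield nodes without edges; empty arms warn", {
  log <- tiny_log()
  net <- build_network(log, "non_covid")
  expect_identical(nrow(net$nodes), 2L) # A and D both acted on P3 day 1
  expect_identical(nrow(net$edges), 1L)

  solo <- filter_stays(log, "P2")
  # drop C so only A remains active... P2 has A once and C twice
  ev <- solo$events[solo$events$hcw_id == "A", ]
  net1 <- build_network(audit_log(ev, solo$roster, solo$stays), "covid")
  expect_identical(nrow(net1$nodes), 1L)
  expect_identical(nrow(net1$edges), 0L)

  expect_warning(
    empty <- build_network(audit_log(ev[0, ], solo$roster, solo$stays), "covid"),
    class = "carenet_empty_network_warning"
  )
  expect_identical(nrow(empty$nodes), 0L)
})

test_that("edge weights equal a brute-force triple scan on random logs", {
  for (s in 1:5) {
    sc <- small_scenario(n_stays = 4L)
    log <- simulate_audit_log(sc, seed = 100 + s)
    # shrink to <= 10 HCWs for the oracle
    keep_hcws <- head(sort(unique(log$events$hcw_id)), 10)
    ev <- log$events[log$events$hcw_id %in% keep_hcws, ]
    log2 <- audit_log(ev, log$roster, log$stays)
    for (unit in c("patient-day", "day")) {
      net <- build_network(log2, "covid", unit)
      expect_equal(net$edges, brute_force_edges(log2, "covid", unit))
    }
  }
})

test_that("networks are order-invariant and duplicate-insensitive", {
  log <- tiny_log()
  net <- build_network(log, "covid")

  shuffled <- audit_log(
    log$events[rev(seq_len(nrow(log$events))), ],
    log$roster, log$stays
  )
  expect_equal(build_network(shuffled, "covid")$edges, net$edges)

  # duplicate an event for an HCW already active on that patient-day
  dup <- audit_log(
    dplyr::bind_rows(log$events, log$events[1, ]),
    log$roster, log$stays
  )
  expect_equal(build_network(dup, "covid")$edges, net$edges)
})

test_that("roster summaries count distinct actors at network and patient level", {
  log <- tiny_log()
  rs <- roster_summary(log, "covid")
  expect_identical(rs$n_hcws, 3L) # A, B, C active in covid stays
  expect_identical(rs$n_expertise, 3L)
  # per-stay distinct HCW counts: P1 -> {A,B} = 2, P2 -> {A,C} = 2
  expect_equal(rs$per_patient_means$hcws, 2)
  expect_equal(sum(rs$expertise_shares$share), 1)

  non <- roster_summary(log, "non_covid")
  expect_identical(non$n_hcws, 2L)
  expect_equal(non$per_patient_means$hcws, 2)
})

test_that("expertise shares follow the 3-vs-1 proportion example", {
  roster <- tibble::tibble(
    hcw_id = c("A", "B", "C", "D"),
    hcw_type = c("nurse", "nurse", "nurse", "physician"),
    specialty = "icu"
  )
  stays <- tibble::tibble(
    patient_id = "P1", arm = "covid",
    admit_ts = "2020-03-01 00:00:00", discharge_ts = "2020-03-02 00:00:00",
    age = 50, sex = "male"
  )
  events <- tibble::tibble(
    hcw_id = c("A", "B", "C", "D"), patient_id = "P1",
    timestamp = "2020-03-01 08:00:00", action_category = "note"
  )
  rs <- roster_summary(audit_log(events, roster, stays), "covid")
  expect_equal(rs$expertise_shares$share, c(0.75, 0.25))
})

test_that("top expertise shares form the union of per-arm top-k lists", {
  mk_summary <- function(expertise, n, arm = "covid") {
    structure(
      list(
        arm = arm, n_hcws = sum(n), n_hcw_types = 1L, n_specialties = 1L,
        n_expertise = length(expertise),
        per_patient_means = tibble::tibble(
          hcws = 1, hcw_types = 1, specialties = 1, expertise = 1
        ),
        expertise_shares = tibble::tibble(
          expertise = expertise, n = n, share = n / sum(n)
        ) |> dplyr::arrange(dplyr::desc(share))
      ),
      class = "roster_summary"
    )
  }
  a <- mk_summary(c("e1", "e2", "e3"), c(5, 3, 2))
  b <- mk_summary(c("f1", "f2", "f3"), c(6, 3, 1), arm = "non_covid")
  # disjoint top-k sets of size k -> union of size 2k
  expect_identical(nrow(top_expertise_shares(a, b, k = 2)), 4L)
  # k beyond the category count saturates to all categories
  expect_identical(nrow(top_expertise_shares(a, b, k = 50)), 6L)
  # identical arms give identical share columns
  both <- top_expertise_shares(a, a, k = 3)
  expect_identical(both$share_a, both$share_b)
})

test_that("graphml export round-trips through igraph and gexf is well-formed", {
  net <- build_network(tiny_log(), "covid")
  gpath <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gpath, "graphml")
  g <- igraph::read_graph(gpath, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes), ignore_attr = TRUE)
  expect_equal(sort(igraph::E(g)$weight), sort(net$edges$weight))
  expect_setequal(igraph::V(g)$expertise, net$nodes$expertise)

  xpath <- withr::local_tempfile(fileext = ".gexf")
  write_network(net, xpath, "gexf")
  doc <- xml2::read_xml(xpath)
  ns <- xml2::xml_ns(doc)
  expect_identical(
    length(xml2::xml_find_all(doc, "//d1:node", ns)), nrow(net$nodes)
  )
  expect_identical(
    length(xml2::xml_find_all(doc, "//d1:edge", ns)), nrow(net$edges)
  )

  cpath <- withr::local_tempfile(fileext = ".csv")
  write_network(net, cpath, "edgelist")
  el <- readr::read_csv(cpath, show_col_types = FALSE)
  expect_named(el, c("source", "target", "weight"))
  expect_identical(nrow(el), nrow(net$edges))
})
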