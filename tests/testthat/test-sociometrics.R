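test_that("eigencentrality matches closed forms on symmetric graphs", {
  k4 <- eigencentrality(complete_network(4))
  expect_equal(k4$score, rep(1, 4), tolerance = 1e-9)

  star <- eigencentrality(star_network(3))
  centre <- star$score[star$hcw_id == "c"]
  leaves <- star$score[star$hcw_id != "c"]
  expect_equal(centre, 1, tolerance = 1e-8)
  expect_equal(leaves, rep(1 / sqrt(3), 3), tolerance = 1e-8)

  k2 <- eigencentrality(collab_network(
    c("a", "b"),
    tibble::tibble(hcw_a = "a", hcw_b = "b", weight = 1L)
  ))
  expect_equal(k2$score, c(1, 1), tolerance = 1e-9)
})

test_that("eigencentrality is exactly invariant to uniform weight scaling", {
  net <- random_network(12, seed = 5, connected = TRUE)
  doubled <- net
  doubled$edges$weight <- doubled$edges$weight * 2L
  expect_identical(eigencentrality(net)$score, eigencentrality(doubled)$score)
})

test_that("power iteration agrees with the dense eigen-decomposition oracle", {
  for (s in 1:25) {
    n <- sample(5:50, 1)
    net <- random_network(n, p = 0.4, seed = 2000 + s, connected = TRUE)
    expect_scores_equal(
      eigencentrality(net),
      dense_eigencentrality(net),
      tol = 1e-6
    )
  }
})

test_that("eigencentrality is strictly positive on connected graphs", {
  for (s in 1:10) {
    net <- random_network(sample(4:15, 1), seed = 300 + s, connected = TRUE)
    e <- eigencentrality(net)
    expect_true(all(e$score > 0))
    expect_equal(max(e$score), 1)
  }
})

test_that("disconnected graphs concentrate eigencentrality on the dominant component", {
  # strong triangle + weak disconnected pair
  edges <- tibble::tibble(
    hcw_a = c("a", "a", "b", "x"),
    hcw_b = c("b", "c", "c", "y"),
    weight = c(5L, 5L, 5L, 1L)
  )
  net <- collab_network(c("a", "b", "c", "x", "y"), edges)
  e <- suppressMessages(eigencentrality(net))
  expect_equal(max(e$score[e$hcw_id %in% c("a", "b", "c")]), 1)
  expect_lt(max(e$score[e$hcw_id %in% c("x", "y")]), 1e-6)
})

test_that("betweenness matches closed forms", {
  p3 <- betweenness(path_network(c("a", "b", "c")))
  expect_equal(p3$score[p3$hcw_id == "b"], 1)
  expect_equal(p3$score[p3$hcw_id != "b"], c(0, 0))

  for (n in c(3, 5, 7)) {
    kn <- betweenness(complete_network(n))
    expect_equal(kn$score, rep(0, n))
  }

  c4 <- betweenness(cycle_network(4))
  expect_equal(c4$score, rep(1 / 6, 4), tolerance = 1e-12)
})

test_that("betweenness (hop convention) ignores positive reweighting", {
  net <- random_network(12, seed = 9)
  rewt <- net
  rewt$edges$weight <- sample.int(9L, nrow(net$edges), replace = TRUE)
  expect_identical(betweenness(net)$score, betweenness(rewt)$score)
})

test_that("Brandes agrees with the exhaustive path-enumeration oracle", {
  for (s in 1:50) {
    n <- sample(4:10, 1)
    net <- random_network(n, p = 0.4, seed = 1000 + s)
    expect_scores_equal(
      betweenness(net),
      brute_force_betweenness(net),
      tol = 1e-9
    )
  }
})

test_that("Brandes agrees with igraph as an independent cross-check", {
  for (s in 1:10) {
    net <- random_network(sample(5:30, 1), p = 0.3, seed = 70 + s)
    ours <- betweenness(net)
    g <- as_igraph(net)
    ig <- igraph::betweenness(g, weights = NA, normalized = TRUE)
    expect_equal(ours$score, unname(ig[ours$hcw_id]), tolerance = 1e-10)
  }
})

test_that("inverse-weight betweenness matches igraph's weighted betweenness", {
  for (s in 1:5) {
    net <- random_network(sample(5:12, 1), p = 0.5, seed = 40 + s)
    ours <- betweenness(net, distance = "inverse_weight")
    g <- as_igraph(net)
    ig <- igraph::betweenness(g,
      weights = 1 / igraph::E(g)$weight, normalized = TRUE
    )
    expect_equal(ours$score, unname(ig[ours$hcw_id]), tolerance = 1e-8)
  }
})

test_that("scores are equivariant under node relabeling", {
  net <- random_network(10, seed = 33, connected = TRUE)
  perm <- withr::with_seed(1, sample(nrow(net$nodes)))
  relabel <- setNames(sprintf("z%02d", perm), net$nodes$hcw_id)
  renamed <- collab_network(
    unname(relabel[net$nodes$hcw_id]),
    tibble::tibble(
      hcw_a = unname(relabel[net$edges$hcw_a]),
      hcw_b = unname(relabel[net$edges$hcw_b]),
      weight = net$edges$weight
    )
  )
  for (fn in list(eigencentrality, betweenness)) {
    orig <- fn(net)
    new <- fn(renamed)
    expect_equal(
      new$score[match(unname(relabel[orig$hcw_id]), new$hcw_id)],
      orig$score,
      tolerance = 1e-9
    )
  }
})

test_that("size caps and empty networks raise typed errors", {
  big <- random_network(13, seed = 2)
  expect_error(brute_force_betweenness(big), class = "carenet_size_error")
  big50 <- random_network(51, p = 0.2, seed = 3)
  expect_error(dense_eigencentrality(big50), class = "carenet_size_error")
  empty <- collab_network(character(0))
  expect_error(eigencentrality(empty), class = "carenet_validation_error")
  expect_error(betweenness(empty), class = "carenet_validation_error")
  expect_error(
    eigencentrality(random_network(10, seed = 4, connected = TRUE), max_iter = 1L),
    class = "carenet_convergence_error"
  )
})

test_that("node_centrality dispatches and node_scores carry their convention", {
  net <- random_network(8, seed = 12, connected = TRUE)
  e <- node_centrality(net, "eigencentrality")
  b <- node_centrality(net, "betweenness")
  expect_identical(attr(e, "metric"), "eigencentrality")
  expect_identical(attr(e, "normalization"), "max_entry_1")
  expect_identical(attr(b, "normalization"), "pair_count_hop")
  td <- tidy(e)
  expect_named(td, c("hcw_id", "expertise", "score", "metric"))
  expect_true(all(b$score >= 0 & b$score <= 1))
})
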