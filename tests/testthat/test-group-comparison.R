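test_that("exact Mann-Whitney p matches full enumeration on the worked case", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u_statistic, 0)
  expect_equal(res$p_value, 0.1) # 2 extreme arrangements of C(6,3) = 20
  expect_identical(res$method, "exact")
  expect_identical(res$direction, -1)
})

test_that("identical samples are degenerate: p = 1, direction 0", {
  res <- mann_whitney_u(rep(2, 5), rep(2, 7))
  expect_identical(res$method, "degenerate")
  expect_equal(res$p_value, 1)
  expect_identical(res$direction, 0)
})

test_that("the approximation path matches the reference implementation on tied data", {
  withr::with_seed(99, {
    for (i in 1:100) {
      x <- sample(0:6, 15, replace = TRUE) / 2
      y <- sample(0:6, 15, replace = TRUE) / 2
      ours <- mann_whitney_u(x, y)
      if (ours$method == "degenerate") next
      ref <- suppressWarnings(
        stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
      )
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
      expect_equal(ours$u_statistic, unname(ref$statistic))
    }
  })
})

test_that("exact and approximate p agree closely at the switchover size", {
  withr::with_seed(7, {
    for (i in 1:20) {
      x <- rnorm(8)
      y <- rnorm(8, 0.5)
      exact <- mann_whitney_u(x, y)$p_value
      approx <- mann_whitney_u(x, y, exact_limit = 0L)$p_value
      expect_lt(abs(exact - approx), 0.02)
    }
  })
})

test_that("the test is symmetric under sample swap and shift-invariant", {
  withr::with_seed(31, {
    x <- rnorm(12)
    y <- rnorm(10, 1)
    ab <- mann_whitney_u(x, y)
    ba <- mann_whitney_u(y, x)
    expect_equal(ab$p_value, ba$p_value)
    expect_identical(ab$direction, -ba$direction)
    expect_equal(ab$u_statistic + ba$u_statistic, 12 * 10)

    shifted <- mann_whitney_u(x + 100, y + 100)
    expect_equal(shifted$p_value, ab$p_value)
    expect_equal(shifted$u_statistic, ab$u_statistic)
  })
})

fake_scores <- function(expertise_counts, shift = 0, seed = 1, metric = "eigencentrality") {
  withr::with_seed(seed, {
    df <- purrr::imap_dfr(expertise_counts, function(n, e) {
      tibble::tibble(
        hcw_id = sprintf("%s_%d_%d", substr(e, 1, 3), seed, seq_len(n)),
        expertise = e,
        score = pmin(1, pmax(0, rnorm(n, 0.5 + shift, 0.1)))
      )
    })
  })
  structure(df,
    class = c("node_scores", class(df)),
    metric = metric, normalization = "max_entry_1", arm = "test"
  )
}

test_that("centrality families filter on group size and Bonferroni-correct", {
  counts <- setNames(rep(10L, 12), sprintf("exp%02d", 1:12))
  small <- c(counts, small1 = 3L) # below the 8-HCW filter
  a <- fake_scores(small, shift = 0, seed = 1)
  b <- fake_scores(c(counts, only_a_missing = 9L), shift = 0, seed = 2)
  cmp <- compare_centrality(a, b, min_group = 8L)
  expect_identical(cmp$m_tests, 12L)
  expect_equal(cmp$adjusted_threshold, 0.05 / 12)
  expect_setequal(cmp$exclusions$expertise, c("small1", "only_a_missing"))
  expect_identical(cmp$network_level$scope, "network")

  idark <- fake_scores(counts, seed = 5)
  same <- compare_centrality(idark, idark)
  expect_identical(sum(tidy(same)$significant), 0L)
  expect_equal(same$network_level$p_value, 1)

  bet <- fake_scores(counts, seed = 6, metric = "betweenness")
  expect_error(compare_centrality(a, bet), class = "carenet_validation_error")
})

test_that("intensity families use the union of per-arm top-k categories", {
  # arm A tops categories c01..c20, arm B shares 16 and adds b17..b20
  mk <- function(cats, stays, base) {
    tidyr::expand_grid(stay_id = stays, expertise = cats) |>
      dplyr::mutate(mean_daily_intensity = base[match(expertise, cats)])
  }
  cats_a <- sprintf("c%02d", 1:20)
  cats_b <- c(sprintf("c%02d", 1:16), sprintf("b%02d", 17:20))
  all_cats <- union(cats_a, cats_b)
  stays_a <- sprintf("A%02d", 1:10)
  stays_b <- sprintf("B%02d", 1:10)
  ia <- mk(all_cats, stays_a, base = c(seq(24, 5, length.out = 20), rep(0.1, 4)))
  ib <- mk(all_cats, stays_b, base = c(seq(24, 9, length.out = 16), rep(0.1, 4), seq(8, 5, length.out = 4)))
  cmp <- compare_intensity(ia, ib, top_k = 20)
  expect_identical(cmp$m_tests, 24L)
  expect_equal(cmp$adjusted_threshold, 0.05 / 24)
  expect_equal(round(cmp$adjusted_threshold, 3), 0.002)
})

test_that("identical intensity tables yield no significant categories", {
  log <- simulate_audit_log(small_scenario(), seed = 41)
  i <- staffing_intensity(log, "covid")
  cmp <- suppressWarnings(compare_intensity(i, i, top_k = 20))
  expect_identical(sum(tidy(cmp)$significant), 0L)
  expect_true(all(tidy(cmp)$p_value == 1))
})

test_that("overall comparisons test the three per-stay measures", {
  withr::with_seed(13, {
    a <- tibble::tibble(
      stay_id = sprintf("a%d", 1:38),
      n_actions = rpois(38, 1100), n_expertise = rpois(38, 29),
      n_hcws = rpois(38, 80)
    )
  })
  same <- compare_overall(a, a)
  expect_identical(same$m_tests, 3L)
  expect_equal(same$adjusted_threshold, 0.05 / 3)
  expect_true(all(tidy(same)$p_value == 1))

  b <- a
  b$stay_id <- sprintf("b%d", 1:38)
  b$n_hcws <- a$n_hcws * 2L
  cmp <- compare_overall(a, b)
  res <- tidy(cmp)
  hcw_row <- res[res$measure == "n_hcws", ]
  expect_true(hcw_row$significant)
  expect_identical(hcw_row$direction, -1)
  expect_false(res$significant[res$measure == "n_actions"])
})

test_that("comparison tables expose tidy/glance and write CSV + JSON twins", {
  counts <- setNames(rep(9L, 4), sprintf("e%d", 1:4))
  cmp <- compare_centrality(
    fake_scores(counts, seed = 3),
    fake_scores(counts, shift = 0.3, seed = 4)
  )
  td <- tidy(cmp)
  expect_true(all(c("expertise", "p_value", "significant") %in% names(td)))
  gl <- glance(cmp)
  expect_identical(gl$m_tests, 4L)

  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_comparison(cmp, path)
  expect_true(file.exists(out[["csv"]]))
  twin <- jsonlite::read_json(out[["json"]], simplifyVector = TRUE)
  expect_equal(twin$adjusted_threshold, cmp$adjusted_threshold)
  expect_identical(nrow(twin$results), 4L)
})
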