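# Inferential layer: two-sided Mann-Whitney U tests over centrality and
# intensity families, with per-family Bonferroni correction. The U test is
# implemented natively: exact enumeration for small tie-free samples, and
# the tie- and continuity-corrected normal approximation otherwise.

#' Two-sided Mann-Whitney U test
#'
#' Computes U by rank sums with midranks for ties. When both samples have at
#' most `exact_limit` observations and there are no ties, the two-sided p
#' value is exact, by full enumeration of the rank arrangements; otherwise
#' the normal approximation with tie correction and continuity correction is
#' used. If every value in both samples is identical the test is degenerate:
#' p = 1, direction 0, no error.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param label_x,label_y Group labels carried into the result.
#' @param exact_limit Per-sample size bound for the exact-enumeration path
#'   (default 8).
#' @return A one-row tibble: labels, sample sizes, `u_statistic` (U of the
#'   first sample), two-sided `p_value`, per-group median/IQR/mean/SD/SE,
#'   `direction` (sign of the median difference, mean-based on median ties),
#'   `method` (`"exact"`, `"normal_approx"`, or `"degenerate"`).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # exact p = 0.1
mann_whitney_u <- function(x, y, label_x = "a", label_y = "b", exact_limit = 8L) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) {
    abort("Both samples must be non-empty.", class = "carenet_validation_error")
  }
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0

  if (length(unique(pooled)) == 1) {
    p <- 1
    method <- "degenerate"
  } else if (nx <= exact_limit && ny <= exact_limit && !ties) {
    # Exact null distribution of U over all C(nx+ny, nx) rank arrangements.
    sets <- combn(nx + ny, nx)
    u_all <- colSums(matrix(seq_len(nx + ny)[sets], nrow = nx)) - nx * (nx + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u), mean(u_all >= u)))
    method <- "exact"
  } else {
    n <- nx + ny
    z <- u - nx * ny / 2
    nties <- table(pooled)
    sigma <- sqrt((nx * ny / 12) * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1))))
    z <- (z - sign(z) * 0.5) / sigma
    p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    method <- "normal_approx"
  }

  med_x <- median(x)
  med_y <- median(y)
  direction <- sign(med_x - med_y)
  if (direction == 0) direction <- sign(mean(x) - mean(y))
  tibble(
    group_a = label_x, group_b = label_y,
    n_a = nx, n_b = ny,
    u_statistic = u, p_value = p,
    median_a = med_x, median_b = med_y,
    iqr_a = IQR(x), iqr_b = IQR(y),
    mean_a = mean(x), mean_b = mean(y),
    sd_a = sd(x), sd_b = sd(y),
    se_a = sd(x) / sqrt(nx), se_b = sd(y) / sqrt(ny),
    direction = direction,
    method = method
  )
}

new_comparison_table <- function(family_name, results, alpha, exclusions = NULL,
                                 network_level = NULL) {
  m <- nrow(results)
  thr <- if (m > 0) alpha / m else alpha
  if (m > 0) results$significant <- results$p_value < thr
  structure(
    list(
      family_name = family_name,
      results = results,
      alpha = alpha,
      m_tests = m,
      adjusted_threshold = thr,
      exclusions = exclusions %||% tibble(),
      network_level = network_level
    ),
    class = "comparison_table"
  )
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf(
    "<comparison_table> %s | %d test(s) | Bonferroni threshold %.4g (alpha %.3g) | %d significant\n",
    x$family_name, x$m_tests, x$adjusted_threshold, x$alpha,
    sum(x$results$significant %||% logical(0))
  ))
  if (!is.null(x$network_level)) {
    cat(sprintf(
      "  network-level: p = %.4g (unadjusted alpha %.3g)\n",
      x$network_level$p_value, x$alpha
    ))
  }
  invisible(x)
}

#' Tidy a comparison table
#' @param x A `comparison_table`.
#' @param ... Unused.
#' @return The per-test results tibble with the `significant` flag.
#' @method tidy comparison_table
#' @export
tidy.comparison_table <- function(x, ...) x$results

#' One-row family summary of a comparison table
#' @param x A `comparison_table`.
#' @param ... Unused.
#' @return A one-row tibble: family name, `m_tests`, `alpha`,
#'   `adjusted_threshold`, `n_significant`, `n_excluded`.
#' @method glance comparison_table
#' @export
glance.comparison_table <- function(x, ...) {
  tibble(
    family_name = x$family_name,
    m_tests = x$m_tests,
    alpha = x$alpha,
    adjusted_threshold = x$adjusted_threshold,
    n_significant = sum(x$results$significant %||% logical(0)),
    n_excluded = nrow(x$exclusions)
  )
}

#' Compare centrality between the two arms
#'
#' One network-level Mann-Whitney test over all node scores (reported
#' against the unadjusted significance level), plus a Bonferroni-corrected
#' family of per-expertise tests restricted to expertise categories with at
#' least `min_group` HCWs in both arms. Excluded categories (too few HCWs,
#' or present in only one arm) are listed in the `exclusions` annex.
#'
#' @param scores_a,scores_b `node_scores` from the same metric on the two
#'   arms' networks.
#' @param label_a,label_b Arm labels.
#' @param min_group Minimum per-arm HCW count for an expertise test
#'   (default 8).
#' @param alpha Family significance level (default 0.05).
#' @return A `comparison_table` with a `network_level` one-row test.
#' @export
compare_centrality <- function(scores_a, scores_b,
                               label_a = "covid", label_b = "non_covid",
                               min_group = 8L, alpha = 0.05) {
  metric_a <- attr(scores_a, "metric")
  metric_b <- attr(scores_b, "metric")
  if (!identical(metric_a, metric_b)) {
    abort(sprintf(
      "Metric mismatch between arms: %s vs %s.", metric_a, metric_b
    ), class = "carenet_validation_error")
  }
  a <- as_tibble(unclass_scores(scores_a))
  b <- as_tibble(unclass_scores(scores_b))
  network_level <- mann_whitney_u(a$score, b$score, label_a, label_b)
  network_level$scope <- "network"

  counts <- dplyr::full_join(
    dplyr::count(a, .data$expertise, name = "n_a"),
    dplyr::count(b, .data$expertise, name = "n_b"),
    by = "expertise"
  ) |>
    dplyr::mutate(
      n_a = tidyr::replace_na(.data$n_a, 0L),
      n_b = tidyr::replace_na(.data$n_b, 0L)
    )
  eligible <- dplyr::filter(counts, .data$n_a >= min_group, .data$n_b >= min_group)
  excluded <- dplyr::filter(counts, .data$n_a < min_group | .data$n_b < min_group) |>
    dplyr::mutate(reason = dplyr::case_when(
      n_a == 0L ~ sprintf("absent from %s arm", label_a),
      n_b == 0L ~ sprintf("absent from %s arm", label_b),
      TRUE ~ sprintf("fewer than %d HCWs in an arm", min_group)
    ))
  results <- purrr::map_dfr(sort(eligible$expertise), function(e) {
    res <- mann_whitney_u(
      a$score[a$expertise == e], b$score[b$expertise == e],
      label_a, label_b
    )
    res$expertise <- e
    res
  })
  if (nrow(results) > 0) {
    results <- dplyr::relocate(results, "expertise")
  }
  new_comparison_table(
    family_name = sprintf("%s_by_expertise", metric_a),
    results = results, alpha = alpha,
    exclusions = excluded, network_level = network_level
  )
}

#' Compare daily staffing intensity between the two arms
#'
#' The candidate family is the union of each arm's `top_k` expertise
#' categories by mean daily staffing intensity (mean over stays, zeros
#' included). Each category is tested over the per-stay intensity values --
#' one value per stay, with explicit zeros for stays the category never
#' touched -- and the family is Bonferroni-corrected over the union size.
#'
#' @param intensity_a,intensity_b Tibbles from [staffing_intensity()] for
#'   the two arms (zero-filled over each arm's expertise grid).
#' @param label_a,label_b Arm labels.
#' @param top_k Per-arm number of top categories (default 20).
#' @param alpha Family significance level (default 0.05).
#' @return A `comparison_table`; rows carry mean (SD) and median (IQR) per
#'   arm.
#' @export
compare_intensity <- function(intensity_a, intensity_b,
                              label_a = "covid", label_b = "non_covid",
                              top_k = 20L, alpha = 0.05) {
  a <- as_tibble(intensity_a)
  b <- as_tibble(intensity_b)
  stays_a <- unique(a$stay_id)
  stays_b <- unique(b$stay_id)
  top_of <- function(d) {
    means <- d |>
      dplyr::group_by(.data$expertise) |>
      dplyr::summarise(m = mean(.data$mean_daily_intensity), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$m), .data$expertise)
    if (nrow(means) < top_k) {
      warn(sprintf(
        "Fewer than top_k = %d expertise categories available (%d); using all.",
        top_k, nrow(means)
      ), class = "carenet_family_warning")
    }
    head(means$expertise, top_k)
  }
  family <- union(top_of(a), top_of(b))
  # Zero-fill against the union so a category absent from one arm tests
  # against all-zero values there.
  values_of <- function(d, stays, e) {
    v <- d$mean_daily_intensity[d$expertise == e]
    ids <- d$stay_id[d$expertise == e]
    out <- setNames(rep(0, length(stays)), stays)
    out[ids] <- v
    unname(out)
  }
  results <- purrr::map_dfr(sort(family), function(e) {
    res <- mann_whitney_u(
      values_of(a, stays_a, e), values_of(b, stays_b, e),
      label_a, label_b
    )
    res$expertise <- e
    res
  })
  results <- dplyr::relocate(results, "expertise")
  new_comparison_table("staffing_intensity", results, alpha)
}

#' Compare overall per-stay activity between the two arms
#'
#' Three two-sided Mann-Whitney tests -- per-stay action count, distinct
#' expertise count, and distinct HCW count (overall staffing intensity) --
#' Bonferroni-corrected as a 3-test family.
#'
#' @param summary_a,summary_b Tibbles from [stay_activity_summary()] for the
#'   two arms.
#' @param label_a,label_b Arm labels.
#' @param alpha Family significance level (default 0.05).
#' @return A `comparison_table` with one row per measure.
#' @export
compare_overall <- function(summary_a, summary_b,
                            label_a = "covid", label_b = "non_covid",
                            alpha = 0.05) {
  a <- as_tibble(summary_a)
  b <- as_tibble(summary_b)
  measures <- c("n_actions", "n_expertise", "n_hcws")
  results <- purrr::map_dfr(measures, function(m) {
    res <- mann_whitney_u(a[[m]], b[[m]], label_a, label_b)
    res$measure <- m
    res
  })
  new_comparison_table("overall_activity", dplyr::relocate(results, "measure"), alpha)
}

#' Dot plot of a comparison table
#'
#' Per-row medians for both arms, coloured by Bonferroni significance.
#'
#' @param object A `comparison_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot comparison_table
#' @export
autoplot.comparison_table <- function(object, ...) {
  res <- object$results
  key <- intersect(c("expertise", "measure"), names(res))[1]
  long <- res |>
    dplyr::select(dplyr::all_of(c(key, "median_a", "median_b", "significant"))) |>
    tidyr::pivot_longer(c("median_a", "median_b"),
      names_to = "arm", values_to = "median"
    ) |>
    dplyr::mutate(arm = ifelse(.data$arm == "median_a", res$group_a[1], res$group_b[1]))
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = stats::reorder(.data[[key]], .data$median),
      y = .data$median, colour = .data$arm, shape = .data$significant
    )
  ) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "median", colour = NULL,
      shape = sprintf("p < %.4g", object$adjusted_threshold),
      title = object$family_name
    ) +
    ggplot2::theme_minimal()
}

#' Write a comparison table as CSV plus a JSON twin
#'
#' @param x A `comparison_table`.
#' @param path CSV output path; the JSON twin replaces the extension with
#'   `.json`.
#' @return Invisibly, the two paths.
#' @export
write_comparison <- function(x, path) {
  stopifnot(inherits(x, "comparison_table"))
  readr::write_csv(x$results, path)
  json_path <- sub("\\.csv$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  payload <- list(
    family_name = x$family_name,
    alpha = x$alpha,
    m_tests = x$m_tests,
    adjusted_threshold = x$adjusted_threshold,
    results = x$results,
    exclusions = x$exclusions
  )
  if (!is.null(x$network_level)) payload$network_level <- x$network_level
  jsonlite::write_json(payload, json_path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(csv = path, json = json_path))
}
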