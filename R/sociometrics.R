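# Native sociometrics on collaboration networks: eigenvector centrality by
# shifted power iteration on the weighted adjacency, and betweenness
# centrality by Brandes' algorithm over unweighted shortest paths. Each has
# an independent small-graph oracle (dense eigen-decomposition; exhaustive
# simple-path enumeration) used by the test suite.

# Weighted adjacency matrix in node order.
adjacency_matrix <- function(net) {
  n <- nrow(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes$hcw_id, net$nodes$hcw_id))
  if (nrow(net$edges) > 0) {
    ia <- match(net$edges$hcw_a, net$nodes$hcw_id)
    ib <- match(net$edges$hcw_b, net$nodes$hcw_id)
    A[cbind(ia, ib)] <- net$edges$weight
    A[cbind(ib, ia)] <- net$edges$weight
  }
  A
}

# Neighbour index lists (unweighted view).
adjacency_list <- function(net) {
  n <- nrow(net$nodes)
  adj <- rep(list(integer(0)), n)
  if (nrow(net$edges) > 0) {
    ia <- match(net$edges$hcw_a, net$nodes$hcw_id)
    ib <- match(net$edges$hcw_b, net$nodes$hcw_id)
    for (k in seq_along(ia)) {
      adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
      adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
    }
  }
  adj
}

new_node_scores <- function(net, values, metric, normalization) {
  out <- tibble(
    hcw_id = net$nodes$hcw_id,
    expertise = net$nodes$expertise,
    score = unname(values)
  )
  structure(out,
    class = c("node_scores", class(out)),
    metric = metric, normalization = normalization, arm = net$arm
  )
}

check_nonempty <- function(net) {
  stopifnot(inherits(net, "collab_network"))
  if (nrow(net$nodes) == 0) {
    abort("Cannot compute centrality on an empty network.",
      class = "carenet_validation_error"
    )
  }
}

#' Eigenvector centrality by power iteration
#'
#' Dominant eigenvector of the weighted adjacency matrix (weights as
#' connection strength), computed by shifted power iteration from the
#' uniform start vector and rescaled so the maximum entry is exactly 1.
#' The shift (half the maximum node strength) breaks the period-2
#' oscillation of bipartite-like graphs without changing the eigenvector,
#' and scales with the weights, so uniformly rescaling all edge weights
#' leaves the scores bit-for-bit unchanged. On a connected graph all scores
#' are strictly positive (Perron-Frobenius); on a disconnected graph
#' scores concentrate on the dominant component and other components come
#' out near zero (a message reports the component count).
#'
#' @param net A `collab_network` with at least one node.
#' @param tol Convergence tolerance in max norm on the max-normalized
#'   iterates.
#' @param max_iter Iteration cap; non-convergence raises an error reporting
#'   the residual.
#' @return A `node_scores` tibble (`hcw_id`, `expertise`, `score`) with
#'   attributes `metric = "eigencentrality"` and `normalization`.
#' @export
eigencentrality <- function(net, tol = 1e-10, max_iter = 1000L) {
  check_nonempty(net)
  n <- nrow(net$nodes)
  if (nrow(net$edges) == 0) {
    # No connections: centrality degenerates; single isolated node scores 1.
    vals <- if (n == 1) 1 else {
      warn("Network has no edges; all eigencentrality scores are 0.")
      rep(0, n)
    }
    return(new_node_scores(net, vals, "eigencentrality", "max_entry_1"))
  }
  A <- adjacency_matrix(net)
  ncomp <- n_components(adjacency_list(net), n)
  if (ncomp > 1) {
    inform(sprintf(
      "Network has %d connected components; eigencentrality concentrates on the dominant one.",
      ncomp
    ))
  }
  sigma <- max(rowSums(A)) / 2
  v <- rep(1 / n, n)
  converged <- FALSE
  residual <- Inf
  for (it in seq_len(max_iter)) {
    w <- as.numeric(A %*% v) + sigma * v
    w <- w / max(w)
    residual <- max(abs(w - v))
    v <- w
    if (residual < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf(
      "Power iteration did not converge in %d iterations (residual %.3g).",
      max_iter, residual
    ), class = "carenet_convergence_error")
  }
  new_node_scores(net, v / max(v), "eigencentrality", "max_entry_1")
}

n_components <- function(adj, n) {
  seen <- rep(FALSE, n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- adj[[v]][!seen[adj[[v]]]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comps
}

#' Betweenness centrality (Brandes' algorithm)
#'
#' Fraction of shortest paths between other node pairs passing through each
#' node, with fractional credit when a pair has several shortest paths, and
#' normalized by the number of such pairs, `(n-1)(n-2)/2`; networks with
#' fewer than 3 nodes score 0 everywhere. Shortest paths are unweighted
#' (hop counts) by default: the edge weights are collaboration frequencies
#' -- similarities, not distances. `distance = "inverse_weight"` instead
#' runs Dijkstra on distances `1/weight`, as a sensitivity analysis.
#' Unreachable pairs contribute to no path counts.
#'
#' @param net A `collab_network` with at least one node.
#' @param distance `"hop"` (default) or `"inverse_weight"`.
#' @return A `node_scores` tibble with attribute `metric = "betweenness"`.
#' @export
betweenness <- function(net, distance = c("hop", "inverse_weight")) {
  check_nonempty(net)
  distance <- match.arg(distance)
  n <- nrow(net$nodes)
  norm_label <- paste0("pair_count_", distance)
  if (n < 3 || nrow(net$edges) == 0) {
    return(new_node_scores(net, rep(0, n), "betweenness", norm_label))
  }
  raw <- if (distance == "hop") {
    brandes_unweighted(adjacency_list(net), n)
  } else {
    brandes_weighted(net)
  }
  new_node_scores(net, raw / ((n - 1) * (n - 2) / 2), "betweenness", norm_label)
}

# Brandes' accumulation over BFS (hop-count) shortest paths. Processes each
# BFS level with vectorized neighbour scans; returns raw (unnormalized)
# undirected betweenness.
brandes_unweighted <- function(adj, n) {
  cb <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    sigma <- numeric(n)
    dist[s] <- 0L
    sigma[s] <- 1
    order_visited <- integer(n)
    order_visited[1] <- s
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      v <- order_visited[head]
      head <- head + 1L
      nb <- adj[[v]]
      if (length(nb) > 0) {
        newly <- nb[dist[nb] < 0L]
        if (length(newly) > 0) {
          dist[newly] <- dist[v] + 1L
          order_visited[(tail + 1L):(tail + length(newly))] <- newly
          tail <- tail + length(newly)
        }
        onpath <- nb[dist[nb] == dist[v] + 1L]
        sigma[onpath] <- sigma[onpath] + sigma[v]
      }
    }
    delta <- numeric(n)
    for (i in rev(seq_len(tail))) {
      w <- order_visited[i]
      if (w == s) next
      pv <- adj[[w]]
      pv <- pv[dist[pv] == dist[w] - 1L]
      delta[pv] <- delta[pv] + sigma[pv] / sigma[w] * (1 + delta[w])
      cb[w] <- cb[w] + delta[w]
    }
  }
  cb / 2
}

# Dijkstra variant with distances 1/weight; shortest-path ties are resolved
# up to a relative tolerance.
brandes_weighted <- function(net, tol = 1e-12) {
  n <- nrow(net$nodes)
  A <- adjacency_matrix(net)
  D <- ifelse(A > 0, 1 / A, Inf)
  adj <- adjacency_list(net)
  cb <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    sigma <- numeric(n)
    dist[s] <- 0
    sigma[s] <- 1
    done <- rep(FALSE, n)
    order_visited <- integer(0)
    repeat {
      cand <- which(!done & is.finite(dist))
      if (length(cand) == 0) break
      v <- cand[which.min(dist[cand])]
      done[v] <- TRUE
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        nd <- dist[v] + D[v, w]
        if (nd < dist[w] - tol) {
          dist[w] <- nd
          sigma[w] <- sigma[v]
        } else if (abs(nd - dist[w]) <= tol) {
          sigma[w] <- sigma[w] + sigma[v]
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      if (w == s) next
      pv <- adj[[w]]
      pv <- pv[abs(dist[pv] + D[cbind(pv, w)] - dist[w]) <= tol]
      delta[pv] <- delta[pv] + sigma[pv] / sigma[w] * (1 + delta[w])
      cb[w] <- cb[w] + delta[w]
    }
  }
  cb / 2
}

#' Betweenness oracle by exhaustive simple-path enumeration
#'
#' Independent testing oracle: for every unordered node pair, enumerates all
#' simple paths (depth-first, pruned at the current best length), keeps the
#' shortest, and accumulates fractional through-credit on interior nodes;
#' same pair-count normalization as [betweenness()]. Only for graphs with
#' at most `max_nodes` nodes.
#'
#' @param net A `collab_network`.
#' @param max_nodes Size cap (default 12); beyond it an error is raised.
#' @return A `node_scores` tibble.
#' @export
brute_force_betweenness <- function(net, max_nodes = 12L) {
  check_nonempty(net)
  n <- nrow(net$nodes)
  if (n > max_nodes) {
    abort(sprintf("brute_force_betweenness is capped at %d nodes (got %d).", max_nodes, n),
      class = "carenet_size_error"
    )
  }
  norm_label <- "pair_count_hop"
  if (n < 3 || nrow(net$edges) == 0) {
    return(new_node_scores(net, rep(0, n), "betweenness_oracle", norm_label))
  }
  adj <- adjacency_list(net)
  cb <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      best <- new.env(parent = emptyenv())
      best$len <- Inf
      best$paths <- list()
      dfs <- function(v, visited, path) {
        if (v == t) {
          len <- length(path) - 1L
          if (len < best$len) {
            best$len <- len
            best$paths <- list(path)
          } else if (len == best$len) {
            best$paths <- c(best$paths, list(path))
          }
          return(invisible())
        }
        if (length(path) - 1L >= best$len) {
          return(invisible())
        }
        for (w in adj[[v]]) {
          if (!visited[w]) {
            visited[w] <- TRUE
            dfs(w, visited, c(path, w))
            visited[w] <- FALSE
          }
        }
        invisible()
      }
      visited <- rep(FALSE, n)
      visited[s] <- TRUE
      dfs(s, visited, s)
      np <- length(best$paths)
      if (np > 0) {
        for (p in best$paths) {
          interior <- p[-c(1, length(p))]
          cb[interior] <- cb[interior] + 1 / np
        }
      }
    }
  }
  new_node_scores(net, cb / ((n - 1) * (n - 2) / 2), "betweenness_oracle", norm_label)
}

#' Eigencentrality oracle by dense eigen-decomposition
#'
#' Independent testing oracle: full symmetric eigen-decomposition of the
#' weighted adjacency, dominant eigenvector oriented non-negative and
#' rescaled to maximum entry 1. Only for graphs with at most `max_nodes`
#' nodes.
#'
#' @param net A `collab_network`.
#' @param max_nodes Size cap (default 50).
#' @return A `node_scores` tibble.
#' @export
dense_eigencentrality <- function(net, max_nodes = 50L) {
  check_nonempty(net)
  n <- nrow(net$nodes)
  if (n > max_nodes) {
    abort(sprintf("dense_eigencentrality is capped at %d nodes (got %d).", max_nodes, n),
      class = "carenet_size_error"
    )
  }
  if (nrow(net$edges) == 0) {
    vals <- if (n == 1) 1 else rep(0, n)
    return(new_node_scores(net, vals, "eigencentrality_oracle", "max_entry_1"))
  }
  A <- adjacency_matrix(net)
  es <- eigen(A, symmetric = TRUE)
  v <- es$vectors[, 1]
  v <- v * sign(v[which.max(abs(v))])
  v <- pmax(v, 0)
  new_node_scores(net, v / max(v), "eigencentrality_oracle", "max_entry_1")
}

#' Seeded random weighted network
#'
#' Erdos-Renyi-style random `collab_network` with integer weights, used by
#' the oracle-equivalence sweeps. With `connected = TRUE`, draws are
#' repeated until the graph is connected.
#'
#' @param n Number of nodes.
#' @param p Edge probability.
#' @param max_weight Weights are uniform on `1:max_weight`.
#' @param seed Integer seed.
#' @param connected Require a connected graph?
#' @return A `collab_network`.
#' @export
random_collab_network <- function(n, p = 0.4, max_weight = 5L, seed = 1L,
                                  connected = FALSE) {
  stopifnot(n >= 2)
  withr::with_seed(seed, {
    ids <- sprintf("h%02d", seq_len(n))
    pairs <- t(combn(n, 2))
    repeat {
      keep <- runif(nrow(pairs)) < p
      edges <- tibble(
        hcw_a = ids[pairs[keep, 1]],
        hcw_b = ids[pairs[keep, 2]],
        weight = sample.int(max_weight, sum(keep), replace = TRUE)
      )
      net <- collab_network(ids, edges)
      if (!connected ||
        (nrow(edges) > 0 && n_components(adjacency_list(net), n) == 1)) {
        return(net)
      }
    }
  })
}

#' Compute a named centrality on a network
#'
#' Thin dispatcher over [eigencentrality()] and [betweenness()], convenient
#' for pipelines.
#'
#' @param net A `collab_network`.
#' @param metric `"eigencentrality"` or `"betweenness"`.
#' @param ... Passed to the underlying metric function.
#' @return A `node_scores` tibble.
#' @export
node_centrality <- function(net, metric = c("eigencentrality", "betweenness"), ...) {
  metric <- match.arg(metric)
  switch(metric,
    eigencentrality = eigencentrality(net, ...),
    betweenness = betweenness(net, ...)
  )
}

#' @export
print.node_scores <- function(x, ...) {
  cat(sprintf(
    "<node_scores> metric %s | %d nodes | normalization %s\n",
    attr(x, "metric"), nrow(x), attr(x, "normalization")
  ))
  NextMethod()
}

#' Tidy node scores
#' @param x A `node_scores` object.
#' @param ... Unused.
#' @return A plain tibble (`hcw_id`, `expertise`, `score`, `metric`).
#' @method tidy node_scores
#' @export
tidy.node_scores <- function(x, ...) {
  out <- as_tibble(unclass_scores(x))
  out$metric <- attr(x, "metric")
  out
}

unclass_scores <- function(x) {
  class(x) <- setdiff(class(x), "node_scores")
  x
}

#' Distribution of node scores by expertise
#'
#' Boxplots of the score distribution for the largest expertise categories.
#'
#' @param object A `node_scores` object.
#' @param top_n Number of expertise categories shown (by HCW count).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot node_scores
#' @export
autoplot.node_scores <- function(object, top_n = 10L, ...) {
  df <- as_tibble(unclass_scores(object))
  keep <- df |>
    dplyr::count(.data$expertise) |>
    dplyr::arrange(dplyr::desc(.data$n)) |>
    head(top_n)
  df <- dplyr::filter(df, .data$expertise %in% keep$expertise)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = stats::reorder(.data$expertise, .data$score, FUN = stats::median),
      y = .data$score
    )
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = attr(object, "metric"),
      title = sprintf("%s by expertise (%s arm)", attr(object, "metric"), attr(object, "arm") %||% "")
    ) +
    ggplot2::theme_minimal()
}
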