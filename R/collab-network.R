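# Collaboration networks: two HCWs are linked when they act on the same
# patient's record on the same calendar day; edge weights count such
# co-access units. Also the per-arm roster summaries.

#' Build an HCW collaboration network for one arm
#'
#' Nodes are the HCWs with at least one event on the arm's stays (rostered
#' but inactive HCWs are excluded). For every unordered HCW pair the edge
#' weight counts, under `edge_unit = "patient-day"` (the default), the
#' number of distinct (patient, calendar day) pairs on which both HCWs have
#' at least one event -- two HCWs co-managing two patients on one day count
#' as two units of collaboration. Under `edge_unit = "day"` multi-patient
#' same-day co-occurrence collapses to one unit per distinct day. Pairs
#' that never co-occur carry no edge; duplicate events within a patient-day
#' never inflate weights.
#'
#' @param log An [audit_log()].
#' @param arm `"covid"` or `"non_covid"`.
#' @param edge_unit Co-access counting convention, `"patient-day"` or
#'   `"day"`.
#' @return A `collab_network`: list with tibbles `nodes` (`hcw_id`,
#'   `hcw_type`, `specialty`, `expertise`) and `edges` (`hcw_a`, `hcw_b`,
#'   `weight`, with `hcw_a < hcw_b`), plus `arm` and `edge_unit`.
#' @export
build_network <- function(log, arm, edge_unit = c("patient-day", "day")) {
  edge_unit <- match.arg(edge_unit)
  ev <- arm_events(log, arm)
  if (nrow(ev) == 0) {
    warn(sprintf("Arm '%s' has no events; returning an empty network.", arm),
      class = "carenet_empty_network_warning"
    )
    return(new_collab_network(
      nodes = tibble(
        hcw_id = character(), hcw_type = character(),
        specialty = character(), expertise = character()
      ),
      edges = empty_edges(), arm = arm, edge_unit = edge_unit
    ))
  }
  co <- ev |>
    dplyr::mutate(day = day_bin(.data$timestamp)) |>
    dplyr::distinct(.data$hcw_id, .data$patient_id, .data$day)
  pairs <- dplyr::inner_join(co, co,
    by = c("patient_id", "day"), relationship = "many-to-many",
    suffix = c("_a", "_b")
  ) |>
    dplyr::filter(.data$hcw_id_a < .data$hcw_id_b)
  edges <- if (edge_unit == "patient-day") {
    dplyr::count(pairs, .data$hcw_id_a, .data$hcw_id_b, name = "weight")
  } else {
    pairs |>
      dplyr::distinct(.data$hcw_id_a, .data$hcw_id_b, .data$day) |>
      dplyr::count(.data$hcw_id_a, .data$hcw_id_b, name = "weight")
  }
  edges <- edges |>
    dplyr::rename(hcw_a = "hcw_id_a", hcw_b = "hcw_id_b") |>
    dplyr::mutate(weight = as.integer(.data$weight)) |>
    dplyr::arrange(.data$hcw_a, .data$hcw_b)
  nodes <- ev |>
    dplyr::distinct(.data$hcw_id, .data$hcw_type, .data$specialty, .data$expertise) |>
    dplyr::arrange(.data$hcw_id)
  new_collab_network(nodes, edges, arm, edge_unit)
}

empty_edges <- function() {
  tibble(hcw_a = character(), hcw_b = character(), weight = integer())
}

new_collab_network <- function(nodes, edges, arm, edge_unit) {
  structure(
    list(nodes = nodes, edges = edges, arm = arm, edge_unit = edge_unit),
    class = "collab_network"
  )
}

#' Construct a collaboration network directly from node and edge tables
#'
#' Mainly for tests and worked examples; [build_network()] is the data
#' path. Checks the structural invariants: no self-loops, positive integer
#' weights, no duplicate (unordered) pairs.
#'
#' @param nodes Tibble with `hcw_id` (and optionally `hcw_type`,
#'   `specialty`, `expertise`), or a character vector of ids.
#' @param edges Tibble with `hcw_a`, `hcw_b`, `weight`.
#' @param arm,edge_unit Labels recorded on the network.
#' @return A `collab_network`.
#' @export
collab_network <- function(nodes, edges = NULL, arm = "covid",
                           edge_unit = "patient-day") {
  if (is.character(nodes)) nodes <- tibble(hcw_id = nodes)
  nodes <- as_tibble(nodes)
  for (col in c("hcw_type", "specialty", "expertise")) {
    if (!col %in% names(nodes)) nodes[[col]] <- NA_character_
  }
  if (is.null(edges) || nrow(as_tibble(edges)) == 0) {
    edges <- empty_edges()
  } else {
    edges <- as_tibble(edges)
    a <- pmin(edges$hcw_a, edges$hcw_b)
    b <- pmax(edges$hcw_a, edges$hcw_b)
    edges$hcw_a <- a
    edges$hcw_b <- b
    if (any(edges$hcw_a == edges$hcw_b)) {
      abort("Self-loops are not allowed.", class = "carenet_validation_error")
    }
    if (any(edges$weight < 1)) {
      abort("Edge weights must be >= 1 (absent pairs carry no edge).",
        class = "carenet_validation_error"
      )
    }
    if (anyDuplicated(edges[c("hcw_a", "hcw_b")])) {
      abort("Duplicate edges.", class = "carenet_validation_error")
    }
    missing <- setdiff(c(edges$hcw_a, edges$hcw_b), nodes$hcw_id)
    if (length(missing) > 0) {
      abort("Edges reference unknown nodes.", class = "carenet_validation_error")
    }
    edges <- dplyr::arrange(edges, .data$hcw_a, .data$hcw_b)
  }
  new_collab_network(dplyr::arrange(nodes, .data$hcw_id), edges, arm, edge_unit)
}

#' @export
print.collab_network <- function(x, ...) {
  cat(sprintf(
    "<collab_network> arm %s | %d nodes | %d edges | edge unit %s | total weight %d\n",
    x$arm, nrow(x$nodes), nrow(x$edges), x$edge_unit, sum(x$edges$weight)
  ))
  invisible(x)
}

#' Convert a collaboration network to an igraph graph
#'
#' @param net A `collab_network`.
#' @return An undirected weighted `igraph` graph with node attributes
#'   `expertise`, `specialty`, `hcw_type`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "collab_network"))
  igraph::graph_from_data_frame(
    d = dplyr::rename(net$edges, from = "hcw_a", to = "hcw_b"),
    directed = FALSE,
    vertices = net$nodes
  )
}

#' Export a collaboration network
#'
#' Writes GraphML or GEXF (with node attributes `expertise`, `specialty`,
#' `hcw_type` and integer edge weights) or a plain edge-list CSV
#' (`source`, `target`, `weight`).
#'
#' @param net A `collab_network`.
#' @param path Output file path.
#' @param format `"graphml"`, `"gexf"`, or `"edgelist"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, format = c("graphml", "gexf", "edgelist")) {
  stopifnot(inherits(net, "collab_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else if (format == "edgelist") {
    readr::write_csv(
      dplyr::rename(net$edges, source = "hcw_a", target = "hcw_b"),
      path
    )
  } else {
    write_gexf(net, path)
  }
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

# Minimal GEXF 1.2 writer (no installed R package emits GEXF).
write_gexf <- function(net, path) {
  n <- net$nodes
  e <- net$edges
  attvals <- function(i) {
    paste0(
      "      <attvalues>",
      sprintf("<attvalue for=\"0\" value=\"%s\"/>", xml_escape(n$expertise[i])),
      sprintf("<attvalue for=\"1\" value=\"%s\"/>", xml_escape(n$specialty[i])),
      sprintf("<attvalue for=\"2\" value=\"%s\"/>", xml_escape(n$hcw_type[i])),
      "</attvalues>"
    )
  }
  node_xml <- if (nrow(n) > 0) {
    vapply(seq_len(nrow(n)), function(i) {
      paste0(
        sprintf(
          "    <node id=\"%s\" label=\"%s\">\n",
          xml_escape(n$hcw_id[i]), xml_escape(n$hcw_id[i])
        ),
        attvals(i), "\n    </node>"
      )
    }, character(1))
  } else {
    character(0)
  }
  edge_xml <- if (nrow(e) > 0) {
    sprintf(
      "    <edge id=\"%d\" source=\"%s\" target=\"%s\" weight=\"%d\"/>",
      seq_len(nrow(e)) - 1L, xml_escape(e$hcw_a), xml_escape(e$hcw_b), e$weight
    )
  } else {
    character(0)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<gexf xmlns=\"http://www.gexf.net/1.2draft\" version=\"1.2\">",
    "  <graph defaultedgetype=\"undirected\" mode=\"static\">",
    "    <attributes class=\"node\">",
    "      <attribute id=\"0\" title=\"expertise\" type=\"string\"/>",
    "      <attribute id=\"1\" title=\"specialty\" type=\"string\"/>",
    "      <attribute id=\"2\" title=\"hcw_type\" type=\"string\"/>",
    "    </attributes>",
    "    <nodes>", node_xml, "    </nodes>",
    "    <edges>", edge_xml, "    </edges>",
    "  </graph>",
    "</gexf>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Summarize the roster active in one arm
#'
#' Network-level counts of distinct HCWs, HCW types, specialties, and
#' expertise categories with at least one event on the arm's stays;
#' per-patient means of the same distinct counts taken stay by stay; and
#' each expertise's share of the arm's active HCWs.
#'
#' @inheritParams build_network
#' @return A `roster_summary`: list with scalars `n_hcws`, `n_hcw_types`,
#'   `n_specialties`, `n_expertise`, a one-row tibble `per_patient_means`,
#'   and a tibble `expertise_shares` (`expertise`, `n`, `share`).
#' @export
roster_summary <- function(log, arm) {
  ev <- arm_events(log, arm)
  st <- arm_stays(log, arm)
  active <- dplyr::distinct(ev, .data$hcw_id, .data$hcw_type, .data$specialty, .data$expertise)
  per_stay <- ev |>
    dplyr::group_by(.data$stay_id) |>
    dplyr::summarise(
      hcws = dplyr::n_distinct(.data$hcw_id),
      hcw_types = dplyr::n_distinct(.data$hcw_type),
      specialties = dplyr::n_distinct(.data$specialty),
      expertise = dplyr::n_distinct(.data$expertise),
      .groups = "drop"
    )
  # Stays with no events contribute zero counts to the per-patient means.
  per_stay <- dplyr::left_join(
    dplyr::select(st, "stay_id"), per_stay,
    by = "stay_id"
  ) |>
    dplyr::mutate(dplyr::across(
      c("hcws", "hcw_types", "specialties", "expertise"),
      ~ tidyr::replace_na(.x, 0L)
    ))
  shares <- active |>
    dplyr::count(.data$expertise, name = "n") |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$share), .data$expertise)
  structure(
    list(
      arm = arm,
      n_hcws = nrow(active),
      n_hcw_types = dplyr::n_distinct(active$hcw_type),
      n_specialties = dplyr::n_distinct(active$specialty),
      n_expertise = dplyr::n_distinct(active$expertise),
      per_patient_means = tibble(
        hcws = mean(per_stay$hcws),
        hcw_types = mean(per_stay$hcw_types),
        specialties = mean(per_stay$specialties),
        expertise = mean(per_stay$expertise)
      ),
      expertise_shares = shares
    ),
    class = "roster_summary"
  )
}

#' @export
print.roster_summary <- function(x, ...) {
  cat(sprintf(
    "<roster_summary> arm %s | %d HCWs, %d types, %d specialties, %d expertise | per-patient mean %.1f HCWs\n",
    x$arm, x$n_hcws, x$n_hcw_types, x$n_specialties, x$n_expertise,
    x$per_patient_means$hcws
  ))
  invisible(x)
}

#' Union of the two arms' top expertise categories by HCW share
#'
#' Takes each arm's top-`k` expertise categories by share of active HCWs,
#' forms their union, and returns both arms' shares per category ordered by
#' combined share (the Figure-1-style comparison table).
#'
#' @param summary_a,summary_b [roster_summary()] objects for the two arms.
#' @param k Number of top categories per arm (default 10).
#' @return A tibble `(expertise, share_a, share_b, combined_share)` in
#'   decreasing `combined_share` order.
#' @export
top_expertise_shares <- function(summary_a, summary_b, k = 10L) {
  stopifnot(inherits(summary_a, "roster_summary"), inherits(summary_b, "roster_summary"))
  if (k < 1) abort("k must be >= 1.", class = "carenet_config_error")
  top <- function(s) head(s$expertise_shares$expertise, k)
  union_exp <- union(top(summary_a), top(summary_b))
  sa <- summary_a$expertise_shares
  sb <- summary_b$expertise_shares
  tibble(expertise = union_exp) |>
    dplyr::left_join(dplyr::select(sa, "expertise", share_a = "share"), by = "expertise") |>
    dplyr::left_join(dplyr::select(sb, "expertise", share_b = "share"), by = "expertise") |>
    dplyr::mutate(
      share_a = tidyr::replace_na(.data$share_a, 0),
      share_b = tidyr::replace_na(.data$share_b, 0),
      combined_share = .data$share_a + .data$share_b
    ) |>
    dplyr::arrange(dplyr::desc(.data$combined_share), .data$expertise)
}

#' Bar chart of the two arms' top expertise shares
#'
#' @param shares A tibble from [top_expertise_shares()].
#' @param label_a,label_b Display names for the two arms.
#' @return A ggplot object.
#' @export
plot_expertise_shares <- function(shares, label_a = "covid", label_b = "non_covid") {
  long <- shares |>
    dplyr::select("expertise", "share_a", "share_b") |>
    tidyr::pivot_longer(c("share_a", "share_b"),
      names_to = "arm", values_to = "share"
    ) |>
    dplyr::mutate(arm = ifelse(.data$arm == "share_a", label_a, label_b))
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = stats::reorder(.data$expertise, .data$share),
      y = .data$share, fill = .data$arm
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "share of active HCWs", fill = NULL,
      title = "Expertise composition of the two collaboration networks"
    ) +
    ggplot2::theme_minimal()
}
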