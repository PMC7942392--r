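# One-call orchestration: (simulated or read) audit log -> index-stay
# selection -> propensity matching -> per-arm networks -> centralities ->
# staffing intensities -> comparison families -> report bundle on disk,
# with a manifest hashing every artifact. One seed reproduces a whole run
# byte for byte.

#' Configure a pipeline run
#'
#' Exactly one of `scenario` (a [simulation_scenario()] or the path of a
#' YAML/JSON scenario file) or the three CSV paths must be given.
#'
#' @param scenario A [simulation_scenario()], or a scenario file path.
#' @param events_path,roster_path,stays_path Canonical CSV inputs (see
#'   [read_audit_log()]).
#' @param out_dir Output directory for the report bundle.
#' @param edge_unit Co-access counting convention; see [build_network()].
#' @param tol,max_iter Power-iteration controls; see [eigencentrality()].
#' @param betweenness_distance `"hop"` or `"inverse_weight"`; see
#'   [betweenness()].
#' @param exact_sex,caliper Matching controls; see [match_cohorts()].
#' @param min_group,top_k,alpha Comparison-family controls; see
#'   [compare_centrality()] and [compare_intensity()].
#' @param seed Integer master seed; per-stage sub-seeds are derived from it
#'   deterministically.
#' @return A `run_config` list.
#' @export
run_config <- function(scenario = NULL,
                       events_path = NULL, roster_path = NULL, stays_path = NULL,
                       out_dir = tempfile("carenet_run_"),
                       edge_unit = "patient-day",
                       tol = 1e-10, max_iter = 1000L,
                       betweenness_distance = "hop",
                       exact_sex = TRUE, caliper = NULL,
                       min_group = 8L, top_k = 20L, alpha = 0.05,
                       seed = 1L) {
  paths_given <- !is.null(events_path) || !is.null(roster_path) || !is.null(stays_path)
  if (!is.null(scenario) && paths_given) {
    abort("Give either a simulation scenario or input CSV paths, not both.",
      class = "carenet_config_error"
    )
  }
  if (is.null(scenario) && !paths_given) {
    abort("One of `scenario` or the input CSV paths is required.",
      class = "carenet_config_error"
    )
  }
  if (paths_given) {
    paths <- c(events_path, roster_path, stays_path)
    if (length(paths) < 3) {
      abort("All three of events_path, roster_path, stays_path are required.",
        class = "carenet_config_error"
      )
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      abort(sprintf("Input file(s) not found: %s", paste(missing, collapse = ", ")),
        class = "carenet_config_error"
      )
    }
  }
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  structure(
    list(
      scenario = scenario,
      events_path = events_path, roster_path = roster_path, stays_path = stays_path,
      out_dir = out_dir, edge_unit = edge_unit,
      tol = tol, max_iter = as.integer(max_iter),
      betweenness_distance = betweenness_distance,
      exact_sex = exact_sex, caliper = caliper,
      min_group = as.integer(min_group), top_k = as.integer(top_k), alpha = alpha,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order: audit-log simulation or ingestion, index-stay
#' selection, propensity fitting and 1:1 matching, per-arm network
#' construction, eigencentrality and betweenness, staffing intensities and
#' per-stay activity summaries, and the three comparison families
#' (centrality by expertise for both metrics, staffing intensity, overall
#' activity). Every artifact is written under `config$out_dir` and listed
#' with an MD5 content hash in `manifest.json`; identical config and seed
#' yield a byte-identical bundle.
#'
#' @param config A [run_config()].
#' @return A `report_bundle`: list with the in-memory objects (`log`,
#'   `pairs`, `networks`, `scores`, `intensity`, `activity`, `comparisons`,
#'   `roster_summaries`) and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  seed <- config$seed

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = "carenet_pipeline_error", parent = e
      )
    })
  }

  log <- stage("ingest", {
    if (!is.null(config$scenario)) {
      l <- simulate_audit_log(config$scenario, seed)
      write_audit_log(l, out)
      l
    } else {
      read_audit_log(config$events_path, config$roster_path, config$stays_path)
    }
  })

  pairs <- stage("match", {
    index <- select_index_stay(log$stays, seed = seed + 1L)
    scores <- fit_propensity(index)
    p <- match_cohorts(scores, index,
      exact_sex = config$exact_sex,
      caliper = config$caliper, seed = seed + 2L
    )
    readr::write_csv(tidy(p), file.path(out, "pairs.csv"))
    jsonlite::write_json(
      list(
        glance = glance(p),
        balance = covariate_balance(p, index),
        unmatched = p$unmatched
      ),
      file.path(out, "matching.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    p
  })
  matched_log <- filter_stays(log, matched_stay_ids(pairs))

  networks <- list()
  scores <- list()
  rosters <- list()
  for (arm in arm_levels()) {
    net <- stage(paste0("network_", arm), {
      n <- build_network(matched_log, arm, edge_unit = config$edge_unit)
      readr::write_csv(
        dplyr::rename(n$edges, source = "hcw_a", target = "hcw_b"),
        file.path(out, sprintf("network_%s_edges.csv", arm))
      )
      write_network(n, file.path(out, sprintf("network_%s.graphml", arm)), "graphml")
      write_network(n, file.path(out, sprintf("network_%s.gexf", arm)), "gexf")
      n
    })
    networks[[arm]] <- net
    scores[[arm]] <- stage(paste0("centrality_", arm), {
      sc <- list(
        eigencentrality = eigencentrality(net, tol = config$tol, max_iter = config$max_iter),
        betweenness = betweenness(net, distance = config$betweenness_distance)
      )
      for (m in names(sc)) {
        readr::write_csv(
          as_tibble(unclass_scores(sc[[m]])),
          file.path(out, sprintf("%s_%s.csv", m, arm))
        )
      }
      sc
    })
    rosters[[arm]] <- roster_summary(matched_log, arm)
  }

  intensity <- list()
  activity <- list()
  for (arm in arm_levels()) {
    intensity[[arm]] <- stage(paste0("intensity_", arm), {
      i <- staffing_intensity(matched_log, arm)
      readr::write_csv(i, file.path(out, sprintf("intensity_%s.csv", arm)))
      i
    })
    activity[[arm]] <- stage(paste0("activity_", arm), {
      s <- stay_activity_summary(matched_log, arm)
      readr::write_csv(s, file.path(out, sprintf("stay_summary_%s.csv", arm)))
      s
    })
  }

  comparisons <- stage("compare", {
    cmp <- list(
      eigencentrality = compare_centrality(
        scores$covid$eigencentrality, scores$non_covid$eigencentrality,
        min_group = config$min_group, alpha = config$alpha
      ),
      betweenness = compare_centrality(
        scores$covid$betweenness, scores$non_covid$betweenness,
        min_group = config$min_group, alpha = config$alpha
      ),
      intensity = compare_intensity(
        intensity$covid, intensity$non_covid,
        top_k = config$top_k, alpha = config$alpha
      ),
      overall = compare_overall(
        activity$covid, activity$non_covid,
        alpha = config$alpha
      )
    )
    for (nm in names(cmp)) {
      write_comparison(cmp[[nm]], file.path(out, sprintf("compare_%s.csv", nm)))
    }
    cmp
  })

  report <- stage("report", {
    rep <- list(
      n_pairs = nrow(pairs$pairs),
      score_correlation = score_correlation(pairs),
      roster_summaries = lapply(rosters, function(r) {
        list(
          arm = r$arm, n_hcws = r$n_hcws, n_hcw_types = r$n_hcw_types,
          n_specialties = r$n_specialties, n_expertise = r$n_expertise,
          per_patient_means = r$per_patient_means
        )
      }),
      median_scores = lapply(scores, function(sc) {
        lapply(sc, function(s) median(s$score))
      }),
      family_summaries = lapply(comparisons, glance)
    )
    jsonlite::write_json(rep, file.path(out, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    rep
  })

  manifest <- stage("manifest", {
    files <- sort(setdiff(list.files(out, recursive = TRUE), "manifest.json"))
    m <- list(
      package = "carenet",
      version = as.character(utils::packageVersion("carenet")),
      seed = seed,
      config = config_echo(config),
      counts = list(
        events = nrow(log$events),
        stays = nrow(log$stays),
        hcws = nrow(log$roster),
        pairs = nrow(pairs$pairs),
        nodes = lapply(networks, function(n) nrow(n$nodes)),
        edges = lapply(networks, function(n) nrow(n$edges))
      ),
      files = lapply(files, function(f) {
        list(path = f, md5 = unname(tools::md5sum(file.path(out, f))))
      })
    )
    jsonlite::write_json(m, file.path(out, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    m
  })

  structure(
    list(
      out_dir = out, log = log, pairs = pairs, networks = networks,
      scores = scores, intensity = intensity, activity = activity,
      comparisons = comparisons, roster_summaries = rosters,
      report = report, manifest = manifest
    ),
    class = "report_bundle"
  )
}

# Config echo for the manifest. Location fields (output directory, input
# paths) are dropped: the bundle must be byte-identical wherever it is
# written, and the manifest's file list already records content.
config_echo <- function(config) {
  echo <- unclass(config)
  echo$out_dir <- NULL
  echo$events_path <- NULL
  echo$roster_path <- NULL
  echo$stays_path <- NULL
  if (!is.null(echo$scenario)) {
    echo$scenario <- unclass(echo$scenario)
  }
  echo
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf(
    "<report_bundle> %s | %d pairs | networks: %s | %d artifact file(s)\n",
    x$out_dir, nrow(x$pairs$pairs),
    paste(sprintf(
      "%s %d nodes/%d edges", names(x$networks),
      vapply(x$networks, function(n) nrow(n$nodes), 1L),
      vapply(x$networks, function(n) nrow(n$edges), 1L)
    ), collapse = ", "),
    length(x$manifest$files)
  ))
  invisible(x)
}
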