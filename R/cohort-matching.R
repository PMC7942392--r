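# Study-design stage: index-stay selection, propensity scores on
# age / sex / length of stay, and greedy 1:1 nearest-neighbour matching
# across arms.

#' Select one index stay per patient
#'
#' Patients with multiple stays contribute one stay each, selected uniformly
#' at random under `seed`; patients with a single stay keep it. Deterministic
#' given the seed.
#'
#' @param stays A stays tibble (as in an [audit_log()]; must carry
#'   `stay_id` and `patient_id`).
#' @param seed Integer seed.
#' @return A stays tibble with exactly one row per `patient_id`, in the
#'   original row order.
#' @export
select_index_stay <- function(stays, seed = 1L) {
  stays <- as_tibble(stays)
  withr::with_seed(seed, {
    keep <- stays |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::slice_sample(n = 1) |>
      dplyr::ungroup()
    dplyr::arrange(keep, .data$.row) |> dplyr::select(-".row")
  })
}

#' Fit propensity scores for arm membership
#'
#' Logistic regression of covid-arm membership on age, sex, and fractional
#' length of stay; the fitted probabilities are the propensity scores.
#'
#' @param stays A stays tibble with columns `stay_id`, `arm`, `age`, `sex`,
#'   and `los_days` (or `admit_ts`/`discharge_ts`, from which `los_days` is
#'   derived).
#' @return A tibble `(stay_id, arm, score)` with all scores in (0, 1).
#' @export
fit_propensity <- function(stays) {
  stays <- as_tibble(stays)
  if (!"los_days" %in% names(stays)) {
    stays$los_days <- los_days(stays$admit_ts, stays$discharge_ts)
  }
  if (!"stay_id" %in% names(stays)) stays$stay_id <- as.character(stays$patient_id)
  counts <- table(factor(stays$arm, arm_levels()))
  if (any(counts < 2)) {
    abort("Need at least 2 stays per arm to fit a propensity model.",
      class = "carenet_validation_error"
    )
  }
  df <- dplyr::mutate(stays,
    is_covid = as.integer(.data$arm == "covid"),
    sex_male = as.integer(.data$sex == "male")
  )
  fit <- withCallingHandlers(
    glm(is_covid ~ age + sex_male + los_days, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        abort(paste(
          "Complete separation: a covariate perfectly predicts arm membership,",
          "so propensity scores are degenerate. Consider exact matching on the",
          "separating covariate instead of propensity-score matching."
        ), class = "carenet_separation_error")
      }
      invokeRestart("muffleWarning")
    }
  )
  p <- fitted(fit)
  if (any(p <= 1e-12 | p >= 1 - 1e-12)) {
    abort(paste(
      "Complete separation: fitted propensity scores reach 0/1.",
      "Consider caliper-free exact matching on covariates instead."
    ), class = "carenet_separation_error")
  }
  tibble(stay_id = df$stay_id, arm = df$arm, score = unname(p))
}

#' Match covid and non-covid stays 1:1 on the propensity score
#'
#' Greedy nearest-neighbour matching without replacement on the logit of the
#' propensity score. Covid stays are processed in seeded random order; each
#' takes the closest still-unmatched non-covid stay (ties broken by stay_id
#' order). With `exact_sex = TRUE` (the default) candidates are restricted
#' to the same sex. A caliper, if given, is an upper bound on the absolute
#' logit-score distance; covid stays with no candidate inside the caliper
#' are reported unmatched rather than raising an error.
#'
#' @param scores Tibble `(stay_id, arm, score)` from [fit_propensity()],
#'   covering all stays.
#' @param stays The stays tibble the scores were fitted on.
#' @param exact_sex Restrict candidates to the same sex?
#' @param caliper Optional non-negative maximum logit-score distance.
#' @param seed Integer seed for the processing order.
#' @return A `matched_pairs` object; see [tidy.matched_pairs()] and
#'   [glance.matched_pairs()].
#' @export
match_cohorts <- function(scores, stays, exact_sex = TRUE, caliper = NULL,
                          seed = 1L) {
  stays <- as_tibble(stays)
  if (!"stay_id" %in% names(stays)) stays$stay_id <- as.character(stays$patient_id)
  scores <- as_tibble(scores)
  missing <- setdiff(stays$stay_id, scores$stay_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "Scores must cover all stays; missing: %s.",
      paste(head(missing, 5), collapse = ", ")
    ), class = "carenet_validation_error")
  }
  df <- dplyr::left_join(
    dplyr::select(stays, "stay_id", "arm", "sex"),
    dplyr::select(scores, "stay_id", "score"),
    by = "stay_id"
  )
  df$logit <- qlogis(df$score)
  covid <- dplyr::filter(df, .data$arm == "covid")
  ctrl <- dplyr::arrange(dplyr::filter(df, .data$arm == "non_covid"), .data$stay_id)

  order_idx <- withr::with_seed(seed, sample(nrow(covid)))
  taken <- rep(FALSE, nrow(ctrl))
  rows <- vector("list", nrow(covid))
  unmatched <- character()
  for (i in order_idx) {
    cand <- which(!taken)
    if (exact_sex) cand <- cand[ctrl$sex[cand] == covid$sex[i]]
    if (length(cand) > 0) {
      d <- abs(ctrl$logit[cand] - covid$logit[i])
      if (!is.null(caliper)) cand_keep <- d <= caliper else cand_keep <- rep(TRUE, length(d))
      cand <- cand[cand_keep]
      d <- d[cand_keep]
    }
    if (length(cand) == 0) {
      unmatched <- c(unmatched, covid$stay_id[i])
      next
    }
    j <- cand[which.min(d)]
    taken[j] <- TRUE
    rows[[i]] <- tibble(
      covid_stay_id = covid$stay_id[i],
      non_covid_stay_id = ctrl$stay_id[j],
      score_covid = covid$score[i],
      score_non_covid = ctrl$score[j],
      distance = abs(covid$logit[i] - ctrl$logit[j])
    )
  }
  pairs <- dplyr::bind_rows(rows[order_idx])
  if (nrow(pairs) == 0) {
    pairs <- tibble(
      covid_stay_id = character(), non_covid_stay_id = character(),
      score_covid = numeric(), score_non_covid = numeric(), distance = numeric()
    )
  }
  structure(
    list(
      pairs = pairs,
      scores = scores,
      unmatched = sort(unmatched),
      exact_sex = exact_sex,
      caliper = caliper
    ),
    class = "matched_pairs"
  )
}

#' Correlation between the matched arms' propensity-score distributions
#'
#' `type = "sorted"` (the default) is the quantile-quantile convention:
#' Pearson correlation between the two matched arms' sorted score vectors.
#' `type = "within_pair"` correlates scores pair by pair instead. If the two
#' vectors are identical the correlation is defined as 1.
#'
#' @param x A `matched_pairs` object.
#' @param type `"sorted"` or `"within_pair"`.
#' @return A single correlation in `[-1, 1]`, or `NA` for fewer than 2 pairs.
#' @export
score_correlation <- function(x, type = c("sorted", "within_pair")) {
  stopifnot(inherits(x, "matched_pairs"))
  type <- match.arg(type)
  a <- x$pairs$score_covid
  b <- x$pairs$score_non_covid
  if (type == "sorted") {
    a <- sort(a)
    b <- sort(b)
  }
  if (length(a) < 2) {
    return(NA_real_)
  }
  if (isTRUE(all.equal(a, b)) || sd(a) == 0 || sd(b) == 0) {
    return(if (max(abs(a - b)) < 1e-12) 1 else NA_real_)
  }
  cor(a, b)
}

#' @export
print.matched_pairs <- function(x, ...) {
  cat(sprintf(
    "<matched_pairs> %d pairs | %d unmatched covid stay(s) | score correlation (sorted) %.3f\n",
    nrow(x$pairs), length(x$unmatched), score_correlation(x)
  ))
  invisible(x)
}

#' Tidy a matched-pairs object
#' @param x A `matched_pairs` object.
#' @param ... Unused.
#' @return The pairs tibble (`covid_stay_id`, `non_covid_stay_id`,
#'   `score_covid`, `score_non_covid`, `distance`).
#' @method tidy matched_pairs
#' @export
tidy.matched_pairs <- function(x, ...) x$pairs

#' One-row summary of a matching
#' @param x A `matched_pairs` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_pairs`, `n_unmatched`, `score_correlation`,
#'   `mean_distance`.
#' @method glance matched_pairs
#' @export
glance.matched_pairs <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$pairs),
    n_unmatched = length(x$unmatched),
    score_correlation = score_correlation(x),
    mean_distance = if (nrow(x$pairs) > 0) mean(x$pairs$distance) else NA_real_
  )
}

#' Stay ids retained by a matching, both arms
#' @param x A `matched_pairs` object.
#' @return Character vector of matched stay ids.
#' @export
matched_stay_ids <- function(x) {
  stopifnot(inherits(x, "matched_pairs"))
  c(x$pairs$covid_stay_id, x$pairs$non_covid_stay_id)
}

#' Covariate balance of a matching
#'
#' @param x A `matched_pairs` object.
#' @param stays The stays tibble used for matching.
#' @return A tibble with per-arm means of age, male share, and length of
#'   stay over the matched stays, plus mean within-pair absolute
#'   differences.
#' @export
covariate_balance <- function(x, stays) {
  stopifnot(inherits(x, "matched_pairs"))
  stays <- as_tibble(stays)
  if (!"los_days" %in% names(stays)) {
    stays$los_days <- los_days(stays$admit_ts, stays$discharge_ts)
  }
  get <- function(ids) stays[match(ids, stays$stay_id), ]
  a <- get(x$pairs$covid_stay_id)
  b <- get(x$pairs$non_covid_stay_id)
  tibble(
    covariate = c("age", "male", "los_days"),
    mean_covid = c(mean(a$age), mean(a$sex == "male"), mean(a$los_days)),
    mean_non_covid = c(mean(b$age), mean(b$sex == "male"), mean(b$los_days)),
    mean_abs_pair_diff = c(
      mean(abs(a$age - b$age)),
      mean(a$sex != b$sex),
      mean(abs(a$los_days - b$los_days))
    )
  )
}
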