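# Daily patient staffing intensity: per (stay, expertise), the mean number
# of distinct HCWs acting per day, with the *fractional* length of stay
# (hours / 24) as the denominator -- deliberately not the calendar-day
# count, so intensities can slightly exceed the plain per-day average when
# a stay is not aligned to midnight.

#' Distinct-HCW counts per calendar day and expertise for one stay
#'
#' For each calendar day of the stay and each expertise category, the number
#' of distinct HCWs of that expertise with at least one event on the stay
#' that day. Duplicate events never inflate counts; days without events
#' yield explicit zero rows, so the returned grid is complete over
#' (stay days) x (expertise categories considered).
#'
#' @param log An [audit_log()].
#' @param stay_id A single `stay_id` present in the log.
#' @param expertise Character vector of expertise categories forming the
#'   count grid; defaults to the categories with at least one event on this
#'   stay. Pass the arm-wide expertise set to obtain all-zero rows for
#'   categories never present on the stay.
#' @return A tibble `(stay_id, day, expertise, n_hcws)` with
#'   `day_count * length(expertise)` rows.
#' @export
daily_expertise_counts <- function(log, stay_id, expertise = NULL) {
  stopifnot(inherits(log, "audit_log"), length(stay_id) == 1)
  st <- dplyr::filter(log$stays, .data$stay_id == !!stay_id)
  if (nrow(st) == 0) {
    abort(sprintf("Unknown stay_id: %s", stay_id), class = "carenet_validation_error")
  }
  ev <- dplyr::filter(arm_events(log), .data$stay_id == !!stay_id)
  counts <- ev |>
    dplyr::mutate(day = day_bin(.data$timestamp)) |>
    dplyr::distinct(.data$hcw_id, .data$day, .data$expertise) |>
    dplyr::count(.data$day, .data$expertise, name = "n_hcws")
  if (is.null(expertise)) expertise <- sort(unique(ev$expertise))
  grid <- tidyr::expand_grid(
    day = stay_days(st$admit_ts, st$discharge_ts),
    expertise = expertise
  )
  grid |>
    dplyr::left_join(counts, by = c("day", "expertise")) |>
    dplyr::mutate(
      stay_id = !!stay_id,
      n_hcws = as.integer(tidyr::replace_na(.data$n_hcws, 0L))
    ) |>
    dplyr::select("stay_id", "day", "expertise", "n_hcws")
}

#' Mean daily staffing intensity from a daily-count sequence
#'
#' The summed daily distinct-HCW counts divided by the *fractional* length
#' of stay. Because the denominator is hours/24 rather than the calendar-day
#' count, a stay spanning two calendar days but lasting 1.5 days with
#' counts `c(2, 1)` has intensity `(2 + 1) / 1.5 = 2`.
#'
#' @param daily_counts Integer vector of per-day distinct-HCW counts,
#'   one entry per calendar day of the stay.
#' @param los Fractional length of stay in days; must be positive.
#' @return A single non-negative number; 0 exactly when all counts are 0.
#' @export
#' @examples
#' mean_daily_intensity(c(2, 4), 2.0) # 3
#' mean_daily_intensity(c(2, 1), 1.5) # 2
mean_daily_intensity <- function(daily_counts, los) {
  if (length(los) != 1 || !is.finite(los) || los <= 0) {
    abort("Invalid stay: length of stay must be a single positive number.",
      class = "carenet_validation_error"
    )
  }
  if (any(daily_counts < 0)) {
    abort("Daily counts must be non-negative.", class = "carenet_validation_error")
  }
  sum(daily_counts) / los
}

#' Per-stay, per-expertise daily staffing intensity for one arm
#'
#' Computes the mean daily staffing intensity for every (stay, expertise)
#' pair of the arm. The expertise grid is the set of categories with at
#' least one event anywhere in the arm (or the supplied `expertise`), and
#' categories absent on a given stay receive an explicit intensity of 0 --
#' the downstream group comparisons need zeros, not missing values.
#'
#' @param log An [audit_log()].
#' @param arm `"covid"` or `"non_covid"`; `NULL` processes all stays.
#' @param expertise Optional character vector fixing the expertise grid.
#' @return A tibble `(stay_id, expertise, mean_daily_intensity)` with one
#'   row per stay x expertise.
#' @export
staffing_intensity <- function(log, arm = NULL, expertise = NULL) {
  stopifnot(inherits(log, "audit_log"))
  st <- arm_stays(log, arm)
  ev <- arm_events(log, arm)
  if (is.null(expertise)) expertise <- sort(unique(ev$expertise))
  sums <- ev |>
    dplyr::mutate(day = day_bin(.data$timestamp)) |>
    dplyr::distinct(.data$stay_id, .data$hcw_id, .data$day, .data$expertise) |>
    dplyr::count(.data$stay_id, .data$expertise, name = "total_hcw_days")
  tidyr::expand_grid(stay_id = st$stay_id, expertise = expertise) |>
    dplyr::left_join(sums, by = c("stay_id", "expertise")) |>
    dplyr::left_join(dplyr::select(st, "stay_id", "los_days"), by = "stay_id") |>
    dplyr::mutate(
      total_hcw_days = tidyr::replace_na(.data$total_hcw_days, 0L),
      mean_daily_intensity = .data$total_hcw_days / .data$los_days
    ) |>
    dplyr::select("stay_id", "expertise", "mean_daily_intensity")
}

#' Per-stay activity summary (overall staffing intensity)
#'
#' For each stay: the total number of actions performed on its record, the
#' number of distinct expertise categories acting, and the number of
#' distinct HCWs acting over the whole stay -- the latter is the overall
#' staffing intensity. An HCW active on several days counts once.
#'
#' @inheritParams staffing_intensity
#' @return A tibble `(stay_id, n_actions, n_expertise, n_hcws)`, one row
#'   per stay of the arm (stays with no events report zeros).
#' @export
stay_activity_summary <- function(log, arm = NULL) {
  stopifnot(inherits(log, "audit_log"))
  st <- arm_stays(log, arm)
  ev <- arm_events(log, arm)
  per <- ev |>
    dplyr::group_by(.data$stay_id) |>
    dplyr::summarise(
      n_actions = dplyr::n(),
      n_expertise = dplyr::n_distinct(.data$expertise),
      n_hcws = dplyr::n_distinct(.data$hcw_id),
      .groups = "drop"
    )
  dplyr::left_join(dplyr::select(st, "stay_id"), per, by = "stay_id") |>
    dplyr::mutate(dplyr::across(
      c("n_actions", "n_expertise", "n_hcws"),
      ~ as.integer(tidyr::replace_na(.x, 0L))
    ))
}
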