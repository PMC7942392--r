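# Domain model for EHR audit logs: rosters, stays, action events, and the
# derived quantities (expertise labels, calendar-day bins, fractional length
# of stay) every downstream stage consumes.

#' The closed set of audit-log action categories
#'
#' Every action an HCW performs on a patient's record is classified into one
#' of six categories: condition-related (e.g. assigning a diagnosis),
#' procedure-related, medication-related, note-related, order-related, and
#' measurement-related actions. Readers reject anything outside this set.
#'
#' @return A character vector of the six category names.
#' @export
#' @examples
#' action_categories()
action_categories <- function() {
  c("condition", "procedure", "medication", "note", "order", "measurement")
}

#' Arm labels for the two-cohort comparison
#' @return Character vector `c("covid", "non_covid")`.
#' @export
arm_levels <- function() c("covid", "non_covid")

#' Compose an expertise label from specialty and HCW type
#'
#' An HCW node is labelled by its expertise, the composite
#' `"<specialty>: <hcw_type>"` (e.g. `"respiratory care: respiratory
#' therapist"`). The label is a pure function of its two components; empty
#' components are rejected.
#'
#' @param specialty Character vector of unit/department names.
#' @param hcw_type Character vector of HCW role names, recycled against
#'   `specialty`.
#' @return Character vector of `"specialty: type"` labels.
#' @export
#' @examples
#' expertise_label("respiratory care", "respiratory therapist")
expertise_label <- function(specialty, hcw_type) {
  specialty <- trimws(as.character(specialty))
  hcw_type <- trimws(as.character(hcw_type))
  bad <- !nzchar(specialty) | !nzchar(hcw_type) | is.na(specialty) | is.na(hcw_type)
  if (any(bad)) {
    abort("`specialty` and `hcw_type` must both be non-empty to form an expertise label.",
      class = "carenet_validation_error"
    )
  }
  paste0(specialty, ": ", hcw_type)
}

#' Bin a timestamp to its calendar day
#'
#' Collaboration is resolved at day granularity: two HCWs are considered
#' connected when they act on the same patient's record on the same calendar
#' day. `day_bin()` truncates an instant to its local calendar date; no
#' timezone arithmetic is applied (single-site local clock time is assumed,
#' stored as UTC).
#'
#' @param timestamp A `POSIXct` vector (or anything coercible via
#'   [as_instant()]).
#' @return A `Date` vector.
#' @export
#' @examples
#' day_bin(as_instant("2020-03-20 23:59:00"))
#' day_bin(as_instant("2020-03-21 00:01:00"))
day_bin <- function(timestamp) {
  timestamp <- as_instant(timestamp)
  as.Date(timestamp, tz = "UTC")
}

#' Coerce to a POSIXct instant in the canonical (UTC-stored) clock
#'
#' @param x `POSIXct`, `Date`, or ISO 8601 character.
#' @return A `POSIXct` vector with `tzone = "UTC"`.
#' @export
as_instant <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(as.numeric(x) * 86400, origin = "1970-01-01", tz = "UTC"))
  }
  out <- as.POSIXct(x, tz = "UTC", tryFormats = c(
    "%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"
  ))
  if (anyNA(out) && !anyNA(x)) {
    abort("Timestamps must be ISO 8601 (e.g. \"2020-03-20T14:05:00\").",
      class = "carenet_validation_error"
    )
  }
  out
}

#' Fractional length of stay in days
#'
#' Length of stay is the number of hours between admission and discharge
#' divided by 24. It is deliberately fractional: a stay admitted at noon and
#' discharged at midnight two days later lasts 1.5 days even though it
#' touches three calendar days. The fractional value is the denominator of
#' the daily staffing-intensity statistic; the calendar-day count is tracked
#' separately by [stay_day_count()].
#'
#' @param admit_ts,discharge_ts Admission and discharge instants
#'   (coercible via [as_instant()]), vectorized.
#' @return Numeric vector of lengths of stay in (fractional) days.
#' @export
#' @examples
#' los_days("2020-03-01 12:00:00", "2020-03-03 00:00:00") # 1.5
los_days <- function(admit_ts, discharge_ts) {
  admit_ts <- as_instant(admit_ts)
  discharge_ts <- as_instant(discharge_ts)
  los <- as.numeric(difftime(discharge_ts, admit_ts, units = "hours")) / 24
  if (any(los <= 0, na.rm = TRUE)) {
    abort("Invalid stay: discharge must be strictly after admission.",
      class = "carenet_validation_error"
    )
  }
  los
}

#' Number of distinct calendar days a stay touches
#'
#' @inheritParams los_days
#' @return Integer vector; always `ceiling(los_days)` or
#'   `ceiling(los_days) + 1` (a stay spanning midnight touches one extra
#'   calendar day).
#' @export
stay_day_count <- function(admit_ts, discharge_ts) {
  a <- day_bin(admit_ts)
  d <- day_bin(discharge_ts)
  as.integer(d - a) + 1L
}

#' Enumerate the calendar days of a stay
#' @inheritParams los_days
#' @return A `Date` vector from the admission day to the discharge day.
#' @export
stay_days <- function(admit_ts, discharge_ts) {
  seq(day_bin(admit_ts), day_bin(discharge_ts), by = "day")
}

required_columns <- list(
  events = c("hcw_id", "patient_id", "timestamp", "action_category"),
  roster = c("hcw_id", "hcw_type", "specialty"),
  stays = c("patient_id", "arm", "admit_ts", "discharge_ts", "age", "sex")
)

check_schema <- function(df, what) {
  missing <- setdiff(required_columns[[what]], names(df))
  if (length(missing) > 0) {
    abort(
      sprintf(
        "%s table is missing required column%s: %s",
        what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
      ),
      class = "carenet_schema_error"
    )
  }
  invisible(df)
}

#' Assemble and validate an audit log
#'
#' Bundles the three canonical tables -- action events, HCW roster, and
#' patient stays -- into a validated `audit_log` object. Validation is
#' total: inputs either load or raise a typed error; no rows are silently
#' dropped. Expertise labels, fractional length of stay (`los_days`), and
#' the calendar-day count (`day_count`) are materialized on construction.
#'
#' Events time-stamped outside their stay's admission--discharge window are
#' retained and flagged in the `in_window` column with a warning (real audit
#' logs contain pre-admission orders); `strict = TRUE` drops them instead.
#' Duplicate events are retained: all day-level computations downstream are
#' duplicate-insensitive by construction.
#'
#' @param events Data frame with columns `hcw_id`, `patient_id`,
#'   `timestamp`, `action_category`.
#' @param roster Data frame with columns `hcw_id`, `hcw_type`, `specialty`.
#' @param stays Data frame with columns `patient_id`, `arm`, `admit_ts`,
#'   `discharge_ts`, `age`, `sex` (optionally `stay_id`; defaults to
#'   `patient_id`).
#' @param strict Drop out-of-window events instead of flagging them?
#' @return An `audit_log`: a list of tibbles `events`, `roster`, `stays`.
#' @export
audit_log <- function(events, roster, stays, strict = FALSE) {
  events <- as_tibble(events)
  roster <- as_tibble(roster)
  stays <- as_tibble(stays)
  check_schema(events, "events")
  check_schema(roster, "roster")
  check_schema(stays, "stays")

  roster <- dplyr::mutate(roster,
    hcw_id = as.character(.data$hcw_id),
    hcw_type = as.character(.data$hcw_type),
    specialty = as.character(.data$specialty)
  )
  if (anyDuplicated(roster$hcw_id)) {
    abort("Roster hcw_id values must be unique.", class = "carenet_validation_error")
  }
  roster$expertise <- expertise_label(roster$specialty, roster$hcw_type)

  if (!"stay_id" %in% names(stays)) stays$stay_id <- as.character(stays$patient_id)
  stays <- dplyr::mutate(stays,
    stay_id = as.character(.data$stay_id),
    patient_id = as.character(.data$patient_id),
    arm = as.character(.data$arm),
    admit_ts = as_instant(.data$admit_ts),
    discharge_ts = as_instant(.data$discharge_ts),
    sex = as.character(.data$sex)
  )
  if (anyDuplicated(stays$stay_id)) {
    abort("stay_id values must be unique.", class = "carenet_validation_error")
  }
  bad_arm <- setdiff(unique(stays$arm), arm_levels())
  if (length(bad_arm) > 0) {
    abort(sprintf(
      "Unknown arm label(s): %s (expected %s).",
      paste(bad_arm, collapse = ", "), paste(arm_levels(), collapse = ", ")
    ), class = "carenet_validation_error")
  }
  bad_sex <- setdiff(unique(stays$sex), c("female", "male"))
  if (length(bad_sex) > 0) {
    abort(sprintf("Unknown sex value(s): %s.", paste(bad_sex, collapse = ", ")),
      class = "carenet_validation_error"
    )
  }
  stays$los_days <- los_days(stays$admit_ts, stays$discharge_ts)
  stays$day_count <- stay_day_count(stays$admit_ts, stays$discharge_ts)
  stays <- dplyr::relocate(
    stays, "patient_id", "stay_id", "arm", "admit_ts", "discharge_ts",
    "age", "sex", "los_days", "day_count"
  )

  events <- dplyr::mutate(events,
    hcw_id = as.character(.data$hcw_id),
    patient_id = as.character(.data$patient_id),
    timestamp = as_instant(.data$timestamp),
    action_category = as.character(.data$action_category)
  )
  bad_cat <- which(!events$action_category %in% action_categories())
  if (length(bad_cat) > 0) {
    abort(sprintf(
      "Unknown action_category in event row%s %s: %s. Valid categories: %s.",
      if (length(bad_cat) > 1) "s" else "",
      paste(head(bad_cat, 10), collapse = ", "),
      paste(unique(events$action_category[bad_cat]), collapse = ", "),
      paste(action_categories(), collapse = ", ")
    ), class = "carenet_validation_error")
  }
  dangling_hcw <- setdiff(unique(events$hcw_id), roster$hcw_id)
  if (length(dangling_hcw) > 0) {
    abort(sprintf(
      "Events reference hcw_id(s) absent from the roster: %s.",
      paste(head(dangling_hcw, 10), collapse = ", ")
    ), class = "carenet_integrity_error")
  }
  dangling_pat <- setdiff(unique(events$patient_id), stays$patient_id)
  if (length(dangling_pat) > 0) {
    abort(sprintf(
      "Events reference patient_id(s) absent from the stays table: %s.",
      paste(head(dangling_pat, 10), collapse = ", ")
    ), class = "carenet_integrity_error")
  }

# An event is in-window if it falls inside any stay window of its patient
  # (multi-stay patients can appear before index-stay selection).
  win <- dplyr::select(stays, "patient_id", "admit_ts", "discharge_ts")
  events$.row <- seq_len(nrow(events))
  joined <- dplyr::left_join(events, win,
    by = "patient_id", relationship = "many-to-many"
  )
  inw <- joined$timestamp >= joined$admit_ts & joined$timestamp <= joined$discharge_ts
  in_window <- tapply(inw, joined$.row, any)
  events$in_window <- as.logical(in_window[as.character(events$.row)])
  events$.row <- NULL
  n_out <- sum(!events$in_window)
  if (n_out > 0) {
    if (strict) {
      events <- events[events$in_window, , drop = FALSE]
      inform(sprintf("Dropped %d event(s) outside their stay window (strict mode).", n_out))
    } else {
      warn(sprintf(
        "%d event(s) fall outside their stay's admission-discharge window; retained and flagged in `in_window`.",
        n_out
      ), class = "carenet_window_warning")
    }
  }

  structure(
    list(events = events, roster = roster, stays = stays),
    class = "audit_log"
  )
}

#' @export
print.audit_log <- function(x, ...) {
  cat(sprintf(
    "<audit_log> %d events | %d HCWs (%d expertise categories) | %d stays (%s)\n",
    nrow(x$events), nrow(x$roster), dplyr::n_distinct(x$roster$expertise),
    nrow(x$stays),
    paste(sprintf("%s: %d", arm_levels(),
      tabulate(factor(x$stays$arm, arm_levels()), 2L)
    ), collapse = ", ")
  ))
  invisible(x)
}

csv_col_types <- list(
  events = readr::cols(
    hcw_id = readr::col_character(), patient_id = readr::col_character(),
    timestamp = readr::col_datetime(), action_category = readr::col_character()
  ),
  roster = readr::cols(.default = readr::col_character()),
  stays = readr::cols(
    patient_id = readr::col_character(), arm = readr::col_character(),
    admit_ts = readr::col_datetime(), discharge_ts = readr::col_datetime(),
    age = readr::col_double(), sex = readr::col_character(),
    .default = readr::col_character()
  )
)

read_table_checked <- function(path, what) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "carenet_io_error")
  }
  df <- readr::read_csv(path, col_types = csv_col_types[[what]])
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(sprintf("Malformed %s CSV at %s (%d parsing problem(s)).", what, path, nrow(prob)),
      class = "carenet_io_error"
    )
  }
  check_schema(df, what)
  df
}

#' Read an audit log from its three canonical CSV files
#'
#' The only ingestion path is the canonical CSV schema (no vendor audit-log
#' dialects): `events.csv` (`hcw_id, patient_id, timestamp, action_category`),
#' `roster.csv` (`hcw_id, hcw_type, specialty`), and `stays.csv`
#' (`patient_id, arm, admit_ts, discharge_ts, age, sex`). Timestamps are
#' ISO 8601. See [audit_log()] for the validation rules.
#'
#' @param events_path,roster_path,stays_path Paths to the three CSV files.
#' @inheritParams audit_log
#' @return A validated [audit_log()].
#' @export
read_audit_log <- function(events_path, roster_path, stays_path, strict = FALSE) {
  audit_log(
    events = read_table_checked(events_path, "events"),
    roster = read_table_checked(roster_path, "roster"),
    stays = read_table_checked(stays_path, "stays"),
    strict = strict
  )
}

#' Write an audit log to the three canonical CSV files
#'
#' Emits RFC 4180 CSV with a header row and ISO 8601 timestamps, such that
#' [read_audit_log()] round-trips the log field-for-field.
#'
#' @param log An [audit_log()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths written.
#' @export
write_audit_log <- function(log, dir) {
  stopifnot(inherits(log, "audit_log"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    events = file.path(dir, "events.csv"),
    roster = file.path(dir, "roster.csv"),
    stays = file.path(dir, "stays.csv")
  )
  readr::write_csv(
    dplyr::select(log$events, "hcw_id", "patient_id", "timestamp", "action_category"),
    paths[["events"]]
  )
  readr::write_csv(
    dplyr::select(log$roster, "hcw_id", "hcw_type", "specialty"),
    paths[["roster"]]
  )
  readr::write_csv(
    dplyr::select(
      log$stays, "patient_id", "stay_id", "arm", "admit_ts", "discharge_ts",
      "age", "sex"
    ),
    paths[["stays"]]
  )
  invisible(paths)
}

# Stays of one arm, as a tibble; `arm = NULL` returns all stays.
arm_stays <- function(log, arm = NULL) {
  stopifnot(inherits(log, "audit_log"))
  if (is.null(arm)) {
    return(log$stays)
  }
  arm <- match.arg(arm, arm_levels())
  dplyr::filter(log$stays, .data$arm == !!arm)
}

# Events of one arm, joined with stay_id and the HCW's expertise.
arm_events <- function(log, arm = NULL) {
  st <- arm_stays(log, arm)
  ev <- dplyr::inner_join(
    log$events,
    dplyr::select(st, "patient_id", "stay_id"),
    by = "patient_id"
  )
  dplyr::left_join(
    ev,
    dplyr::select(log$roster, "hcw_id", "expertise", "specialty", "hcw_type"),
    by = "hcw_id"
  )
}

#' Restrict an audit log to a subset of stays
#'
#' Keeps only the given stays, their events, and the HCWs active on them.
#'
#' @param log An [audit_log()].
#' @param stay_ids Character vector of `stay_id`s to keep.
#' @return A new [audit_log()].
#' @export
filter_stays <- function(log, stay_ids) {
  stopifnot(inherits(log, "audit_log"))
  stays <- dplyr::filter(log$stays, .data$stay_id %in% stay_ids)
  events <- dplyr::filter(log$events, .data$patient_id %in% stays$patient_id)
  roster <- dplyr::filter(log$roster, .data$hcw_id %in% unique(events$hcw_id))
  structure(list(events = events, roster = roster, stays = stays), class = "audit_log")
}
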