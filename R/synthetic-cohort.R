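# Seeded synthetic audit-log generator. Emulates the statistical structure
# the downstream analysis assumes: a matched two-arm cohort of ICU stays,
# an expertise roster with archetype-structured patient assignment, and
# per-patient-day staffing draws with planted arm-specific effects.

hcw_archetypes <- c("core", "bridge", "peripheral", "trainee")

# Dirichlet concentration of an HCW's patient-affinity weights, by archetype.
# Core (and trainee) staff are near-daily repeaters on a small patient set;
# bridge staff spread across many patients; peripheral staff are in between
# but sparse by virtue of low participation rates.
archetype_concentration <- c(
  core = 0.1, trainee = 0.1, bridge = 25, peripheral = 1
)

#' Default expertise roster for the simulator
#'
#' Eleven expertise categories ("specialty: type") spanning the staff mix of
#' a COVID-era medical ICU: core internal-medicine physicians, bridging
#' internal-medicine nurse practitioners, trainee residents, and peripheral
#' nursing, pharmacy, and consulting categories. `pool_*` is the number of
#' distinct HCWs available per arm; `rate_*` is the expected number of HCWs
#' of that expertise acting on a given patient-day.
#'
#' @return A tibble with columns `specialty`, `hcw_type`, `archetype`,
#'   `pool_covid`, `pool_non_covid`, `rate_covid`, `rate_non_covid`,
#'   `expertise`.
#' @export
default_roster_spec <- function() {
  spec <- tibble::tribble(
    ~specialty, ~hcw_type, ~archetype, ~pool, ~rate,
    "internal medicine", "physician", "core", 10L, 0.9,
    "internal medicine", "nurse practitioner", "bridge", 12L, 0.5,
    "medical intensive care unit", "registered nurse", "peripheral", 40L, 1.0,
    "medicine house staff", "resident physician", "trainee", 14L, 0.8,
    "respiratory care", "respiratory therapist", "peripheral", 18L, 0.8,
    "pharmacy inpatient", "pharmacist", "peripheral", 15L, 0.25,
    "radiology", "physician", "peripheral", 20L, 0.35,
    "emergency medicine", "physician", "peripheral", 15L, 0.3,
    "allergy/pulmonary", "physician", "peripheral", 8L, 0.8,
    "cardiovascular medicine", "physician", "peripheral", 12L, 0.2,
    "nephrology", "physician", "peripheral", 10L, 0.15
  )
  dplyr::mutate(spec,
    pool_covid = .data$pool, pool_non_covid = .data$pool,
    rate_covid = .data$rate, rate_non_covid = .data$rate,
    pool = NULL, rate = NULL,
    expertise = expertise_label(.data$specialty, .data$hcw_type)
  )
}

#' Define a simulation scenario
#'
#' A scenario fixes every distributional choice of the synthetic audit-log
#' generator. Defaults emulate the study conditions of a matched two-arm
#' critical-care cohort: 38 stays per arm, log-normal length of stay with
#' median 13.5 days (SD about 10), age centred at 54 years (SD 12, truncated
#' to 18--95), 23/38 probability of male sex, and the 11-category roster of
#' [default_roster_spec()].
#'
#' @param n_stays_per_arm Stays per arm (default 38).
#' @param los_meanlog,los_sdlog Log-normal length-of-stay parameters in days
#'   (defaults `log(13.5)`, `0.6`).
#' @param age_mean,age_sd Normal age parameters in years, truncated to
#'   `[18, 95]`.
#' @param sex_ratio Probability a stay is male (default `23/38`).
#' @param twin_age_sd,twin_los_sdlog Perturbation scales used to construct
#'   each non-covid stay as a covariate-matched twin of a covid stay
#'   (additive years; multiplicative log-days).
#' @param covid_window,non_covid_window Length-2 character vectors of
#'   admission-window dates per arm.
#' @param roster_spec Roster tibble as in [default_roster_spec()].
#' @param actions_per_hcw_day Mean number of events an active HCW generates
#'   on a patient-day (each active HCW emits at least one).
#' @param effect_multipliers Tibble `(expertise, arm, multiplier)` of planted
#'   per-arm participation-rate ratios; empty means all multipliers are 1.
#' @param seed Default integer seed for [simulate_audit_log()].
#' @return A `simulation_scenario` object (a validated list).
#' @export
simulation_scenario <- function(n_stays_per_arm = 38L,
                                los_meanlog = log(13.5), los_sdlog = 0.6,
                                age_mean = 54, age_sd = 12,
                                sex_ratio = 23 / 38,
                                twin_age_sd = 2, twin_los_sdlog = 0.08,
                                covid_window = c("2020-03-17", "2020-05-31"),
                                non_covid_window = c("2019-12-01", "2020-02-29"),
                                roster_spec = default_roster_spec(),
                                actions_per_hcw_day = 4,
                                effect_multipliers = NULL,
                                seed = 1L) {
  if (is.null(effect_multipliers)) {
    effect_multipliers <- tibble(
      expertise = character(), arm = character(), multiplier = numeric()
    )
  }
  scenario <- structure(
    list(
      n_stays_per_arm = as.integer(n_stays_per_arm),
      los_meanlog = los_meanlog, los_sdlog = los_sdlog,
      age_mean = age_mean, age_sd = age_sd,
      sex_ratio = sex_ratio,
      twin_age_sd = twin_age_sd, twin_los_sdlog = twin_los_sdlog,
      covid_window = covid_window, non_covid_window = non_covid_window,
      roster_spec = as_tibble(roster_spec),
      actions_per_hcw_day = actions_per_hcw_day,
      effect_multipliers = as_tibble(effect_multipliers),
      seed = as.integer(seed)
    ),
    class = "simulation_scenario"
  )
  validate_scenario(scenario)
}

validate_scenario <- function(scenario) {
  s <- scenario
  if (s$n_stays_per_arm < 1) {
    abort("n_stays_per_arm must be >= 1.", class = "carenet_config_error")
  }
  if (s$los_sdlog <= 0 || s$age_sd <= 0) {
    abort("Distribution scale parameters must be strictly positive.",
      class = "carenet_config_error"
    )
  }
  if (s$sex_ratio < 0 || s$sex_ratio > 1) {
    abort("sex_ratio must be a probability.", class = "carenet_config_error")
  }
  if (s$actions_per_hcw_day < 1) {
    abort("actions_per_hcw_day must be >= 1 (an active HCW emits at least one event).",
      class = "carenet_config_error"
    )
  }
  rs <- s$roster_spec
  needed <- c(
    "specialty", "hcw_type", "archetype", "pool_covid", "pool_non_covid",
    "rate_covid", "rate_non_covid"
  )
  missing <- setdiff(needed, names(rs))
  if (length(missing) > 0) {
    abort(sprintf("roster_spec is missing column(s): %s.", paste(missing, collapse = ", ")),
      class = "carenet_config_error"
    )
  }
  if (!"expertise" %in% names(rs)) {
    rs$expertise <- expertise_label(rs$specialty, rs$hcw_type)
    scenario$roster_spec <- rs
  }
  if (!all(rs$archetype %in% hcw_archetypes)) {
    abort(sprintf("Unknown archetype(s); valid: %s.", paste(hcw_archetypes, collapse = ", ")),
      class = "carenet_config_error"
    )
  }
  if (any(rs$pool_covid < 0 | rs$pool_non_covid < 0) ||
    any(rs$rate_covid < 0 | rs$rate_non_covid < 0)) {
    abort("Pool sizes and participation rates must be non-negative.",
      class = "carenet_config_error"
    )
  }
  for (a in arm_levels()) {
    lam <- effective_rates(scenario, a)
    pool <- rs[[paste0("pool_", a)]]
    bad <- which(lam > pool)
    if (length(bad) > 0) {
      abort(sprintf(
        "Effective participation rate exceeds pool size for %s in arm %s.",
        paste(rs$expertise[bad], collapse = ", "), a
      ), class = "carenet_config_error")
    }
  }
  scenario
}

# Per-expertise participation rate for one arm, with planted multipliers
# applied.
effective_rates <- function(scenario, arm) {
  rs <- scenario$roster_spec
  lam <- rs[[paste0("rate_", arm)]]
  em <- scenario$effect_multipliers
  if (nrow(em) > 0) {
    em <- dplyr::filter(em, .data$arm == !!arm)
    idx <- match(rs$expertise, em$expertise)
    mult <- ifelse(is.na(idx), 1, em$multiplier[idx])
    lam <- lam * mult
  }
  lam
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf(
    "<simulation_scenario> %d stays/arm | %d expertise categories | %d planted multiplier(s) | seed %d\n",
    x$n_stays_per_arm, nrow(x$roster_spec), nrow(x$effect_multipliers), x$seed
  ))
  invisible(x)
}

#' Null version of a scenario (arms exchangeable)
#'
#' Returns a copy in which the two arms are statistically exchangeable:
#' all planted effect multipliers are cleared, per-arm participation rates
#' are replaced by their across-arm mean, and per-arm pool sizes by their
#' across-arm maximum. Idempotent. Used for type-I-error simulations.
#'
#' @param scenario A [simulation_scenario()].
#' @return A `simulation_scenario`.
#' @export
null_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  rs <- scenario$roster_spec
  rate <- (rs$rate_covid + rs$rate_non_covid) / 2
  pool <- pmax(rs$pool_covid, rs$pool_non_covid)
  rs$rate_covid <- rate
  rs$rate_non_covid <- rate
  rs$pool_covid <- pool
  rs$pool_non_covid <- pool
  scenario$roster_spec <- rs
  scenario$effect_multipliers <- tibble(
    expertise = character(), arm = character(), multiplier = numeric()
  )
  validate_scenario(scenario)
}

#' Scenario with the default planted team-structure effects
#'
#' Starting from `scenario`, plants the two structural contrasts the
#' simulator is designed to carry: a participation-rate multiplier
#' (default 3) for the internal-medicine nurse-practitioner category in the
#' covid arm, and removal of trainees (resident pool and rate set to 0) from
#' the covid arm.
#'
#' @param scenario Base [simulation_scenario()].
#' @param np_multiplier Covid-arm rate multiplier for
#'   `"internal medicine: nurse practitioner"`.
#' @param remove_trainees_from Arm whose trainee pool is zeroed (`"covid"`
#'   by default; `NULL` keeps trainees in both arms).
#' @return A `simulation_scenario`.
#' @export
planted_scenario <- function(scenario = simulation_scenario(),
                             np_multiplier = 3,
                             remove_trainees_from = "covid") {
  stopifnot(inherits(scenario, "simulation_scenario"))
  scenario$effect_multipliers <- dplyr::bind_rows(
    scenario$effect_multipliers,
    tibble(
      expertise = "internal medicine: nurse practitioner",
      arm = "covid", multiplier = np_multiplier
    )
  )
  if (!is.null(remove_trainees_from)) {
    arm <- match.arg(remove_trainees_from, arm_levels())
    rs <- scenario$roster_spec
    tr <- rs$archetype == "trainee"
    rs[[paste0("pool_", arm)]][tr] <- 0L
    rs[[paste0("rate_", arm)]][tr] <- 0
    scenario$roster_spec <- rs
  }
  validate_scenario(scenario)
}

date_window <- function(w) {
  as_instant(paste(w, c("00:00:00", "23:59:59")))
}

#' Generate a matched two-arm cohort of patient stays
#'
#' Draws `n_stays_per_arm` covid stays from the scenario's age, sex, and
#' length-of-stay distributions, then constructs each non-covid stay as a
#' covariate-matched twin of one covid stay (same sex; age and length of
#' stay perturbed at the scenario's twin scales) so the matching stage has
#' signal to recover. Admission instants are uniform over the per-arm
#' windows, giving stays whose calendar-day count generally differs from
#' their fractional length of stay.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Integer seed (defaults to the scenario's).
#' @return A tibble of stays (`stay_id`, `patient_id`, `arm`, `admit_ts`,
#'   `discharge_ts`, `age`, `sex`), `2 * n_stays_per_arm` rows.
#' @export
generate_cohort <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  n <- scenario$n_stays_per_arm
  withr::with_seed(seed, {
    los_c <- rlnorm(n, scenario$los_meanlog, scenario$los_sdlog)
    age_c <- pmin(pmax(round(rnorm(n, scenario$age_mean, scenario$age_sd)), 18), 95)
    sex <- ifelse(runif(n) < scenario$sex_ratio, "male", "female")
    los_n <- los_c * exp(rnorm(n, 0, scenario$twin_los_sdlog))
    age_n <- pmin(pmax(age_c + round(rnorm(n, 0, scenario$twin_age_sd)), 18), 95)

    wc <- date_window(scenario$covid_window)
    wn <- date_window(scenario$non_covid_window)
    admit_c <- wc[1] + round(runif(n) * as.numeric(difftime(wc[2], wc[1], units = "secs")))
    admit_n <- wn[1] + round(runif(n) * as.numeric(difftime(wn[2], wn[1], units = "secs")))

    covid <- tibble(
      stay_id = sprintf("C%02d", seq_len(n)),
      patient_id = sprintf("C%02d", seq_len(n)),
      arm = "covid",
      admit_ts = admit_c,
      discharge_ts = admit_c + round(los_c * 86400),
      age = age_c, sex = sex
    )
    non_covid <- tibble(
      stay_id = sprintf("N%02d", seq_len(n)),
      patient_id = sprintf("N%02d", seq_len(n)),
      arm = "non_covid",
      admit_ts = admit_n,
      discharge_ts = admit_n + round(los_n * 86400),
      age = age_n, sex = sex
    )
    dplyr::bind_rows(covid, non_covid)
  })
}

slugify <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))

# Roster tibble for one arm: pool_covid/pool_non_covid expanded to HCW rows.
arm_roster <- function(scenario, arm) {
  rs <- scenario$roster_spec
  pool <- rs[[paste0("pool_", arm)]]
  tag <- if (arm == "covid") "c" else "n"
  purrr::pmap_dfr(
    list(rs$specialty, rs$hcw_type, pool),
    function(spec, type, p) {
      if (p == 0) {
        return(NULL)
      }
      tibble(
        hcw_id = sprintf("%s_%s_%s_%02d", slugify(spec), slugify(type), tag, seq_len(p)),
        hcw_type = type, specialty = spec
      )
    }
  )
}

#' Generate audit-log events for a cohort of stays
#'
#' For each (stay, calendar day, expertise), the number of active HCWs is
#' Poisson with the arm's effective participation rate (rate times any
#' planted multiplier), truncated at the pool size. Active HCWs are sampled
#' from the expertise pool with archetype-dependent patient-affinity
#' weights: core (and trainee) HCWs concentrate on a small set of stays and
#' therefore repeat near-daily on the same patients, bridge HCWs spread
#' across many stays, peripheral HCWs are uniform and sparse. Each active
#' HCW emits at least one event on the patient-day, with categories drawn
#' uniformly over [action_categories()] and timestamps uniform within the
#' day (clipped to the stay window on admission/discharge days).
#'
#' @param scenario A [simulation_scenario()].
#' @param stays A stays tibble from [generate_cohort()].
#' @param seed Integer seed.
#' @return A validated [audit_log()].
#' @export
generate_audit_log <- function(scenario, stays, seed = scenario$seed) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  stays <- as_tibble(stays)
  rs <- scenario$roster_spec
  apd <- scenario$actions_per_hcw_day

  withr::with_seed(seed, {
    rosters <- list()
    events <- list()
    for (arm in arm_levels()) {
      st <- dplyr::filter(stays, .data$arm == !!arm)
      roster <- arm_roster(scenario, arm)
      rosters[[arm]] <- roster
      if (nrow(st) == 0 || nrow(roster) == 0) next

      day_list <- purrr::map2(st$admit_ts, st$discharge_ts, stay_days)
      grid <- tibble(
        stay_idx = rep(seq_len(nrow(st)), lengths(day_list)),
        day = as.Date(unlist(day_list), origin = "1970-01-01")
      )
      n_pd <- nrow(grid)
      lam <- effective_rates(scenario, arm)
      pool <- rs[[paste0("pool_", arm)]]

      for (r in seq_len(nrow(rs))) {
        if (pool[r] == 0 || lam[r] == 0) next
        ids <- sprintf(
          "%s_%s_%s_%02d",
          slugify(rs$specialty[r]), slugify(rs$hcw_type[r]),
          if (arm == "covid") "c" else "n", seq_len(pool[r])
        )
        conc <- archetype_concentration[[rs$archetype[r]]]
        # Patient-affinity weights: one Dirichlet draw per HCW over stays.
        W <- matrix(
          rgamma(pool[r] * nrow(st), shape = conc) + 1e-12,
          nrow = pool[r]
        )
        k <- pmin(rpois(n_pd, lam[r]), pool[r])
        hit <- which(k > 0)
        if (length(hit) == 0) next
        chosen <- purrr::map2(hit, k[hit], function(g, kk) {
          si <- grid$stay_idx[g]
          if (kk >= pool[r]) {
            ids
          } else {
            sample(ids, kk, prob = W[, si])
          }
        })
        active <- tibble(
          hcw_id = unlist(chosen),
          stay_idx = rep(grid$stay_idx[hit], lengths(chosen)),
          day = rep(grid$day[hit], lengths(chosen))
        )
        n_ev <- 1L + rpois(nrow(active), apd - 1)
        ev <- active[rep(seq_len(nrow(active)), n_ev), ]
        day_start <- as_instant(ev$day)
        lo <- pmax(day_start, st$admit_ts[ev$stay_idx])
        hi <- pmin(day_start + 86399, st$discharge_ts[ev$stay_idx])
        ev$timestamp <- lo + round(runif(nrow(ev)) * as.numeric(hi - lo, units = "secs"))
        ev$action_category <- sample(action_categories(), nrow(ev), replace = TRUE)
        ev$patient_id <- st$patient_id[ev$stay_idx]
        events[[length(events) + 1]] <- dplyr::select(
          ev, "hcw_id", "patient_id", "timestamp", "action_category"
        )
      }
    }
    events <- if (length(events) > 0) {
      dplyr::arrange(
        dplyr::bind_rows(events),
        .data$patient_id, .data$timestamp, .data$hcw_id, .data$action_category
      )
    } else {
      tibble(
        hcw_id = character(), patient_id = character(),
        timestamp = as_instant(character()), action_category = character()
      )
    }
    roster <- dplyr::bind_rows(rosters)
    audit_log(events, roster, stays)
  })
}

#' Simulate a complete audit log from a scenario
#'
#' Convenience wrapper: [generate_cohort()] then [generate_audit_log()],
#' with the event-generation seed derived deterministically from `seed`.
#'
#' @inheritParams generate_cohort
#' @return A validated [audit_log()].
#' @export
simulate_audit_log <- function(scenario, seed = scenario$seed) {
  stays <- generate_cohort(scenario, seed)
  generate_audit_log(scenario, stays, seed = (seed %% 1000000007L) + 1L)
}

#' Read a simulation scenario from a YAML or JSON file
#'
#' The file's top-level keys map onto the arguments of
#' [simulation_scenario()]; `roster_spec` and `effect_multipliers` are given
#' as lists of records. Omitted keys take the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return A `simulation_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Scenario file not found: %s", path), class = "carenet_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$roster_spec) && !is.data.frame(raw$roster_spec)) {
    raw$roster_spec <- dplyr::bind_rows(lapply(raw$roster_spec, as_tibble))
  }
  if (!is.null(raw$effect_multipliers) && !is.data.frame(raw$effect_multipliers)) {
    raw$effect_multipliers <- dplyr::bind_rows(lapply(raw$effect_multipliers, as_tibble))
  }
  known <- names(formals(simulation_scenario))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown scenario field(s): %s.", paste(unknown, collapse = ", ")),
      class = "carenet_config_error"
    )
  }
  do.call(simulation_scenario, raw)
}
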