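test_that("generate_cohort returns balanced arms with the configured structure", {
  sc <- simulation_scenario()
  stays <- generate_cohort(sc, seed = 7)
  expect_identical(nrow(stays), 76L)
  expect_identical(sum(stays$arm == "covid"), 38L)
  expect_identical(sum(stays$arm == "non_covid"), 38L)
  expect_true(all(stays$discharge_ts > stays$admit_ts))

  all_male <- generate_cohort(simulation_scenario(sex_ratio = 1), seed = 3)
  expect_true(all(all_male$sex == "male"))

  expect_equal(generate_cohort(sc, seed = 11), generate_cohort(sc, seed = 11))
})

test_that("twin construction gives the matching stage signal to recover", {
  stays <- generate_cohort(simulation_scenario(), seed = 5)
  covid <- stays[stays$arm == "covid", ]
  non <- stays[stays$arm == "non_covid", ]
  expect_identical(covid$sex, non$sex)
  expect_lt(mean(abs(covid$age - non$age)), 3 * 2) # twin_age_sd = 2
  los_c <- los_days(covid$admit_ts, covid$discharge_ts)
  los_n <- los_days(non$admit_ts, non$discharge_ts)
  expect_gt(cor(los_c, los_n), 0.9)
})

test_that("scenario validation rejects degenerate parameters", {
  expect_error(simulation_scenario(los_sdlog = 0), class = "carenet_config_error")
  expect_error(simulation_scenario(sex_ratio = 1.2), class = "carenet_config_error")
  rs <- default_roster_spec()
  rs$rate_covid[1] <- rs$pool_covid[1] + 5 # rate above pool size
  expect_error(simulation_scenario(roster_spec = rs), class = "carenet_config_error")
})

test_that("the generator is calibrated: active-HCW counts match the configured rate", {
  # One expertise, many patient-days; empirical mean within 3 SE of lambda.
  rs <- default_roster_spec()[3, ] # MICU RN pool, peripheral
  rs$rate_covid <- 2
  rs$rate_non_covid <- 2
  sc <- simulation_scenario(
    n_stays_per_arm = 20L, los_meanlog = log(14), los_sdlog = 0.3,
    roster_spec = rs
  )
  stays <- generate_cohort(sc, seed = 9)
  log <- generate_audit_log(sc, stays, seed = 10)
  covid_stays <- stays[stays$arm == "covid", ]
  n_days <- sum(stay_day_count(covid_stays$admit_ts, covid_stays$discharge_ts))
  active <- log$events |>
    dplyr::inner_join(covid_stays[, "patient_id"], by = "patient_id") |>
    dplyr::mutate(day = day_bin(timestamp)) |>
    dplyr::distinct(hcw_id, patient_id, day)
  emp <- nrow(active) / n_days
  se <- sqrt(2 / n_days)
  expect_lt(abs(emp - 2), 3 * se)
})

test_that("planted multipliers scale one arm's participation rate", {
  sc <- planted_scenario(
    simulation_scenario(n_stays_per_arm = 25L),
    np_multiplier = 3, remove_trainees_from = "covid"
  )
  log <- simulate_audit_log(sc, seed = 21)
  np <- "internal medicine: nurse practitioner"
  rate_of <- function(arm) {
    st <- log$stays[log$stays$arm == arm, ]
    ev <- log$events |>
      dplyr::inner_join(st[, "patient_id"], by = "patient_id") |>
      dplyr::left_join(log$roster[, c("hcw_id", "expertise")], by = "hcw_id") |>
      dplyr::filter(expertise == np) |>
      dplyr::mutate(day = day_bin(timestamp)) |>
      dplyr::distinct(hcw_id, patient_id, day)
    nrow(ev) / sum(stay_day_count(st$admit_ts, st$discharge_ts))
  }
  ratio <- rate_of("covid") / rate_of("non_covid")
  expect_gt(ratio, 2)
  expect_lt(ratio, 4.5)

  # trainee pool zeroed in the covid arm -> no trainee events there
  trainees <- log$roster$hcw_id[log$roster$hcw_type == "resident physician"]
  covid_patients <- log$stays$patient_id[log$stays$arm == "covid"]
  expect_identical(
    sum(log$events$hcw_id %in% trainees & log$events$patient_id %in% covid_patients),
    0L
  )
})

test_that("null_scenario clears multipliers, equalizes arms, and is idempotent", {
  sc <- planted_scenario()
  nul <- null_scenario(sc)
  expect_identical(nrow(nul$effect_multipliers), 0L)
  expect_identical(nul$roster_spec$rate_covid, nul$roster_spec$rate_non_covid)
  expect_identical(nul$roster_spec$pool_covid, nul$roster_spec$pool_non_covid)
  expect_equal(null_scenario(nul), nul)
})

test_that("identical scenario and seed give byte-identical audit-log CSVs", {
  sc <- small_scenario()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_audit_log(simulate_audit_log(sc, seed = 13), d1)
  write_audit_log(simulate_audit_log(sc, seed = 13), d2)
  for (f in c("events.csv", "roster.csv", "stays.csv")) {
    expect_identical(
      readLines(file.path(d1, f)),
      readLines(file.path(d2, f))
    )
  }
})

test_that("every simulated event falls inside its stay window", {
  log <- simulate_audit_log(small_scenario(), seed = 17)
  expect_true(all(log$events$in_window))
})

test_that("scenario files round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(
    list(n_stays_per_arm = 10, sex_ratio = 0.5, seed = 4),
    path
  )
  sc <- read_scenario(path)
  expect_s3_class(sc, "simulation_scenario")
  expect_identical(sc$n_stays_per_arm, 10L)
  expect_identical(sc$seed, 4L)
  expect_equal(sc$roster_spec, default_roster_spec())

  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(not_a_field = 1), bad)
  expect_error(read_scenario(bad), class = "carenet_config_error")
})
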