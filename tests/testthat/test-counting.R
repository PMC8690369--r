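test_that("age classes partition ages by completed years", {
  expect_identical(as.character(age_class(33)), "30-34")
  expect_identical(as.character(age_class(61)), ">=60")
  expect_identical(as.character(age_class(60)), ">=60")
  expect_identical(as.character(age_class(24.9)), "18-24")
  expect_identical(as.character(age_class(25)), "25-29")
  expect_warning(cl <- age_class(17), "below 18")
  expect_identical(as.character(cl), "18-24")
  expect_identical(nlevels(age_class(30)), 9L)
})

## one-patient bundle with a fully controlled timeline:
## index stay days -17..-7 (10 nights, forms the index episode),
## anchor end (= at-risk start) day 0
timeline_bundle <- function(stay2 = NULL, death_day = NA, end_day = 400) {
  hosp <- mk_stays("A", -17, -7)
  if (!is.null(stay2)) hosp <- dplyr::bind_rows(hosp, mk_stays("A", stay2[1], stay2[2]))
  registry_bundle(
    patients = tibble::tibble(patient_id = "A", sex = "M",
                              birth_date = as.Date("1980-01-01"),
                              death_date = if (is.na(death_day)) as.Date(NA) else D0 + death_day),
    hospitalisations = hosp,
    outpatient_visits = mk_visits("A", -10, code = "F20.1"),
    dispensations = mk_disp("A", -15, "N05AH03"),
    study_start = "2006-01-01", study_end = D0 + end_day
  )
}

rows_for <- function(bundle, timescale = "gap", split = FALSE, K_max = 10) {
  cohort <- build_cohort(bundle,
                         cohort_config(bundle$study_start, bundle$study_end))
  eps <- identify_episodes(bundle, "primary")
  build_counting_data(bundle, cohort, eps, K_max = K_max, timescale = timescale,
                      split_covariates = split)
}

test_that("clock rules: at-risk spans, relapse events and stratum entries", {
  ## next episode starts day 200 (stay 200-210, episode end 217)
  cp <- rows_for(timeline_bundle(stay2 = c(200, 210)))
  expect_identical(cp$stratum, c(0L, 1L))
  expect_equal(cp$entry, c(0, 0))
  expect_equal(cp$exit, c(200 / 365.25, (400 - 217) / 365.25))
  expect_identical(as.character(cp$event), c("relapse", "censored"))
  ## gap clock restarts at the second episode's end
  expect_equal(cp$origin_day[2] - cp$origin_day[1], 217)

  ## on the from-index timescale the second row continues the same clock
  cpf <- rows_for(timeline_bundle(stay2 = c(200, 210)), timescale = "from_index")
  expect_equal(cpf$entry, c(0, 217 / 365.25))
  expect_equal(cpf$exit, c(200 / 365.25, 400 / 365.25))
})

test_that("death inside an at-risk interval is a competing event", {
  cp <- rows_for(timeline_bundle(death_day = 100))
  expect_identical(nrow(cp), 1L)
  expect_identical(as.character(cp$event), "death")
  expect_equal(cp$exit, 100 / 365.25)
})

test_that("no at-risk row opens inside the post-episode censor window", {
  ## discharge (day 217) lands 3 days before follow-up end (day 220): the
  ## 7-day quiet window overruns follow-up and stratum 1 never opens
  cp <- rows_for(timeline_bundle(stay2 = c(200, 217), end_day = 220))
  expect_identical(cp$stratum, 0L)
  expect_identical(as.character(cp$event), "relapse")
})

test_that("stratum truncation stops the contribution after K_max", {
  sim <- simulate_cohort(quick_params(n = 150, seed = 23))
  cohort <- suppressMessages(build_cohort(sim$bundle))
  eps <- identify_episodes(sim$bundle, "primary")
  cp <- build_counting_data(sim$bundle, cohort, eps, K_max = 3, timescale = "gap",
                            split_covariates = FALSE)
  expect_lte(max(cp$stratum), 3)
  ## a patient enters stratum k only after a relapse event in stratum k-1
  by_pat <- split(cp, cp$patient_id)
  for (d in by_pat) {
    expect_identical(sort(unique(d$stratum)), seq(0L, max(d$stratum)))
    for (k in setdiff(unique(d$stratum), 0L)) {
      expect_true(any(d$stratum == k - 1 & d$event == "relapse"))
    }
  }
  ## at-risk counts are non-increasing in k
  n_k <- table(factor(cp$stratum, levels = 0:3))
  expect_true(all(diff(as.integer(n_k)) <= 0))
})

test_that("covariate splitting preserves at-risk time and events exactly", {
  sim <- simulate_cohort(quick_params(n = 200, seed = 29))
  cohort <- suppressMessages(build_cohort(sim$bundle))
  eps <- identify_episodes(sim$bundle, "primary")
  u <- build_counting_data(sim$bundle, cohort, eps, timescale = "gap",
                           split_covariates = FALSE)
  s <- build_counting_data(sim$bundle, cohort, eps, timescale = "gap",
                           split_covariates = TRUE)
  agg <- function(d) {
    d |>
      dplyr::group_by(patient_id, stratum) |>
      dplyr::summarise(t = sum(exit - entry), ev = sum(event == "relapse"),
                       .groups = "drop") |>
      dplyr::arrange(patient_id, stratum)
  }
  expect_equal(agg(s), agg(u), tolerance = 1e-12, ignore_attr = TRUE)

  ## sub-rows are strictly increasing intervals
  expect_true(all(s$exit > s$entry))
  ## age class matches a from-scratch computation and is constant on the row
  birth <- sim$bundle$patients$birth_date[match(s$patient_id, sim$bundle$patients$patient_id)]
  age_at_entry <- (s$entry_day - as.numeric(birth - sim$bundle$study_start)) / 365.25
  expect_identical(as.character(s$age_class),
                   as.character(suppressWarnings(age_class(age_at_entry))))
  age_at_last <- (s$exit_day - 1 - as.numeric(birth - sim$bundle$study_start)) / 365.25
  expect_identical(as.character(s$age_class),
                   as.character(suppressWarnings(age_class(pmax(age_at_last, age_at_entry)))))
})

test_that("per-patient day accounting balances exactly", {
  for (seed in c(3, 41)) {
    sim <- simulate_cohort(quick_params(n = 150, seed = seed))
    cohort <- suppressMessages(build_cohort(sim$bundle))
    for (proxy in c("primary", "primary30")) {
      eps <- identify_episodes(sim$bundle, proxy)
      audit <- audit_time_accounting(sim$bundle, cohort, eps)
      expect_identical(nrow(audit), sum(cohort$included))
      expect_true(all(audit$balance == 0))
    }
  }
})
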