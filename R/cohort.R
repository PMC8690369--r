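## min/max over possibly empty date vectors (dplyr probes summarise
## expressions on an empty slice, which would warn through min.default)
min_date <- function(x) if (length(x)) min(x) else as.Date(NA)
max_date <- function(x) if (length(x)) max(x) else as.Date(NA)

#' Cohort configuration
#'
#' Inclusion and exclusion settings for [build_cohort()]. The main (incident)
#' variant requires, within the study window: at least two schizophrenia
#' diagnosis records (inpatient or outpatient, primary or secondary), at
#' least one filled antipsychotic prescription (ATC N05A), and at least one
#' discharge from a psychiatric hospitalisation with at least one overnight
#' stay; it excludes patients whose first-ever schizophrenia diagnosis or
#' first-ever psychiatric hospital discharge predates the window, and
#' patients older than `max_age_at_first_dx` (in completed years) at their
#' first schizophrenia diagnosis. Age exactly `max_age_at_first_dx` is
#' allowed.
#'
#' Variants: `"incident_2dx"` (the main analysis), `"ge1_dx"` (one diagnosis
#' record suffices; always a superset of the main cohort), and
#' `"include_prevalent"` (pre-window history back to `history_start` does not
#' exclude; it is instead used for the index episode and relapse-history
#' accounting, so follow-up may begin before the study window).
#'
#' @param study_start,study_end Study window (dates).
#' @param variant One of `"incident_2dx"`, `"ge1_dx"`, `"include_prevalent"`.
#' @param max_age_at_first_dx Upper age bound, completed years (default 60).
#' @param min_schizophrenia_dx Required diagnosis-record count (2 for the
#'   main variant, 1 for `ge1_dx`; derived from `variant` when `NULL`).
#' @param require_ap_prescription Require one filled N05A prescription.
#' @param history_start Start of the pre-window lookback (default 1987-01-01).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(study_start = "2006-01-01",
                          study_end = "2015-12-31",
                          variant = c("incident_2dx", "ge1_dx", "include_prevalent"),
                          max_age_at_first_dx = 60,
                          min_schizophrenia_dx = NULL,
                          require_ap_prescription = TRUE,
                          history_start = "1987-01-01") {
  variant <- match.arg(variant)
  if (is.null(min_schizophrenia_dx)) {
    min_schizophrenia_dx <- if (variant == "ge1_dx") 1L else 2L
  }
  if (min_schizophrenia_dx < 1L) {
    abort("`min_schizophrenia_dx` must be >= 1")
  }
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (study_start >= study_end) abort("`study_start` must precede `study_end`")
  structure(
    list(study_start = study_start, study_end = study_end, variant = variant,
         max_age_at_first_dx = max_age_at_first_dx,
         min_schizophrenia_dx = as.integer(min_schizophrenia_dx),
         require_ap_prescription = isTRUE(require_ap_prescription),
         history_start = as.Date(history_start)),
    class = "cohort_config"
  )
}

#' Index episode of one or more patients
#'
#' The index date anchoring follow-up is the discharge from the
#' chronologically first psychiatric-coded hospitalisation with at least one
#' overnight stay (discharge strictly after admission; day-precision data
#' cannot distinguish hours) whose discharge falls inside the window.
#'
#' @param hospitalisations Hospitalisation rows (any patients; diagnosis
#'   codes are classified internally with [is_psychiatric_dx()]).
#' @param config A [cohort_config()]; under the `include_prevalent` variant
#'   the search window opens at `history_start`.
#' @return A tibble with one row per patient that has an index episode:
#'   `patient_id`, `index_date`.
#' @export
find_index_episode <- function(hospitalisations, config = cohort_config()) {
  window_start <- if (config$variant == "include_prevalent") config$history_start else config$study_start
  hospitalisations |>
    filter(
      is_psychiatric_dx(diagnosis_code, code_system),
      .data$discharge_date > .data$admission_date,
      .data$discharge_date >= window_start,
      .data$discharge_date <= config$study_end
    ) |>
    group_by(patient_id) |>
    summarise(index_date = min_date(.data$discharge_date), .groups = "drop")
}

#' Apply cohort inclusion and exclusion criteria
#'
#' Classifies every patient in the bundle as included (with an index date and
#' follow-up end) or excluded with a reason from a fixed enumeration:
#' `too_few_dx`, `no_ap_prescription`, `no_psych_hospitalisation`,
#' `prevalent_dx`, `prevalent_hospitalisation`, `age_over_limit`. Reasons are
#' assigned in that order of precedence and every patient appears exactly
#' once. Unparseable diagnosis codes classify as no match; their count is
#' reported with a message.
#'
#' @param bundle A [registry_bundle()].
#' @param config A [cohort_config()].
#' @return A tibble of class `relapse_cohort`: `patient_id`, `included`,
#'   `exclusion_reason` (`NA` when included), `index_date`, `follow_up_end`
#'   (`min(death date, study end)`), `sex`, `birth_date`, `death_date`,
#'   `first_dx_date`, `age_at_first_dx`.
#' @examples
#' sim <- simulate_cohort(sim_params(n_patients = 100, seed = 3))
#' cohort <- build_cohort(sim$bundle)
#' table(cohort$exclusion_reason, useNA = "ifany")
#' @export
build_cohort <- function(bundle, config = cohort_config()) {
  stopifnot(inherits(bundle, "registry_bundle"))
  stopifnot(inherits(config, "cohort_config"))

  dx <- bind_rows(
    bundle$hospitalisations |>
      transmute(patient_id, dx_date = .data$admission_date,
                diagnosis_code, code_system),
    bundle$outpatient_visits |>
      transmute(patient_id, dx_date = .data$visit_date,
                diagnosis_code, code_system)
  )
  n_unparsed <- sum(!grepl("^\\s*([A-Z][0-9]{2}|[0-9]{3})", dx$diagnosis_code,
                           ignore.case = TRUE))
  if (n_unparsed > 0) {
    message(sprintf("build_cohort: %d diagnosis code(s) unparseable under ICD-10/ICD-9; classified as no match", n_unparsed))
  }
  sz <- dx |> filter(is_schizophrenia_dx(diagnosis_code, code_system))

  dx_window_start <- if (config$variant == "include_prevalent") config$history_start else config$study_start
  sz_stats <- sz |>
    group_by(patient_id) |>
    summarise(
      n_dx_window = sum(.data$dx_date >= dx_window_start & .data$dx_date <= config$study_end),
      first_dx_date = min_date(.data$dx_date),
      .groups = "drop"
    )

  ap <- bundle$dispensations |>
    filter(is_antipsychotic(atc_code),
           .data$dispense_date >= min(config$study_start, dx_window_start),
           .data$dispense_date <= config$study_end) |>
    distinct(patient_id) |>
    mutate(has_ap = TRUE)

  index <- find_index_episode(bundle$hospitalisations, config)

  first_psych_discharge <- bundle$hospitalisations |>
    filter(is_psychiatric_dx(diagnosis_code, code_system),
           .data$discharge_date > .data$admission_date) |>
    group_by(patient_id) |>
    summarise(first_psych_discharge = min_date(.data$discharge_date), .groups = "drop")

  members <- bundle$patients |>
    left_join(sz_stats, by = "patient_id") |>
    left_join(ap, by = "patient_id") |>
    left_join(index, by = "patient_id") |>
    left_join(first_psych_discharge, by = "patient_id") |>
    mutate(
      n_dx_window = coalesce(.data$n_dx_window, 0L),
      has_ap = coalesce(.data$has_ap, FALSE),
      age_at_first_dx = floor(as.numeric(.data$first_dx_date - birth_date) / 365.25),
      exclusion_reason = case_when(
        n_dx_window < config$min_schizophrenia_dx ~ "too_few_dx",
        config$require_ap_prescription & !has_ap ~ "no_ap_prescription",
        is.na(index_date) ~ "no_psych_hospitalisation",
        config$variant != "include_prevalent" &
          .data$first_dx_date < config$study_start ~ "prevalent_dx",
        config$variant != "include_prevalent" &
          .data$first_psych_discharge < config$study_start ~ "prevalent_hospitalisation",
        .data$age_at_first_dx > config$max_age_at_first_dx ~ "age_over_limit",
        .default = NA_character_
      ),
      included = is.na(.data$exclusion_reason),
      index_date = if_else(.data$included, index_date, as.Date(NA)),
      follow_up_end = if_else(.data$included,
                              pmin(coalesce(death_date, config$study_end),
                                   config$study_end),
                              as.Date(NA))
    ) |>
    select(patient_id, included, exclusion_reason, index_date, follow_up_end,
           sex, birth_date, death_date, first_dx_date, age_at_first_dx)

  ## a patient dying before any qualifying index has no usable follow-up
  bad_fu <- members$included & members$follow_up_end < members$index_date
  if (any(bad_fu)) {
    members$included[bad_fu] <- FALSE
    members$exclusion_reason[bad_fu] <- "no_psych_hospitalisation"
    members$index_date[bad_fu] <- as.Date(NA)
    members$follow_up_end[bad_fu] <- as.Date(NA)
  }

  structure(members, class = c("relapse_cohort", class(members)),
            config = config)
}

#' @export
print.relapse_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<relapse_cohort> variant", if (is.null(cfg)) "?" else cfg$variant, "-",
      sum(x$included), "included /", nrow(x), "patients\n")
  excl <- table(x$exclusion_reason)
  if (length(excl)) {
    for (r in names(excl)) cat(sprintf("  excluded %-26s %d\n", r, excl[[r]]))
  }
  NextMethod()
}
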