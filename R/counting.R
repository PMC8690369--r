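#' Age classes used as a time-varying covariate
#'
#' Ordered classes 18-24, 25-29, ..., 55-59, >=60, partitioning ages by
#' completed years. Rows of the counting process are split where a birthday
#' crosses a class boundary. Ages below 18 (possible in synthetic data) fold
#' into the lowest class with a warning.
#'
#' @param age Numeric vector of ages in years.
#' @return Factor with the ordered class labels.
#' @examples
#' age_class(c(33, 24.9, 61))
#' @export
age_class <- function(age) {
  stopifnot(all(age >= 0, na.rm = TRUE))
  if (any(age < 18, na.rm = TRUE)) {
    warn("age_class: ages below 18 assigned to class 18-24")
  }
  breaks <- c(-Inf, seq(25, 60, by = 5), Inf)
  labels <- c("18-24", paste(seq(25, 55, 5), seq(29, 59, 5), sep = "-"), ">=60")
  cut(floor(age), breaks = breaks, labels = labels, right = FALSE)
}

.age_boundaries <- seq(25, 60, by = 5)

## per-patient at-risk intervals between episodes, before covariate splits.
## Returns the base rows plus the per-patient anchor bookkeeping.
counting_base <- function(bundle, cohort, episodes, merge_gap_days, K_max) {
  members <- cohort |>
    filter(.data$included) |>
    select(patient_id, index_date, follow_up_end, sex, birth_date, death_date)
  class(members) <- c("tbl_df", "tbl", "data.frame")
  if (!nrow(members)) {
    return(list(
      rows = tibble(patient_id = character(), k = integer(),
                    entry_day = numeric(), exit_day = numeric(), event = character()),
      members = members |> mutate(anchor_end_day = numeric(), fu_day = numeric(),
                                  index_day = numeric(), birth_day = numeric(),
                                  death = logical()),
      episodes = tibble(patient_id = character(), ordinal = integer(),
                        start_day = numeric(), end_day = numeric()),
      n_clipped = 0L
    ))
  }
  origin <- bundle$study_start

  psych <- bundle$hospitalisations |>
    filter(is_psychiatric_dx(diagnosis_code, code_system),
           patient_id %in% members$patient_id)
  clusters <- cluster_stays(psych, merge_gap_days)
  anchors <- clusters |>
    inner_join(members |> select(patient_id, index_date), by = "patient_id") |>
    filter(first_adm <= index_date, last_dis >= index_date) |>
    transmute(patient_id,
              anchor_end_day = as.numeric(last_dis + merge_gap_days - origin))

  m <- members |>
    inner_join(anchors, by = "patient_id") |>
    mutate(
      index_day = as.numeric(index_date - origin),
      fu_day = as.numeric(follow_up_end - origin),
      birth_day = as.numeric(birth_date - origin),
      death = !is.na(death_date) & death_date <= bundle$study_end
    )

  eps <- episodes |>
    inner_join(m |> select(patient_id, anchor_end_day, fu_day), by = "patient_id") |>
    mutate(start_day = as.numeric(as.Date(start) - origin),
           end_day = as.numeric(as.Date(end) - origin)) |>
    filter(start_day > .data$anchor_end_day)
  n_clipped <- sum(eps$start_day > eps$fu_day)
  eps <- eps |>
    filter(start_day <= fu_day) |>
    group_by(patient_id) |>
    arrange(start_day, .by_group = TRUE) |>
    mutate(ordinal = row_number()) |>
    ungroup() |>
    filter(.data$ordinal <= K_max + 1L) |>
    select(patient_id, ordinal, start_day, end_day)

  entries <- bind_rows(
    m |> transmute(patient_id, k = 0L, entry_day = .data$anchor_end_day),
    eps |> filter(.data$ordinal <= K_max) |>
      transmute(patient_id, k = .data$ordinal, entry_day = .data$end_day)
  )
  events <- eps |> transmute(patient_id, k = .data$ordinal - 1L,
                             event_day = .data$start_day)
  rows <- entries |>
    left_join(events, by = c("patient_id", "k")) |>
    left_join(m |> select(patient_id, fu_day, death), by = "patient_id") |>
    mutate(
      event = case_when(!is.na(.data$event_day) ~ "relapse",
                        death ~ "death",
                        .default = "censored"),
      exit_day = coalesce(.data$event_day, .data$fu_day)
    ) |>
    filter(entry_day < exit_day) |>
    select(patient_id, k, entry_day, exit_day, event) |>
    arrange(patient_id, k)

  list(rows = rows, members = m, episodes = eps, n_clipped = n_clipped)
}

#' Build recurrent-event counting-process data
#'
#' Converts cohort membership plus a relapse-episode stream into one at-risk
#' interval per patient per prior-relapse stratum, the representation both
#' the cause-specific Cox model and the Aalen-Johansen estimator consume.
#'
#' The clock anchoring follow-up starts at the end of the index episode: the
#' end of the first `merge_gap_days` consecutive days after the index
#' discharge without psychiatric readmission. At-risk time for the (k+1)-th
#' relapse begins at the end of the k-th episode; a relapse event is recorded
#' at the next episode's admission; time spent inside an episode -- including
#' its trailing quiet window, during which no event can occur by construction
#' -- is not at risk. Death inside an at-risk interval is a competing event
#' (`event = "death"`); reaching the end of follow-up is administrative
#' censoring. Strata run from 0 to `K_max` prior relapses; a relapse in
#' stratum `K_max` is recorded but opens no further stratum. Episodes that
#' begin before the index-episode end are excluded from ordinal numbering;
#' episodes starting after follow-up end are dropped with a warning.
#'
#' With `split_covariates = TRUE` rows are further split at calendar-year
#' boundaries and at birthdays crossing an age-class boundary, and carry the
#' time-varying covariates `prior_relapses`, `age_class`, `gender`,
#' `calendar_year`. Splitting never changes total at-risk time.
#'
#' Two timescales are supported: `"from_index"` (time since the index-episode
#' end; the Cox default) and `"gap"` (clock reset to 0 at each stratum's
#' entry; the Aalen-Johansen timescale and the gap-time Cox configuration).
#'
#' @param bundle A [registry_bundle()].
#' @param cohort A [build_cohort()] result.
#' @param episodes An [identify_episodes()] result (same bundle).
#' @param K_max Highest prior-relapse stratum (default 10).
#' @param timescale `"from_index"` or `"gap"`.
#' @param split_covariates Split rows and attach covariates (default `TRUE`).
#' @param merge_gap_days Quiet-period length closing an episode; defaults to
#'   the `episodes` attribute.
#' @return A tibble of class `counting_data`: `patient_id`, `stratum`,
#'   `entry`, `exit` (years on the chosen timescale), `event` (factor:
#'   censored/relapse/death), covariates (when split), and the day-precision
#'   bookkeeping columns `entry_day`, `exit_day`, `origin_day`.
#' @examples
#' sim <- simulate_cohort(sim_params(n_patients = 80, seed = 5))
#' cohort <- build_cohort(sim$bundle)
#' eps <- identify_episodes(sim$bundle, "primary")
#' cp <- build_counting_data(sim$bundle, cohort, eps, timescale = "gap")
#' table(cp$stratum, cp$event)
#' @export
build_counting_data <- function(bundle, cohort, episodes, K_max = 10,
                                timescale = c("from_index", "gap"),
                                split_covariates = TRUE,
                                merge_gap_days = NULL) {
  stopifnot(inherits(bundle, "registry_bundle"))
  timescale <- match.arg(timescale)
  merge_gap_days <- merge_gap_days %||% attr(episodes, "merge_gap_days") %||% 7

  base <- counting_base(bundle, cohort, episodes, merge_gap_days, K_max)
  if (base$n_clipped > 0) {
    warn(sprintf("build_counting_data: %d episode(s) beyond follow-up end dropped",
                 base$n_clipped))
  }
  rows <- base$rows |> mutate(origin_day = .data$entry_day, row_id = row_number())
  m <- base$members

  if (split_covariates && nrow(rows)) {
    origin <- bundle$study_start
    yrs <- seq(as.integer(format(origin - 7000, "%Y")),
               as.integer(format(bundle$study_end, "%Y")))
    year_days <- as.numeric(as.Date(paste0(yrs, "-01-01")) - origin)
    year_days <- year_days[year_days > min(rows$entry_day) & year_days < max(rows$exit_day)]

    cuts_year <- tidyr::crossing(
      rows |> select(row_id, entry_day, exit_day),
      tibble(cut_day = year_days)
    ) |>
      filter(cut_day > entry_day, cut_day < exit_day) |>
      select(row_id, cut_day)

    age_cuts <- tidyr::crossing(
      m |> select(patient_id, birth_day),
      tibble(age_b = .age_boundaries)
    ) |>
      transmute(patient_id, cut_day = ceiling(.data$birth_day + .data$age_b * 365.25))
    cuts_age <- rows |>
      select(row_id, patient_id, entry_day, exit_day) |>
      inner_join(age_cuts, by = "patient_id", relationship = "many-to-many") |>
      filter(cut_day > entry_day, cut_day < exit_day) |>
      select(row_id, cut_day)

    pts <- bind_rows(
      rows |> transmute(row_id, t = entry_day),
      cuts_year |> transmute(row_id, t = cut_day),
      cuts_age |> transmute(row_id, t = cut_day),
      rows |> transmute(row_id, t = exit_day)
    ) |>
      distinct() |>
      arrange(row_id, t)

    ## consecutive point pairs within each original row form the sub-intervals
    same_row <- pts$row_id == lead(pts$row_id, default = -1L)
    subs <- tibble(row_id = pts$row_id[same_row],
                   sub_entry = pts$t[same_row],
                   sub_exit = lead(pts$t)[same_row])
    rows <- subs |>
      inner_join(rows |>
                   select(row_id, patient_id, k, full_exit_day = exit_day,
                          event, origin_day),
                 by = "row_id") |>
      transmute(patient_id, k,
                event = if_else(.data$sub_exit == .data$full_exit_day,
                                event, "censored"),
                entry_day = .data$sub_entry, exit_day = .data$sub_exit,
                origin_day)
  }

  if (nrow(rows)) {
    origin <- bundle$study_start
    all_years <- seq(as.integer(format(origin, "%Y")) - 20L,
                     as.integer(format(bundle$study_end, "%Y")))
    year_starts <- as.numeric(as.Date(paste0(all_years, "-01-01")) - origin)
    rows <- rows |>
      left_join(m |> select(patient_id, sex, birth_day, anchor_end_day),
                by = "patient_id") |>
      mutate(
        stratum = .data$k,
        prior_relapses = factor(.data$k, levels = 0:K_max),
        gender = factor(sex, levels = c("F", "M")),
        age_class = age_class((.data$entry_day - .data$birth_day) / 365.25),
        calendar_year = factor(all_years[findInterval(.data$entry_day, year_starts)]),
        entry = if (timescale == "from_index") {
          (.data$entry_day - .data$anchor_end_day) / 365.25
        } else {
          (.data$entry_day - .data$origin_day) / 365.25
        },
        exit = if (timescale == "from_index") {
          (.data$exit_day - .data$anchor_end_day) / 365.25
        } else {
          (.data$exit_day - .data$origin_day) / 365.25
        },
        event = factor(event, levels = c("censored", "relapse", "death"))
      ) |>
      select(patient_id, stratum, entry, exit, event, prior_relapses, age_class,
             gender, calendar_year, entry_day, exit_day, origin_day) |>
      arrange(patient_id, entry_day)
  } else {
    rows <- tibble(patient_id = character(), stratum = integer(),
                   entry = numeric(), exit = numeric(),
                   event = factor(character(), levels = c("censored", "relapse", "death")),
                   prior_relapses = factor(integer(), levels = 0:K_max),
                   age_class = age_class(numeric()), gender = factor(character(), c("F", "M")),
                   calendar_year = factor(character()),
                   entry_day = numeric(), exit_day = numeric(), origin_day = numeric())
  }

  structure(rows, class = c("counting_data", class(rows)),
            timescale = timescale, K_max = K_max,
            merge_gap_days = merge_gap_days,
            proxy = attr(episodes, "proxy"))
}

#' Audit exact day accounting of the counting process
#'
#' For each included patient, follow-up from the index date decomposes
#' exactly into: the remainder of the index episode (index discharge to the
#' end of its quiet window), at-risk time, in-episode (in-hospital span)
#' time, and episode quiet-window time -- to the day. The audit recomputes
#' each component independently and reports the balance. Run with the
#' stratum truncation lifted (large `K_max`), since truncation deliberately
#' discards tail at-risk intervals.
#'
#' @inheritParams build_counting_data
#' @return A tibble with one row per included patient: the component day
#'   counts, `follow_up_days`, and `balance` (components minus follow-up;
#'   0 when the accounting is exact).
#' @export
audit_time_accounting <- function(bundle, cohort, episodes,
                                  merge_gap_days = NULL, K_max = 10000) {
  merge_gap_days <- merge_gap_days %||% attr(episodes, "merge_gap_days") %||% 7
  base <- counting_base(bundle, cohort, episodes, merge_gap_days, K_max)
  m <- base$members
  at_risk <- base$rows |>
    group_by(patient_id) |>
    summarise(at_risk_days = sum(.data$exit_day - .data$entry_day), .groups = "drop")
  ep <- base$episodes |>
    inner_join(m |> select(patient_id, fu_day), by = "patient_id") |>
    mutate(
      dis_day = .data$end_day - merge_gap_days,
      in_episode = pmin(.data$dis_day, fu_day) - .data$start_day,
      quiet = pmin(.data$end_day, fu_day) - pmin(.data$dis_day, fu_day)
    ) |>
    group_by(patient_id) |>
    summarise(in_episode_days = sum(.data$in_episode),
              quiet_window_days = sum(.data$quiet), .groups = "drop")
  m |>
    transmute(patient_id,
              follow_up_days = .data$fu_day - .data$index_day,
              index_episode_days = pmin(.data$anchor_end_day, .data$fu_day) - .data$index_day) |>
    left_join(at_risk, by = "patient_id") |>
    left_join(ep, by = "patient_id") |>
    mutate(across(c("at_risk_days", "in_episode_days", "quiet_window_days"),
                  ~coalesce(.x, 0)),
           balance = .data$index_episode_days + .data$at_risk_days +
             .data$in_episode_days + .data$quiet_window_days - .data$follow_up_days)
}
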