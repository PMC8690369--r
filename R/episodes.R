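#' Relapse-proxy episode identification
#'
#' Three proxy rules turn raw registry event streams into relapse episodes.
#'
#' **Primary proxy** ([identify_primary_episodes()]): a psychiatric
#' hospitalisation lasting at least `min_stay_days` (7) days opens an
#' episode; its start is the hospital admission and its end is the end of
#' the first `merge_gap_days` (7, or 30 for the redefined variant)
#' consecutive days after discharge without rehospitalisation. A readmission
#' within that window is not a new relapse; it is grouped into the same
#' episode. Overlapping or nested stays (ward transfers) are unioned before
#' chaining.
#'
#' **Antipsychotic-switch proxy** ([identify_switch_episodes()]): a
#' psychiatric hospitalisation with at least one overnight stay followed by
#' the start of a new antipsychotic treatment line within
#' `switch_window_days` (30) days of discharge. Stays are merged exactly as
#' in the primary proxy; the episode end follows the same
#' discharge-plus-7-quiet-days rule.
#'
#' **High-frequency outpatient proxy** ([identify_highfreq_episodes()]): a
#' 14-day period with at least 8 outpatient psychiatric visits opens an
#' episode whose start is the end of that fortnight; the episode ends on the
#' first day from which visit frequency stays at or below 1 per week for four
#' consecutive weeks.
#'
#' All three operate on day-precision dates, are invariant to input row
#' order, and return disjoint, chronologically ordered episodes per patient.
#'
#' @param stays Data frame of psychiatric hospital stays (any number of
#'   patients): `patient_id`, `admission_date`, `discharge_date`. Callers
#'   holding the full registry table should use [identify_episodes()], which
#'   filters to psychiatric-coded stays first.
#' @param min_stay_days Minimum qualifying duration in days, measured as
#'   discharge minus admission (nights); default 7.
#' @param merge_gap_days Readmissions starting within this many days of the
#'   previous discharge continue the same episode; also the quiet period
#'   added after the final discharge to close the episode. 7 for the main
#'   primary proxy, 30 for the redefined variant.
#' @param duration_rule How the duration criterion applies to a merged
#'   cluster of stays: `"total_or_single"` (default; the cluster qualifies
#'   when its summed in-hospital days reach `min_stay_days` or any single
#'   stay does) or `"single_stay"` (some single unioned stay must qualify).
#' @return A tibble with one row per episode: `patient_id`, `ordinal`
#'   (1-based within patient), `start`, `end` (Dates).
#' @name relapse_proxies
NULL

## union overlapping stays, then chain stays whose admission follows the
## previous discharge by <= merge_gap_days; one row per cluster.
## Pure numeric day arithmetic with a per-patient offset so that running
## maxima and gaps never cross patient boundaries; no grouped operations.
cluster_stays <- function(stays, merge_gap_days) {
  if (!nrow(stays)) {
    return(tibble(patient_id = character(), cl = integer(),
                  first_adm = as.Date(character()), last_dis = as.Date(character()),
                  covered = numeric(), max_single = numeric()))
  }
  adm <- as.numeric(as.Date(stays$admission_date))
  dis <- as.numeric(as.Date(stays$discharge_date))
  pid <- as.character(stays$patient_id)
  o <- order(pid, adm, dis)
  pid <- pid[o]; adm <- adm[o]; dis <- dis[o]
  off <- cumsum(!duplicated(pid)) * 1e9

  ## union overlapping / nested / touching stays
  runmax <- cummax(dis + off)
  new_union <- (adm + off) > c(-Inf, runmax[-length(runmax)])
  iu_first <- which(new_union)
  iu_last <- c(iu_first[-1L] - 1L, length(adm))
  u_pid <- pid[iu_first]
  u_adm <- adm[iu_first]
  u_dis <- runmax[iu_last] - off[iu_first]
  u_off <- off[iu_first]

  ## chain unioned intervals into clusters
  nu <- length(u_adm)
  gap <- (u_adm + u_off) - c(-Inf, (u_dis + u_off)[-nu])
  new_cl <- gap > merge_gap_days
  ic_first <- which(new_cl)
  ic_last <- c(ic_first[-1L] - 1L, nu)

  dur <- u_dis - u_adm
  cs <- cumsum(dur)
  covered <- cs[ic_last] - cs[ic_first] + dur[ic_first]
  cl_id <- cumsum(new_cl)
  mx <- cummax(dur + cl_id * 1e9)
  max_single <- mx[ic_last] - cl_id[ic_last] * 1e9

  out <- tibble(
    patient_id = u_pid[ic_first],
    first_adm = as.Date(u_adm[ic_first], origin = "1970-01-01"),
    last_dis = as.Date(u_dis[ic_last], origin = "1970-01-01"),
    covered = covered, max_single = max_single
  )
  out$cl <- seq_len(nrow(out)) # cluster row id, unique across patients
  out
}

#' @rdname relapse_proxies
#' @export
identify_primary_episodes <- function(stays, min_stay_days = 7,
                                      merge_gap_days = 7,
                                      duration_rule = c("total_or_single", "single_stay")) {
  duration_rule <- match.arg(duration_rule)
  cl <- cluster_stays(stays, merge_gap_days)
  keep <- if (duration_rule == "total_or_single") {
    cl$covered >= min_stay_days | cl$max_single >= min_stay_days
  } else {
    cl$max_single >= min_stay_days
  }
  cl[keep, ] |>
    group_by(patient_id) |>
    arrange(first_adm, .by_group = TRUE) |>
    transmute(ordinal = row_number(), start = first_adm,
              end = last_dis + merge_gap_days) |>
    ungroup()
}

#' Antipsychotic treatment lines from dispensations
#'
#' A treatment line is a maximal run of dispensations of the same
#' antipsychotic substance; the first dispensation of a different substance
#' starts a new line (a treatment switch). Substance identity is the full
#' ATC code; only codes in class N05A are considered, the rest are dropped.
#'
#' @param dispensations Data frame: `patient_id`, `dispense_date`,
#'   `atc_code` (any number of patients).
#' @return A tibble: `patient_id`, `line_id` (1-based per patient),
#'   `substance`, `line_start`, `line_end` (first and last dispensation of
#'   the line).
#' @export
build_treatment_lines <- function(dispensations) {
  if (!nrow(dispensations)) {
    return(tibble(patient_id = character(), line_id = integer(),
                  substance = character(),
                  line_start = as.Date(character()), line_end = as.Date(character())))
  }
  dispensations |>
    filter(is_antipsychotic(atc_code)) |>
    transmute(patient_id, dispense_date = as.Date(.data$dispense_date),
              substance = toupper(trimws(atc_code))) |>
    arrange(patient_id, dispense_date, substance) |>
    group_by(patient_id) |>
    mutate(line_id = cumsum(substance != lag(substance, default = "<none>"))) |>
    group_by(patient_id, line_id) |>
    summarise(substance = substance[1L], line_start = min_date(dispense_date),
              line_end = max_date(dispense_date), .groups = "drop")
}

#' @rdname relapse_proxies
#' @param treatment_lines Output of [build_treatment_lines()].
#' @param switch_window_days A new treatment line must start within this many
#'   days after discharge (default 30) for the stay to count as a relapse.
#' @export
identify_switch_episodes <- function(stays, treatment_lines,
                                     switch_window_days = 30,
                                     merge_gap_days = 7) {
  cl <- cluster_stays(stays, merge_gap_days) |>
    filter(max_single >= 1) # >= 1 overnight stay somewhere in the cluster
  if (!nrow(cl)) {
    return(tibble(patient_id = character(), ordinal = integer(),
                  start = as.Date(character()), end = as.Date(character())))
  }
  ## a new line (line_id > 1) starting in (discharge, discharge + window]
  new_lines <- treatment_lines |> filter(line_id > 1L)
  switched <- cl |>
    left_join(new_lines, by = "patient_id", relationship = "many-to-many") |>
    group_by(patient_id, cl, first_adm, last_dis) |>
    summarise(has_switch = any(!is.na(line_start) &
                                 line_start > last_dis &
                                 as.numeric(line_start - last_dis) <= switch_window_days),
              .groups = "drop") |>
    filter(.data$has_switch)
  switched |>
    group_by(patient_id) |>
    arrange(first_adm, .by_group = TRUE) |>
    transmute(ordinal = row_number(), start = first_adm,
              end = last_dis + merge_gap_days) |>
    ungroup()
}

## high-frequency scan for a single patient's sorted visit day numbers
highfreq_scan_one <- function(v, fu_end, window_days = 14L, min_visits = 8L,
                              quiet_weeks = 4L) {
  starts <- integer(); ends <- integer()
  count_between <- function(lo, hi) { # visits in [lo, hi]
    findInterval(hi, v) - findInterval(lo - 1L, v)
  }
  scan_from_idx <- 1L
  while (scan_from_idx <= length(v)) {
    d0 <- v[scan_from_idx]
    ## first window [d, d + window - 1] holding >= min_visits, d from first visit
    d_seq <- d0:max(d0, v[length(v)])
    cnt <- count_between(d_seq, d_seq + window_days - 1L)
    hit <- which(cnt >= min_visits)
    if (!length(hit)) break
    ep_start <- d_seq[hit[1L]] + window_days - 1L
    ## end: first day e > start from which each of the quiet_weeks 7-day
    ## blocks [e + 7b, e + 7b + 6] holds <= 1 visit; the empty tail beyond
    ## follow-up guarantees e = fu_end qualifies
    e_seq <- (ep_start + 1L):fu_end
    ok <- rep(TRUE, length(e_seq))
    for (b in seq_len(quiet_weeks) - 1L) {
      ok <- ok & count_between(e_seq + 7L * b, e_seq + 7L * b + 6L) <= 1L
    }
    ep_end <- if (any(ok)) e_seq[which(ok)[1L]] else fu_end
    starts <- c(starts, ep_start); ends <- c(ends, ep_end)
    nxt <- which(v > ep_end)
    if (!length(nxt)) break
    scan_from_idx <- nxt[1L]
  }
  list(start = starts, end = ends)
}

#' @rdname relapse_proxies
#' @param visits Data frame of outpatient psychiatric visits: `patient_id`,
#'   `visit_date` (any number of patients).
#' @param follow_up_end Date (scalar or one per patient, named by patient id)
#'   capping episode ends; an episode whose visit frequency never subsides is
#'   closed at follow-up end. Defaults to 28 days after each patient's last
#'   visit.
#' @export
identify_highfreq_episodes <- function(visits, follow_up_end = NULL) {
  if (!nrow(visits)) {
    return(tibble(patient_id = character(), ordinal = integer(),
                  start = as.Date(character()), end = as.Date(character())))
  }
  origin <- min(as.Date(visits$visit_date))
  by_pat <- visits |>
    transmute(patient_id, day = as.integer(as.Date(.data$visit_date) - origin)) |>
    arrange(patient_id, day) |>
    group_by(patient_id) |>
    summarise(days = list(day), .groups = "drop")

  fu_for <- function(id, last_visit) {
    if (is.null(follow_up_end)) return(last_visit + 28L)
    fu <- follow_up_end
    if (!is.null(names(fu))) fu <- fu[[id]]
    as.integer(as.Date(fu) - origin)
  }
  out <- purrr::map2(by_pat$patient_id, by_pat$days, function(id, v) {
    res <- highfreq_scan_one(v, fu_for(id, v[length(v)]))
    if (!length(res$start)) return(NULL)
    tibble(patient_id = id, ordinal = seq_along(res$start),
           start = origin + res$start, end = origin + res$end)
  })
  out <- purrr::compact(out)
  if (!length(out)) {
    return(tibble(patient_id = character(), ordinal = integer(),
                  start = as.Date(character()), end = as.Date(character())))
  }
  bind_rows(out)
}

#' Identify relapse episodes in a registry bundle
#'
#' Front end over the proxy algorithms: classifies the relevant event stream
#' (psychiatric-coded stays, N05A dispensations, outpatient visits) and runs
#' the requested proxy over every patient.
#'
#' @param bundle A [registry_bundle()].
#' @param proxy `"primary"` (>= 7-day psychiatric hospitalisation, 7-day
#'   merge window), `"primary30"` (30-day merge window), `"switch"`
#'   (overnight stay followed by an antipsychotic switch within 30 days), or
#'   `"highfreq"` (at least 8 outpatient visits in a fortnight).
#' @param min_stay_days,duration_rule,switch_window_days See
#'   [relapse_proxies].
#' @param merge_gap_days Override the proxy's merge window (7, or 30 for
#'   `"primary30"`).
#' @param follow_up_end Optional cap for `"highfreq"` episode ends; defaults
#'   to the bundle's study end.
#' @return A tibble `patient_id`, `proxy`, `ordinal`, `start`, `end`, with
#'   attributes `proxy` and `merge_gap_days`.
#' @examples
#' sim <- simulate_cohort(sim_params(n_patients = 60, seed = 11))
#' identify_episodes(sim$bundle, "primary")
#' @export
identify_episodes <- function(bundle,
                              proxy = c("primary", "primary30", "switch", "highfreq"),
                              min_stay_days = 7,
                              merge_gap_days = NULL,
                              duration_rule = c("total_or_single", "single_stay"),
                              switch_window_days = 30,
                              follow_up_end = NULL) {
  stopifnot(inherits(bundle, "registry_bundle"))
  proxy <- match.arg(proxy)
  duration_rule <- match.arg(duration_rule)
  merge_gap_days <- merge_gap_days %||% if (proxy == "primary30") 30 else 7

  psych <- bundle$hospitalisations |>
    filter(is_psychiatric_dx(diagnosis_code, code_system))

  eps <- switch(
    proxy,
    primary = ,
    primary30 = identify_primary_episodes(psych, min_stay_days, merge_gap_days,
                                          duration_rule),
    switch = identify_switch_episodes(psych, build_treatment_lines(bundle$dispensations),
                                      switch_window_days, merge_gap_days),
    highfreq = identify_highfreq_episodes(
      bundle$outpatient_visits |>
        filter(is_psychiatric_dx(diagnosis_code, code_system)),
      follow_up_end %||% bundle$study_end
    )
  )
  out <- eps |>
    mutate(proxy = proxy, .after = "patient_id") |>
    arrange(patient_id, start)
  attr(out, "proxy") <- proxy
  attr(out, "merge_gap_days") <- merge_gap_days
  out
}
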