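#' Per-stratum summary table (patients at risk, median time, hazard ratio)
#'
#' Assembles the headline table of the analysis: for each prior-relapse
#' count k, the number of patients at risk of their next relapse, the median
#' time to next relapse read off the Aalen-Johansen curve, and the Cox
#' hazard ratio versus patients with no prior relapse. Strata whose
#' cumulative incidence never reaches the quantile have an undefined median
#' (`NA`, printed as an em dash).
#'
#' @param counting A gap-timescale [build_counting_data()] result.
#' @param cox A [fit_cox()] result.
#' @param cif A [cumulative_incidence()] result.
#' @param p Quantile for the time-to-next-relapse column (default 0.5).
#' @return A tibble of class `stratum_summary`: `stratum`, `n_at_risk`,
#'   `n_events`, `median_gap_years`, `hr`, `conf_low`, `conf_high`, `proxy`.
#' @export
summarise_strata <- function(counting, cox, cif, p = 0.5) {
  proxies <- unique(c(attr(counting, "proxy"), attr(cif, "proxy")))
  proxies <- proxies[!is.na(proxies)]
  if (length(proxies) > 1) {
    abort(sprintf("mismatched proxies between inputs: %s",
                  paste(proxies, collapse = " vs ")))
  }
  at_risk <- counting |>
    group_by(stratum) |>
    summarise(n_at_risk = n_distinct(patient_id),
              n_events = sum(event == "relapse"), .groups = "drop")
  med <- median_from_cif(cif, p)
  out <- at_risk |>
    left_join(med, by = "stratum") |>
    left_join(cox$strata |> select(stratum, hr, conf_low, conf_high),
              by = "stratum") |>
    mutate(proxy = if (length(proxies)) proxies else NA_character_) |>
    arrange(stratum)
  structure(out, class = c("stratum_summary", class(out)))
}

#' @export
print.stratum_summary <- function(x, digits = 2, ...) {
  fmt <- function(v, d = digits) ifelse(is.na(v), "—", formatC(v, digits = d, format = "f"))
  cat("Relapse risk by number of prior relapses (proxy:",
      x$proxy[1] %||% "?", ")\n")
  cat(sprintf("%3s %10s %8s %22s %12s\n",
              "k", "n at risk", "events", "median time (years)", "HR (95% CI)"))
  for (i in seq_len(nrow(x))) {
    hr_txt <- if (is.na(x$hr[i])) {
      if (x$stratum[i] == 0) "1 (ref)" else "—"
    } else {
      sprintf("%s (%s-%s)", fmt(x$hr[i]), fmt(x$conf_low[i]), fmt(x$conf_high[i]))
    }
    cat(sprintf("%3d %10d %8d %22s %12s\n", x$stratum[i], x$n_at_risk[i],
                x$n_events[i], fmt(x$median_gap_years[i]), hr_txt))
  }
  invisible(x)
}

#' Run the full relapse-trajectory analysis on a registry bundle
#'
#' End-to-end driver: builds the cohort, identifies relapse episodes under
#' the chosen proxy, constructs the counting-process data, fits the
#' cause-specific Cox model, estimates the per-stratum Aalen-Johansen
#' cumulative incidence of the next relapse, and assembles the per-stratum
#' summary table together with pipeline stage counts.
#'
#' @param bundle A [registry_bundle()].
#' @param proxy Relapse proxy, see [identify_episodes()].
#' @param config A [cohort_config()]; its window defaults to the bundle's.
#' @param K_max Highest prior-relapse stratum (default 10).
#' @param cox_timescale Timescale for the Cox fit: `"from_index"` (time
#'   since the index-episode end; the default baseline) or `"gap"` (clock
#'   reset at each episode end, matching the Aalen-Johansen timescale).
#' @param ... Passed to [identify_episodes()].
#' @return An object of class `relapse_trajectory` with components
#'   `cohort`, `episodes`, `counting_cox`, `counting_gap`, `cox`, `cif`,
#'   `summary`, and `counts` (patients in bundle, included, with at least
#'   one relapse episode, total episodes).
#' @examples
#' sim <- simulate_cohort(sim_params(n_patients = 150, seed = 9))
#' traj <- relapse_trajectory(sim$bundle)
#' traj$summary
#' @export
relapse_trajectory <- function(bundle, proxy = "primary", config = NULL,
                               K_max = 10,
                               cox_timescale = c("from_index", "gap"), ...) {
  stopifnot(inherits(bundle, "registry_bundle"))
  cox_timescale <- match.arg(cox_timescale)
  config <- config %||% cohort_config(bundle$study_start, bundle$study_end)

  cohort <- build_cohort(bundle, config)
  episodes <- identify_episodes(bundle, proxy, ...)
  counting_gap_plain <- build_counting_data(bundle, cohort, episodes, K_max,
                                            timescale = "gap",
                                            split_covariates = FALSE)
  counting_cox <- build_counting_data(bundle, cohort, episodes, K_max,
                                      timescale = cox_timescale)

  if (!nrow(counting_cox) || !any(counting_cox$event == "relapse")) {
    warn("relapse_trajectory: no relapse events; returning empty summary")
    cox <- NULL
    cif <- NULL
    summary <- structure(
      tibble(stratum = integer(), n_at_risk = integer(), n_events = integer(),
             median_gap_years = numeric(), hr = numeric(), conf_low = numeric(),
             conf_high = numeric(), proxy = character()),
      class = c("stratum_summary", "tbl_df", "tbl", "data.frame"))
  } else {
    cox <- fit_cox(counting_cox)
    cif <- cumulative_incidence(counting_gap_plain)
    summary <- summarise_strata(counting_gap_plain, cox, cif)
  }

  rel_by_patient <- episodes |>
    semi_join(cohort |> filter(.data$included), by = "patient_id")
  counts <- tibble(
    n_patients = nrow(cohort),
    n_included = sum(cohort$included),
    n_with_episode = n_distinct(counting_gap_plain$patient_id[
      counting_gap_plain$event == "relapse"]),
    n_episodes_raw = nrow(rel_by_patient),
    n_relapse_events = sum(counting_gap_plain$event == "relapse")
  )

  structure(
    list(cohort = cohort, episodes = episodes, counting_cox = counting_cox,
         counting_gap = counting_gap_plain, cox = cox, cif = cif,
         summary = summary, counts = counts, proxy = attr(episodes, "proxy"),
         config = config, K_max = K_max, cox_timescale = cox_timescale),
    class = "relapse_trajectory"
  )
}

#' @export
print.relapse_trajectory <- function(x, ...) {
  cat("<relapse_trajectory> proxy:", x$proxy, "| cohort variant:",
      x$config$variant, "\n")
  with(x$counts, cat(sprintf(
    "  %d patients -> %d included -> %d with >= 1 relapse; %d relapse events analysed\n",
    n_patients, n_included, n_with_episode, n_relapse_events)))
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}

#' @method glance relapse_trajectory
#' @export
glance.relapse_trajectory <- function(x, ...) {
  bind_cols(x$counts, tibble(proxy = x$proxy, variant = x$config$variant,
                             K_max = x$K_max, cox_timescale = x$cox_timescale))
}
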