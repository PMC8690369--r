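#' Cause-specific Cox model over prior-relapse strata
#'
#' Fits a multivariate Cox proportional hazards model on counting-process
#' data with delayed entry, estimating the cause-specific hazard of relapse:
#' death and administrative censoring are both treated as censoring in the
#' partial likelihood. Covariates are the time-varying prior-relapse count
#' (reference level: 0 prior relapses), age class, gender and calendar year.
#' Ties are handled by the Efron approximation by default -- day-precision
#' registry data produce many tied event times. Confidence intervals are
#' Wald intervals on the log-hazard scale.
#'
#' The partial-likelihood maximisation is delegated to
#' [survival::coxph()]; the contract of this function is the returned
#' estimates, which the package's test suite verifies against a brute-force
#' partial-likelihood oracle on small samples.
#'
#' @param rows A [build_counting_data()] result (covariates split).
#' @param covariates Adjustment covariates besides `prior_relapses`; any of
#'   `"age_class"`, `"gender"`, `"calendar_year"`. Covariates with fewer
#'   than two observed levels are dropped automatically.
#' @param ties Tie-handling method passed to [survival::coxph()].
#' @param robust Use a patient-clustered sandwich variance (off by default).
#' @param conf_level Confidence level for the Wald intervals.
#' @return An object of class `relapse_cox`: the underlying `coxph` fit plus
#'   a per-stratum hazard-ratio table (`$strata`: `stratum`, `hr`,
#'   `conf_low`, `conf_high`, `n_events`).
#' @examples
#' sim <- simulate_cohort(sim_params(n_patients = 150, seed = 2))
#' cohort <- build_cohort(sim$bundle)
#' eps <- identify_episodes(sim$bundle, "primary")
#' cp <- build_counting_data(sim$bundle, cohort, eps, timescale = "gap")
#' fit <- fit_cox(cp)
#' fit$strata
#' @export
fit_cox <- function(rows, covariates = c("age_class", "gender", "calendar_year"),
                    ties = c("efron", "breslow"), robust = FALSE,
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  covariates <- match.arg(covariates, several.ok = TRUE)
  if (!nrow(rows) || !any(rows$event == "relapse")) {
    abort("fit_cox: no relapse events in the counting-process data")
  }
  dat <- rows |>
    mutate(status = as.integer(event == "relapse"),
           prior_relapses = droplevels(.data$prior_relapses)) |>
    mutate(across(all_of(covariates), droplevels))
  usable <- covariates[vapply(dat[covariates], nlevels, 1L) >= 2L]
  terms <- c("prior_relapses", usable)
  f <- stats::as.formula(paste(
    "survival::Surv(entry, exit, status) ~", paste(terms, collapse = " + "),
    if (robust) "+ cluster(patient_id)" else ""
  ))
  fit <- survival::coxph(f, data = dat, ties = ties)

  co <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  names(se) <- names(co)
  dropped <- names(co)[is.na(co)]
  if (length(dropped)) {
    warn(paste("fit_cox: non-identifiable level(s) dropped:",
               paste(dropped, collapse = ", ")))
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  idx <- grep("^prior_relapses", names(co))
  lev <- sub("^prior_relapses", "", names(co)[idx])
  ev <- dat |>
    filter(.data$status == 1L) |>
    count(.data$prior_relapses, name = "n_events")
  strata_tab <- tibble(
    stratum = as.integer(lev),
    coef = unname(co[idx]),
    se = unname(se[idx]),
    hr = exp(unname(co[idx])),
    conf_low = exp(unname(co[idx]) - z * unname(se[idx])),
    conf_high = exp(unname(co[idx]) + z * unname(se[idx]))
  ) |>
    left_join(ev |> mutate(stratum = as.integer(as.character(.data$prior_relapses))) |>
                select(stratum, n_events),
              by = "stratum") |>
    filter(!is.na(coef))

  structure(
    list(fit = fit, strata = strata_tab, covariates = usable, ties = ties,
         conf_level = conf_level, timescale = attr(rows, "timescale"),
         n = length(unique(rows$patient_id)), n_events = sum(dat$status),
         loglik = fit$loglik[length(fit$loglik)]),
    class = "relapse_cox"
  )
}

#' @export
print.relapse_cox <- function(x, ...) {
  cat("<relapse_cox> cause-specific hazard of relapse,", x$timescale,
      "timescale\n", x$n, "patients,", x$n_events, "relapse events; ties:",
      x$ties, "\nHazard ratios vs 0 prior relapses:\n")
  print(x$strata, n = Inf)
  invisible(x)
}

#' @method tidy relapse_cox
#' @export
tidy.relapse_cox <- function(x, ...) {
  co <- stats::coef(x$fit)
  se <- sqrt(diag(x$fit$var))
  z <- qnorm(1 - (1 - x$conf_level) / 2)
  tibble(term = names(co), estimate = unname(co), std.error = unname(se),
         hr = exp(unname(co)),
         conf.low = exp(unname(co) - z * unname(se)),
         conf.high = exp(unname(co) + z * unname(se)))
}

#' @method glance relapse_cox
#' @export
glance.relapse_cox <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, log_partial_lik = x$loglik,
         n_coef = sum(!is.na(stats::coef(x$fit))),
         concordance = unname(x$fit$concordance["concordance"]))
}

#' Aalen-Johansen estimator of cumulative incidence with competing death
#'
#' Nonparametric estimator of the cumulative incidence of the next relapse
#' on the gap timescale, with death as a competing risk. At each event time
#' \eqn{t_i} with \eqn{n_i} subjects at risk, \eqn{d_{rel,i}} relapses and
#' \eqn{d_{death,i}} deaths:
#' \deqn{S(t_i) = S(t_i-) (1 - (d_{rel,i}+d_{death,i})/n_i)}
#' \deqn{F_{rel}(t_i) = F_{rel}(t_i-) + S(t_i-) d_{rel,i}/n_i}
#' and symmetrically for death. With no deaths, \eqn{F_{rel}} reduces to one
#' minus the Kaplan-Meier estimator. Delayed entry is supported (a subject is
#' at risk at \eqn{t} when \eqn{entry < t \le exit}).
#'
#' @param rows Data frame with columns `exit` (event/censoring time), `event`
#'   (values `"relapse"`, `"death"`, `"censored"`) and optionally `entry`
#'   (default 0).
#' @return A tibble of class `cif_curve`: `time`, `n_risk`, `d_relapse`,
#'   `d_death`, `surv`, `cif_relapse`, `cif_death`, starting with a row at
#'   time 0. `surv + cif_relapse + cif_death = 1` at every time.
#' @examples
#' rows <- tibble::tibble(exit = c(1, 2, 3, 4),
#'                        event = c("relapse", "death", "relapse", "censored"))
#' aalen_johansen(rows)
#' @export
aalen_johansen <- function(rows) {
  entry <- if ("entry" %in% names(rows)) rows$entry else rep(0, nrow(rows))
  exit <- rows$exit
  event <- as.character(rows$event)
  if (any(entry >= exit)) {
    abort("aalen_johansen: malformed input, entry must precede exit")
  }
  tt <- sort(unique(exit[event != "censored"]))
  if (!length(tt)) {
    out <- tibble(time = 0, n_risk = length(exit), d_relapse = 0L, d_death = 0L,
                  surv = 1, cif_relapse = 0, cif_death = 0)
    return(structure(out, class = c("cif_curve", class(out))))
  }
  n_risk <- vapply(tt, function(t) sum(entry < t & exit >= t), numeric(1))
  d_rel <- vapply(tt, function(t) sum(exit == t & event == "relapse"), numeric(1))
  d_dth <- vapply(tt, function(t) sum(exit == t & event == "death"), numeric(1))
  if (any(n_risk == 0)) {
    abort("aalen_johansen: no subjects at risk at an event time (malformed input)")
  }
  s <- cumprod(1 - (d_rel + d_dth) / n_risk)
  s_lag <- c(1, s[-length(s)])
  f_rel <- cumsum(s_lag * d_rel / n_risk)
  f_dth <- cumsum(s_lag * d_dth / n_risk)
  out <- tibble(
    time = c(0, tt), n_risk = c(n_risk[1L], n_risk),
    d_relapse = c(0L, as.integer(d_rel)), d_death = c(0L, as.integer(d_dth)),
    surv = c(1, s), cif_relapse = c(0, f_rel), cif_death = c(0, f_dth)
  )
  structure(out, class = c("cif_curve", class(out)))
}

#' Aalen-Johansen curves for every prior-relapse stratum
#'
#' Runs [aalen_johansen()] within each prior-relapse stratum of gap-timescale
#' counting data, giving one cumulative-incidence curve of the next relapse
#' per stratum, as plotted in stacked time-to-next-relapse displays.
#'
#' @param rows A [build_counting_data()] result on the `"gap"` timescale
#'   (`split_covariates = FALSE` is sufficient).
#' @return A tibble of class `relapse_cif`: the [aalen_johansen()] columns
#'   plus `stratum`.
#' @export
cumulative_incidence <- function(rows) {
  if (!is.null(attr(rows, "timescale")) && attr(rows, "timescale") != "gap") {
    abort("cumulative_incidence expects counting data on the gap timescale")
  }
  out <- rows |>
    group_by(stratum) |>
    group_modify(~aalen_johansen(.x)) |>
    ungroup()
  structure(out, class = c("relapse_cif", class(out)),
            K_max = attr(rows, "K_max"), proxy = attr(rows, "proxy"))
}

#' Time by which a proportion of patients has relapsed
#'
#' Reads the `p`-quantile off a cumulative-incidence curve: the smallest
#' event time at which the cumulative incidence of relapse reaches `p`
#' (default the median, 0.5). Undefined -- `NA` -- when the curve never
#' reaches `p`, as happens in heavily censored strata.
#'
#' @param curve A `cif_curve` from [aalen_johansen()], or a `relapse_cif`
#'   from [cumulative_incidence()] (then one value per stratum is returned).
#' @param p Probability in (0, 1).
#' @return A single time (years) or `NA`; for a `relapse_cif`, a tibble
#'   `stratum`, `median_gap_years`.
#' @export
median_from_cif <- function(curve, p = 0.5) {
  if (length(p) != 1 || is.na(p) || p <= 0 || p >= 1) {
    abort("`p` must be a probability strictly between 0 and 1")
  }
  if (inherits(curve, "relapse_cif")) {
    return(curve |>
             group_by(stratum) |>
             summarise(median_gap_years = {
               hit <- which(cif_relapse >= p)
               if (length(hit)) time[hit[1L]] else NA_real_
             }, .groups = "drop"))
  }
  hit <- which(curve$cif_relapse >= p)
  if (length(hit)) curve$time[hit[1L]] else NA_real_
}
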