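#' Simulation parameters for the synthetic registry
#'
#' Defines the generating process of [simulate_cohort()]. The process is a
#' gap-time recurrent-event model: after a patient's index hospitalisation,
#' successive relapse waiting times are exponential with hazard
#' `baseline_rate * acceleration^k` per person-year, where `k` is the number
#' of prior relapses -- each relapse accelerates the next. Death competes with
#' relapse between episodes as an independent exponential. Every true relapse
#' is realised as a schizophrenia-coded psychiatric hospitalisation lasting at
#' least 7 days, optionally followed by a bounce-back readmission within 7
#' days of discharge (which registry episode logic should merge). Noise
#' records -- non-psychiatric stays, short (< 7 day) psychiatric stays,
#' routine outpatient visits -- and a continuous antipsychotic dispensation
#' stream are superimposed.
#'
#' @param n_patients Number of patients.
#' @param study_start,study_end Study window (dates). Default 2006-01-01 to
#'   2015-12-31, a ten-year observation window.
#' @param baseline_rate Relapse hazard with zero prior relapses, events per
#'   person-year (`h0 > 0`).
#' @param acceleration Multiplier on the relapse hazard per prior relapse
#'   (`r >= 1`); hazard with `k` priors is `h0 * r^k`.
#' @param death_rate Death hazard, events per person-year (`>= 0`).
#' @param mean_stay_days Mean of the raw hospital-stay duration draw; relapse
#'   stays are floored at 7 days, the index stay at 1 day.
#' @param readmission_prob Probability a relapse discharge is followed by a
#'   bounce-back readmission starting within 7 days.
#' @param nonpsych_stay_rate Non-psychiatric hospitalisations per person-year.
#' @param short_psych_stay_rate Short (< 7 day) psychiatric stays per
#'   person-year, coded with non-schizophrenia psychiatric diagnoses.
#' @param outpatient_visit_rate Routine outpatient psychiatric visits per
#'   person-year after onset.
#' @param dispensation_interval_days Typical antipsychotic refill gap.
#' @param switch_prob Probability that a relapse discharge is followed by a
#'   switch to a different antipsychotic substance within 30 days.
#' @param prevalent_frac Fraction of patients given a pre-window (1987--2005)
#'   schizophrenia diagnosis and psychiatric hospitalisation, making them
#'   prevalent cases under the incident cohort variants.
#' @param death_during_stay If `TRUE`, death may also strike during a hospital
#'   stay (an independent calendar-time exponential truncates the record
#'   stream); by default death competes only between episodes.
#' @param seed Integer seed; identical parameters and seed reproduce
#'   byte-identical tables.
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_patients = 2000,
                       study_start = "2006-01-01",
                       study_end = "2015-12-31",
                       baseline_rate = 0.5,
                       acceleration = 1.5,
                       death_rate = 0.01,
                       mean_stay_days = 14,
                       readmission_prob = 0.2,
                       nonpsych_stay_rate = 0.2,
                       short_psych_stay_rate = 0.3,
                       outpatient_visit_rate = 4,
                       dispensation_interval_days = 90,
                       switch_prob = 0.3,
                       prevalent_frac = 0.05,
                       death_during_stay = FALSE,
                       seed = 1L) {
  p <- list(
    n_patients = n_patients, study_start = as.Date(study_start),
    study_end = as.Date(study_end), baseline_rate = baseline_rate,
    acceleration = acceleration, death_rate = death_rate,
    mean_stay_days = mean_stay_days, readmission_prob = readmission_prob,
    nonpsych_stay_rate = nonpsych_stay_rate,
    short_psych_stay_rate = short_psych_stay_rate,
    outpatient_visit_rate = outpatient_visit_rate,
    dispensation_interval_days = dispensation_interval_days,
    switch_prob = switch_prob, prevalent_frac = prevalent_frac,
    death_during_stay = isTRUE(death_during_stay), seed = as.integer(seed)
  )
  check_scalar <- function(field, ok, what) {
    x <- p[[field]]
    if (length(x) != 1L || is.na(x) || !ok(x)) {
      abort(sprintf("invalid simulation parameter `%s`: must be %s", field, what))
    }
  }
  check_scalar("n_patients", function(x) x >= 1 && x == floor(x), "a positive integer")
  check_scalar("baseline_rate", function(x) x > 0, "> 0 (events per person-year)")
  check_scalar("acceleration", function(x) x >= 1, ">= 1")
  for (f in c("death_rate", "nonpsych_stay_rate", "short_psych_stay_rate",
              "outpatient_visit_rate")) {
    check_scalar(f, function(x) x >= 0, ">= 0 (events per person-year)")
  }
  check_scalar("mean_stay_days", function(x) x > 0, "a positive number of days")
  check_scalar("dispensation_interval_days", function(x) x > 0, "a positive number of days")
  for (f in c("readmission_prob", "switch_prob", "prevalent_frac")) {
    check_scalar(f, function(x) x >= 0 && x <= 1, "a probability in [0, 1]")
  }
  if (is.na(p$study_start) || is.na(p$study_end) || p$study_start >= p$study_end) {
    abort("invalid simulation parameter `study_start`/`study_end`: study_start must precede study_end")
  }
  check_scalar("seed", function(x) TRUE, "an integer")
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  for (f in setdiff(names(x), c("study_start", "study_end"))) {
    cat(sprintf("  %-28s %s\n", f, format(x[[f]])))
  }
  cat(sprintf("  %-28s %s to %s\n", "study window", format(x$study_start),
              format(x$study_end)))
  invisible(x)
}

.code_palette <- list(
  schizophrenia_icd10 = c("F20.0", "F20.1", "F20.2", "F20.3", "F20.5", "F20.9"),
  schizophrenia_icd9 = c("295.1", "295.3", "295.6"),
  other_psychiatric = c("F31.1", "F32.1", "F33.2"),
  non_psychiatric = c("I21.9", "J18.9"),
  antipsychotics = c("N05AH03", "N05AX08", "N05AH04", "N05AA01",
                     "N05AE04", "N05AL01", "N05AX13")
)

#' Simulate a registry-shaped cohort with known ground truth
#'
#' Generates the four registry tables (see [registry_bundle()]) under the
#' gap-time relapse process described in [sim_params()], together with the
#' ground truth that produced them, so that every downstream stage of the
#' pipeline can be validated against known quantities.
#'
#' Timing model, all at day precision: the patient's index psychiatric stay
#' starts at a uniformly drawn onset day; the at-risk clock for the first
#' relapse starts 7 days after its discharge (the quiet period that closes an
#' episode). With `k` prior relapses the waiting time to the next relapse is
#' exponential with rate `h0 * r^k`, competing with an exponential death rate;
#' the realised relapse admission opens a schizophrenia-coded stay of at least
#' 7 days, a possible bounce-back readmission within 7 days follows, and the
#' clock restarts 7 days after the final discharge.
#'
#' @param params A [sim_params()] object.
#' @return A list with components `bundle` (a [registry_bundle()]) and
#'   `truth`, itself a list of tibbles: `patients` (one row per patient:
#'   onset, index discharge, true death date, prevalent flag) and `relapses`
#'   (one row per true relapse: ordinal `k`, admission date, final discharge,
#'   gap days since the previous episode's end, whether a bounce-back
#'   readmission and/or a treatment switch was generated). The generating
#'   `params` are attached as an attribute of `truth`.
#' @examples
#' sim <- simulate_cohort(sim_params(n_patients = 50, seed = 7))
#' sim$bundle
#' head(sim$truth$relapses)
#' @export
simulate_cohort <- function(params) {
  if (!inherits(params, "sim_params")) {
    abort("`params` must be created by sim_params()")
  }
  withr::local_seed(params$seed)

  W <- as.integer(params$study_end - params$study_start)
  n <- params$n_patients
  h_d <- params$death_rate / 365.25
  scale_stay <- params$mean_stay_days / 2
  pal <- .code_palette
  icd9_cutoff <- as.integer(as.Date("1997-01-01") - params$study_start)

  ## accumulators (per patient slots, bound once at the end)
  acc <- function() vector("list", n)
  h_pid <- acc(); h_adm <- acc(); h_dis <- acc(); h_code <- acc(); h_sys <- acc()
  v_pid <- acc(); v_day <- acc(); v_code <- acc(); v_sys <- acc()
  d_pid <- acc(); d_day <- acc(); d_atc <- acc()
  t_k <- acc(); t_adm <- acc(); t_dis <- acc(); t_gap <- acc()
  t_readm <- acc(); t_switch <- acc()

  pid <- sprintf("P%05d", seq_len(n))
  onset <- sample.int(W - 60L, n, replace = TRUE) - 1L
  age_onset <- pmin(70, pmax(18, rnorm(n, 34, 11.5)))
  birth_day <- onset - as.integer(round(age_onset * 365.25))
  sex <- ifelse(runif(n) < 0.654, "M", "F")
  prevalent <- runif(n) < params$prevalent_frac
  death_day <- rep(NA_integer_, n)
  index_dis <- integer(n)
  at_risk_days <- numeric(n)

  for (i in seq_len(n)) {
    on_i <- onset[i]

    ## --- index stay (>= 1 overnight enforced downstream by cohort rules) ---
    idx_dur <- max(1L, as.integer(round(rgamma(1L, 2, scale = scale_stay))))
    adm <- on_i
    dis <- on_i + idx_dur
    index_dis[i] <- dis
    clock <- dis + 7L

    ## --- relapse / death process, drawn in one vectorised block ---
    Kcap <- max(2L, as.integer(ceiling((W - clock) / 15)) + 2L)
    h_rel <- pmin(params$baseline_rate * params$acceleration^(seq_len(Kcap) - 1), 1e6) / 365.25
    Tw <- rexp(Kcap, h_rel + h_d)
    is_death <- runif(Kcap) < h_d / (h_rel + h_d)
    gap_days <- pmax(1, ceiling(Tw))
    dur <- pmax(7L, as.integer(round(rgamma(Kcap, 2, scale = scale_stay))))
    readm <- runif(Kcap) < params$readmission_prob
    rb_gap <- sample.int(7L, Kcap, replace = TRUE)
    rb_dur <- pmax(1L, rpois(Kcap, 3))
    cycle <- gap_days + dur + ifelse(readm, rb_gap + rb_dur, 0L) + 7L
    clock_before <- clock + c(0, cumsum(cycle))[seq_len(Kcap)]
    event_time <- clock_before + Tw
    censored <- event_time > W
    trigger <- which(censored | is_death)[1L]
    n_rel <- if (is.na(trigger)) Kcap else trigger - 1L
    if (!is.na(trigger) && !censored[trigger] && is_death[trigger]) {
      death_day[i] <- min(W, max(clock_before[trigger] + 1L,
                                 as.integer(ceiling(event_time[trigger]))))
    }

    jj <- seq_len(n_rel)
    at_risk_days[i] <- sum(gap_days[jj]) +
      if (is.na(trigger)) 0 else if (censored[trigger]) {
        max(0, W - clock_before[trigger])
      } else {
        death_day[i] - clock_before[trigger]
      }
    r_adm <- as.integer(clock_before[jj] + gap_days[jj])
    r_dis <- r_adm + dur[jj]
    r_readm <- readm[jj]
    rb_adm <- r_dis + rb_gap[jj]
    rb_dis <- rb_adm + rb_dur[jj]
    final_dis <- ifelse(r_readm, rb_dis, r_dis)

    sw <- runif(n_rel) < params$switch_prob
    sw_day <- as.integer(final_dis + sample.int(30L, max(n_rel, 1L), replace = TRUE)[seq_len(n_rel)])

    ## optional death during a stay: an independent calendar-time clock
    if (params$death_during_stay && params$death_rate > 0) {
      D <- on_i + as.integer(ceiling(rexp(1L, h_d)))
      if (D <= min(death_day[i], W, na.rm = TRUE)) {
        death_day[i] <- D
        keep <- r_adm < D
        jj <- jj[keep]; r_adm <- r_adm[keep]; r_dis <- pmin(r_dis[keep], D)
        r_readm <- r_readm[keep] & rb_adm[keep] < D
        rb_adm <- rb_adm[keep]; rb_dis <- pmin(rb_dis[keep], D)
        final_dis <- ifelse(r_readm, rb_dis, r_dis)
        sw <- sw[keep] & sw_day[keep] < D
        sw_day <- sw_day[keep]
        n_rel <- length(jj)
        dis <- min(dis, D)
        index_dis[i] <- dis
      }
    }
    fu_end <- min(W, death_day[i], na.rm = TRUE)

    ## --- hospitalisation records: index + relapse stays (+ bounce-backs) ---
    n_codes <- 1L + n_rel + sum(r_readm)
    adm_all <- c(adm, r_adm, rb_adm[r_readm])
    dis_all <- c(dis, r_dis, rb_dis[r_readm])
    code_all <- sample(pal$schizophrenia_icd10, n_codes, replace = TRUE)
    sys_all <- rep("ICD10", n_codes)

    ## --- noise stays ---
    m1 <- rpois(1L, params$nonpsych_stay_rate * fu_end / 365.25)
    if (m1 > 0) {
      a1 <- sample.int(max(fu_end, 1L), m1, replace = TRUE) - 1L
      d1 <- pmin(a1 + rpois(m1, 4), fu_end)
      adm_all <- c(adm_all, a1); dis_all <- c(dis_all, d1)
      code_all <- c(code_all, sample(pal$non_psychiatric, m1, replace = TRUE))
      sys_all <- c(sys_all, rep("ICD10", m1))
    }
    span2 <- fu_end - on_i
    m2 <- if (span2 > 1) rpois(1L, params$short_psych_stay_rate * span2 / 365.25) else 0L
    if (m2 > 0) {
      a2 <- on_i + sample.int(span2, m2, replace = TRUE)
      d2 <- pmin(a2 + sample(0:6, m2, replace = TRUE,
                             prob = c(.15, .25, .2, .15, .1, .1, .05)), fu_end)
      adm_all <- c(adm_all, a2); dis_all <- c(dis_all, d2)
      code_all <- c(code_all, sample(pal$other_psychiatric, m2, replace = TRUE))
      sys_all <- c(sys_all, rep("ICD10", m2))
    }

    ## --- pre-window history for prevalent cases ---
    if (prevalent[i]) {
      pre_adm <- -sample(365:6800, 1L)
      pre_dis <- pre_adm + max(1L, rpois(1L, 10))
      pre_icd9 <- pre_adm < icd9_cutoff
      adm_all <- c(adm_all, pre_adm); dis_all <- c(dis_all, pre_dis)
      code_all <- c(code_all, if (pre_icd9) sample(pal$schizophrenia_icd9, 1L)
                              else sample(pal$schizophrenia_icd10, 1L))
      sys_all <- c(sys_all, if (pre_icd9) "ICD9" else "ICD10")
    }

    h_pid[[i]] <- rep(pid[i], length(adm_all))
    h_adm[[i]] <- adm_all; h_dis[[i]] <- dis_all
    h_code[[i]] <- code_all; h_sys[[i]] <- sys_all

    ## --- outpatient visits: diagnostic confirmations + background stream ---
    conf <- pmin(on_i + sample(7:180, 2L), fu_end)
    m3 <- if (span2 > 1) rpois(1L, params$outpatient_visit_rate * span2 / 365.25) else 0L
    bg <- if (m3 > 0) on_i + sample.int(span2, m3, replace = TRUE) else integer()
    vd <- c(conf, bg)
    vc <- c(sample(pal$schizophrenia_icd10, 2L, replace = TRUE),
            sample(c(pal$other_psychiatric, pal$schizophrenia_icd10), m3,
                   replace = TRUE, prob = c(rep(0.7 / 3, 3), rep(0.3 / 6, 6))))
    v_pid[[i]] <- rep(pid[i], length(vd)); v_day[[i]] <- vd; v_code[[i]] <- vc
    v_sys[[i]] <- rep("ICD10", length(vd))

    ## --- antipsychotic dispensation stream with post-relapse switches ---
    start_disp <- on_i + sample(0:14, 1L)
    if (start_disp <= fu_end) {
      n_ref <- as.integer(ceiling((fu_end - start_disp) /
                                    (params$dispensation_interval_days * 0.6))) + 2L
      gaps <- pmax(7, as.integer(round(rnorm(n_ref, params$dispensation_interval_days,
                                             params$dispensation_interval_days / 6))))
      refills <- start_disp + c(0L, cumsum(gaps))
      refills <- refills[refills <= fu_end]
      sw_days <- sort(sw_day[sw & sw_day <= fu_end])
      times <- sort(c(refills, sw_days))
      n_sub <- length(sw_days) + 1L
      subs <- character(n_sub)
      subs[1L] <- sample(pal$antipsychotics, 1L)
      if (n_sub > 1L) {
        for (s in 2:n_sub) subs[s] <- sample(setdiff(pal$antipsychotics, subs[s - 1L]), 1L)
      }
      d_pid[[i]] <- rep(pid[i], length(times)); d_day[[i]] <- times
      d_atc[[i]] <- subs[findInterval(times, sw_days) + 1L]
    }

    if (n_rel > 0) {
      t_k[[i]] <- seq_len(n_rel)
      t_adm[[i]] <- r_adm; t_dis[[i]] <- as.integer(final_dis)
      t_gap[[i]] <- as.integer(gap_days[jj])
      t_readm[[i]] <- r_readm; t_switch[[i]] <- sw
    }
  }

  day2date <- function(d) params$study_start + unlist(d, use.names = FALSE)
  patients <- tibble(
    patient_id = pid, sex = sex,
    birth_date = params$study_start + birth_day,
    death_date = params$study_start + death_day
  )
  hospitalisations <- tibble(
    patient_id = unlist(h_pid, use.names = FALSE),
    admission_date = day2date(h_adm), discharge_date = day2date(h_dis),
    diagnosis_code = unlist(h_code, use.names = FALSE),
    code_system = unlist(h_sys, use.names = FALSE)
  ) |> arrange(patient_id, admission_date, discharge_date)
  outpatient_visits <- tibble(
    patient_id = unlist(v_pid, use.names = FALSE),
    visit_date = day2date(v_day),
    diagnosis_code = unlist(v_code, use.names = FALSE),
    code_system = unlist(v_sys, use.names = FALSE)
  ) |> arrange(patient_id, visit_date)
  dispensations <- tibble(
    patient_id = unlist(d_pid, use.names = FALSE),
    dispense_date = day2date(d_day),
    atc_code = unlist(d_atc, use.names = FALSE)
  ) |> arrange(patient_id, dispense_date)

  bundle <- registry_bundle(patients, hospitalisations, outpatient_visits,
                            dispensations, params$study_start, params$study_end,
                            validate = FALSE)

  truth_patients <- tibble(
    patient_id = pid,
    onset_date = params$study_start + onset,
    index_discharge = params$study_start + index_dis,
    birth_date = patients$birth_date,
    death_date = patients$death_date,
    prevalent = prevalent,
    n_relapses = vapply(t_k, length, integer(1)),
    at_risk_days = at_risk_days
  )
  truth_relapses <- tibble(
    patient_id = unlist(lapply(seq_len(n), function(i) rep(pid[i], length(t_k[[i]]))),
                        use.names = FALSE),
    k = unlist(t_k, use.names = FALSE),
    admission_date = day2date(t_adm),
    episode_discharge = day2date(t_dis),
    gap_days = unlist(t_gap, use.names = FALSE),
    readmitted = unlist(t_readm, use.names = FALSE),
    switched = unlist(t_switch, use.names = FALSE)
  )
  truth <- structure(list(patients = truth_patients, relapses = truth_relapses),
                     params = params, class = "ground_truth")

  list(bundle = bundle, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", nrow(x$patients), "patients,",
      nrow(x$relapses), "true relapses\n")
  invisible(x)
}
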