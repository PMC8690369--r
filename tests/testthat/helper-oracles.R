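## Independent oracles and fixture builders shared across the test files.

## ---- brute-force Aalen-Johansen: explicit risk-set enumeration, subject
## by subject, sequential product-limit updates ----
aj_oracle <- function(entry, exit, event) {
  event <- as.character(event)
  tt <- sort(unique(exit[event != "censored"]))
  S <- 1; f_rel <- 0; f_dth <- 0
  res <- data.frame(time = numeric(), surv = numeric(),
                    cif_relapse = numeric(), cif_death = numeric())
  for (t in tt) {
    at_risk <- 0L
    for (i in seq_along(exit)) {
      if (entry[i] < t && exit[i] >= t) at_risk <- at_risk + 1L
    }
    d_rel <- sum(exit == t & event == "relapse")
    d_dth <- sum(exit == t & event == "death")
    stopifnot(at_risk > 0)
    f_rel <- f_rel + S * d_rel / at_risk
    f_dth <- f_dth + S * d_dth / at_risk
    S <- S * (1 - (d_rel + d_dth) / at_risk)
    res <- rbind(res, data.frame(time = t, surv = S, cif_relapse = f_rel,
                                 cif_death = f_dth))
  }
  res
}

random_aj_instance <- function(n_max = 10) {
  n <- sample(1:n_max, 1)
  data.frame(
    entry = if (runif(1) < 0.3) round(runif(n, 0, 0.5), 2) else rep(0, n),
    exit = numeric(n),
    event = sample(c("relapse", "death", "censored"), n, replace = TRUE)
  ) -> d
  d$exit <- d$entry + round(runif(n, 0.01, 3), 2) + 0.005
  ## encourage tied event times where the interval stays valid
  if (n > 2 && runif(1) < 0.5 && d$exit[1] > d$entry[2]) d$exit[2] <- d$exit[1]
  d
}

## ---- hand-written Cox partial likelihood (right-censored, no ties,
## single binary covariate), maximised by brute force ----
cox_pl_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

cox_pl_oracle <- function(time, status, x) {
  ## coarse grid then golden-section refinement
  grid <- seq(-5, 5, by = 0.1)
  ll <- vapply(grid, cox_pl_loglik, numeric(1), time = time, status = status, x = x)
  b0 <- grid[which.max(ll)]
  stats::optimize(cox_pl_loglik, c(b0 - 0.2, b0 + 0.2), maximum = TRUE,
                  time = time, status = status, x = x, tol = 1e-12)$maximum
}

## ---- brute-force day-by-day episode scanner (O(stays^2 + days)) ----
## naive sequential chaining over stays plus day-enumeration of covered time
primary_episodes_oracle <- function(adm, dis, min_stay_days = 7,
                                    merge_gap_days = 7,
                                    duration_rule = "total_or_single") {
  o <- order(adm, dis)
  adm <- adm[o]; dis <- dis[o]
  clusters <- list(); current <- c(1)
  if (length(adm) == 0) return(data.frame(start = numeric(), end = numeric()))
  for (i in seq_along(adm)[-1]) {
    max_dis <- max(dis[current])
    if (adm[i] <= max_dis + merge_gap_days) {
      current <- c(current, i)
    } else {
      clusters[[length(clusters) + 1]] <- current
      current <- i
    }
  }
  clusters[[length(clusters) + 1]] <- current
  out <- data.frame(start = numeric(), end = numeric())
  for (cl in clusters) {
    covered_days <- unique(unlist(lapply(cl, function(i) {
      if (dis[i] > adm[i]) seq(adm[i], dis[i] - 1) else numeric()
    })))
    covered <- length(covered_days)
    max_single <- 0
    if (covered > 0) {
      runs <- split(sort(covered_days), cumsum(c(1, diff(sort(covered_days)) != 1)))
      max_single <- max(vapply(runs, length, numeric(1)))
    }
    ok <- if (duration_rule == "total_or_single") {
      covered >= min_stay_days || max_single >= min_stay_days
    } else {
      max_single >= min_stay_days
    }
    if (ok) {
      out <- rbind(out, data.frame(start = min(adm[cl]),
                                   end = max(dis[cl]) + merge_gap_days))
    }
  }
  out[order(out$start), , drop = FALSE]
}

## ---- bundle builders ----
empty_bundle <- function() {
  registry_bundle(
    patients = tibble::tibble(patient_id = character(), sex = character(),
                              birth_date = as.Date(character()),
                              death_date = as.Date(character())),
    hospitalisations = tibble::tibble(patient_id = character(),
                                      admission_date = as.Date(character()),
                                      discharge_date = as.Date(character()),
                                      diagnosis_code = character(),
                                      code_system = character()),
    outpatient_visits = tibble::tibble(patient_id = character(),
                                       visit_date = as.Date(character()),
                                       diagnosis_code = character(),
                                       code_system = character()),
    dispensations = tibble::tibble(patient_id = character(),
                                   dispense_date = as.Date(character()),
                                   atc_code = character()),
    study_start = "2006-01-01", study_end = "2015-12-31"
  )
}

D0 <- as.Date("2010-01-01") # fixture day origin

mk_stays <- function(pid, adm, dis, code = "F20.0", system = "ICD10") {
  tibble::tibble(patient_id = pid, admission_date = D0 + adm,
                 discharge_date = D0 + dis,
                 diagnosis_code = code, code_system = system)
}
mk_disp <- function(pid, days, atc) {
  tibble::tibble(patient_id = pid, dispense_date = D0 + days, atc_code = atc)
}
mk_visits <- function(pid, days, code = "F32.1") {
  tibble::tibble(patient_id = pid, visit_date = D0 + days,
                 diagnosis_code = code, code_system = "ICD10")
}

## Twelve hand-built patients exercising every proxy rule; expected episodes
## (as day offsets from D0) enumerated by hand.
fixture_bundle <- function() {
  pid <- sprintf("F%02d", 1:12)
  patients <- tibble::tibble(
    patient_id = pid, sex = rep(c("F", "M"), 6),
    birth_date = as.Date("1980-06-15"), death_date = as.Date(NA)
  )
  hosp <- dplyr::bind_rows(
    mk_stays("F01", 0, 7),                       # single 7-night stay
    mk_stays("F02", 0, 3),                       # 3 nights: switch proxy only
    mk_stays("F03", c(0, 15), c(10, 18)),        # bounce-back, 5-day gap
    mk_stays("F04", c(0, 18), c(10, 20)),        # 8-day gap
    mk_stays("F05", c(0, 39), c(10, 41)),        # 29-day gap
    mk_stays("F06", c(0, 41), c(10, 51)),        # 31-day gap
    mk_stays("F07", 0, 2),                       # switch at 10 days
    mk_stays("F08", 0, 2),                       # switch at 40 days: too late
    mk_stays("F09", 0, 2)                        # refill only, no switch
  )
  disp <- dplyr::bind_rows(
    mk_disp("F02", c(-100, -40), "N05AH03"), mk_disp("F02", 10, "N05AX08"),
    mk_disp("F07", c(-60, -30), "N05AH03"), mk_disp("F07", c(12, 40), "N05AX08"),
    mk_disp("F08", c(-60, -30), "N05AH03"), mk_disp("F08", 42, "N05AH04"),
    mk_disp("F09", c(-60, 10, 40), "N05AH03")
  )
  visits <- dplyr::bind_rows(
    mk_visits("F10", 0:7),                       # 8 visits in a fortnight
    mk_visits("F11", seq(0, 12, by = 2)),        # 7 visits: below threshold
    mk_visits("F12", c(0:7, c(20, 23, 27, 30, 34, 37, 41, 44)))
  )
  registry_bundle(patients, hosp, visits, disp,
                  study_start = "2006-01-01", study_end = "2015-12-31")
}

## expected episodes per proxy, day offsets from D0
fixture_expected <- function(proxy) {
  tab <- list(
    primary = data.frame(
      patient_id = c("F01", "F03", "F04", "F05", "F06", "F06"),
      start = c(0, 0, 0, 0, 0, 41),
      end = c(14, 25, 17, 17, 17, 58)
    ),
    primary30 = data.frame(
      patient_id = c("F01", "F03", "F04", "F05", "F06", "F06"),
      start = c(0, 0, 0, 0, 0, 41),
      end = c(37, 48, 50, 71, 40, 81)
    ),
    switch = data.frame(
      patient_id = c("F02", "F07"),
      start = c(0, 0),
      end = c(10, 9)
    ),
    highfreq = data.frame(
      patient_id = c("F10", "F12"),
      start = c(13, 13),
      end = c(14, 42)
    )
  )
  tab[[proxy]]
}

## small quick default for simulation-based tests
quick_params <- function(n = 300, seed = 1, ...) {
  sim_params(n_patients = n, seed = seed, ...)
}
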